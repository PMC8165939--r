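#' Configuration for a synthetic spheroid phantom series
#'
#' The phantom emulates what the real assay sees: a dark spheroid body on a
#' brighter phase-contrast background, growing over a 96-timepoint (hourly)
#' course. The `round` phenotype mimics self-renewing spheroids: a disk whose
#' radius grows linearly. The `branched` phenotype mimics differentiating
#' spheroids: identical to the round phantom until `branch_onset`, after
#' which elliptical lobes ("buds") grow outward along angles fixed per well
#' (a static morphogenesis axis). Static imaging artifacts — a bright halo
#' ring and dust specks, both constant across frames — plus per-frame
#' Gaussian noise and sub-pixel centroid jitter complete the scene.
#'
#' Phase-contrast optics are approximated as dark interior + bright ring, not
#' physically simulated: the downstream method consumes only frame-to-frame
#' intensity differences.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param n_timepoints number of frames (hourly acquisitions).
#' @param initial_radius spheroid radius at the first frame, pixels.
#' @param growth_rate body radius growth, pixels per timepoint.
#' @param phenotype `"round"` or `"branched"`.
#' @param n_branches number of lobes for the branched phenotype.
#' @param branch_onset 1-based timepoint at which lobes start growing.
#' @param branch_growth_rate lobe elongation, pixels per timepoint.
#' @param lobe_width lobe semi-minor axis, pixels.
#' @param foreground_level,background_level intensities in native units.
#' @param halo_amplitude intensity added on the static halo ring (0 disables).
#' @param halo_radius radius of the static halo ring; default (`NULL`) places
#'   it 24 px outside the largest extent the spheroid can reach — beyond the
#'   dilated reach of the moving edge — so the ring never moves and never
#'   overlaps the growing object.
#' @param dust_count number of static high-contrast specks, placed outside
#'   the halo ring.
#' @param noise_sd per-pixel Gaussian noise standard deviation, native units.
#' @param jitter_sd per-frame centroid jitter standard deviation, pixels.
#' @param seed integer seed; the series is fully determined by it.
#' @return A `phantom_config` list, validated.
#' @export
phantom_config <- function(image_size = c(256L, 256L), n_timepoints = 96L,
                           initial_radius = 10, growth_rate = 0.30,
                           phenotype = c("round", "branched"),
                           n_branches = 3L, branch_onset = 20L,
                           branch_growth_rate = 0.28, lobe_width = 7,
                           foreground_level = 60, background_level = 110,
                           halo_amplitude = 70, halo_radius = NULL,
                           dust_count = 6L, noise_sd = 2, jitter_sd = 0.03,
                           seed = 1L) {
  phenotype <- match.arg(phenotype)
  cfg <- list(image_size = as.integer(image_size),
              n_timepoints = as.integer(n_timepoints),
              initial_radius = initial_radius, growth_rate = growth_rate,
              phenotype = phenotype, n_branches = as.integer(n_branches),
              branch_onset = as.integer(branch_onset),
              branch_growth_rate = branch_growth_rate,
              lobe_width = lobe_width,
              foreground_level = foreground_level,
              background_level = background_level,
              halo_amplitude = halo_amplitude, halo_radius = halo_radius,
              dust_count = as.integer(dust_count),
              noise_sd = noise_sd, jitter_sd = jitter_sd,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
}

## maximum extent any phenotype with these geometry parameters can reach;
## deliberately phenotype-independent so a round and a branched config with
## the same geometry get the same halo placement (and identical backdrops)
max_phantom_extent <- function(cfg) {
  r_final <- cfg$initial_radius + (cfg$n_timepoints - 1L) * cfg$growth_rate
  ext <- r_final
  if (cfg$n_branches > 0L) {
    lobe_len <- cfg$branch_growth_rate *
      max(0L, cfg$n_timepoints - cfg$branch_onset)
    ext <- r_final + lobe_len + 4  # lobe tip reaches r + len + 3
  }
  ext
}

validate_phantom_config <- function(cfg) {
  half <- min(cfg$image_size) / 2
  r_final <- cfg$initial_radius + (cfg$n_timepoints - 1L) * cfg$growth_rate
  if (r_final >= half)
    stop("spheroid would outgrow the frame: final radius ", r_final,
         " >= half image size ", half)
  if (max_phantom_extent(cfg) + 4 * cfg$jitter_sd >= half)
    stop("branched lobes would outgrow the frame; reduce branch_growth_rate")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$n_timepoints < 2L) stop("need at least 2 timepoints")
  if (is.null(cfg$halo_radius))
    cfg$halo_radius <- min(max_phantom_extent(cfg) + 24, half - 6)
  if (cfg$halo_amplitude > 0 && cfg$halo_radius <= max_phantom_extent(cfg))
    stop("halo_radius must lie outside the spheroid's maximum extent")
  cfg
}

## squared-distance grids from a centre, reused for every primitive
dist2_grid <- function(h, w, cy, cx) {
  dy <- (seq_len(h) - cy)
  dx <- (seq_len(w) - cx)
  outer(dy^2, dx^2, `+`)
}

## Foreground coverage in [0, 1] with a soft edge of width `edge` pixels —
## the diffraction-limited edge of a phase image is not a hard step, and a
## soft edge is what lets sub-pixel growth register as an intensity change
## in every consecutive-frame Delta. The ground-truth mask is coverage >= 0.5.
render_phantom_coverage <- function(cfg, t, centre, angles, edge = 1.5) {
  h <- cfg$image_size[1L]; w <- cfg$image_size[2L]
  r <- cfg$initial_radius + (t - 1L) * cfg$growth_rate
  dist <- sqrt(dist2_grid(h, w, centre[1L], centre[2L]))
  cov <- pmin(pmax((r - dist) / edge + 0.5, 0), 1)
  if (cfg$phenotype == "branched" && t > cfg$branch_onset &&
      cfg$n_branches > 0L) {
    len <- cfg$branch_growth_rate * (t - cfg$branch_onset)
    a <- len / 2 + 6          # semi-major; buds start as small caps
    b <- cfg$lobe_width       # semi-minor
    yy <- matrix(seq_len(h) - centre[1L], h, w)
    xx <- matrix(rep(seq_len(w) - centre[2L], each = h), h, w)
    for (th in angles) {
      d <- r + len / 2 - 3    # lobe centre; overlaps the body by ~3 px
      oy <- d * sin(th); ox <- d * cos(th)
      u <- (yy - oy) * sin(th) + (xx - ox) * cos(th)
      v <- -(yy - oy) * cos(th) + (xx - ox) * sin(th)
      q <- sqrt(u^2 / a^2 + v^2 / b^2)
      ## (1 - q) * b approximates the signed distance to the ellipse edge
      cov <- pmax(cov, pmin(pmax((1 - q) * b / edge + 0.5, 0), 1))
    }
  }
  cov
}

#' Generate one ground-truthed phantom time-lapse series
#'
#' Deterministic given `config$seed`. Geometry draws (lobe angles, dust
#' positions) and per-frame draws (jitter, noise) come from separate seeded
#' streams, so a round and a branched config sharing the same seed and
#' geometry parameters produce bitwise-identical frames before
#' `branch_onset` — the property that forces early-timepoint classifier
#' confusion.
#'
#' @param config a [phantom_config()].
#' @param keep_masks store the per-timepoint ground-truth masks (default
#'   `TRUE`; disable to bound memory on large plates — areas are always kept).
#' @return list with `series` (a [frame_series()]) and `truth`: per-timepoint
#'   masks (if kept), true areas in px^2, phenotype label, and the static
#'   `artifact_mask` (halo ring + dust pixels).
#' @export
generate_series <- function(config, keep_masks = TRUE) {
  cfg <- validate_phantom_config(config)
  h <- cfg$image_size[1L]; w <- cfg$image_size[2L]
  centre0 <- c((h + 1) / 2, (w + 1) / 2)

  ## geometry stream: consumed identically for both phenotypes
  set.seed(cfg$seed)
  angles <- runif(max(cfg$n_branches, 0L), 0, 2 * pi)
  artifact <- matrix(FALSE, h, w)
  if (cfg$halo_amplitude > 0) {
    d2 <- dist2_grid(h, w, centre0[1L], centre0[2L])
    artifact <- artifact |
      (d2 >= (cfg$halo_radius - 1.5)^2 & d2 <= (cfg$halo_radius + 1.5)^2)
  }
  if (cfg$dust_count > 0L) {
    placed <- 0L
    while (placed < cfg$dust_count) {
      ry <- sample.int(h - 4L, 1L) + 2L
      rx <- sample.int(w - 4L, 1L) + 2L
      if (sqrt((ry - centre0[1L])^2 + (rx - centre0[2L])^2) >
          cfg$halo_radius + 4) {
        artifact[ry + (-1:1), rx + (-1:1)] <- TRUE
        placed <- placed + 1L
      }
    }
  }
  backdrop <- matrix(cfg$background_level, h, w)
  backdrop[artifact] <- pmin(cfg$background_level + cfg$halo_amplitude,
                             255)[1L]

  ## frame stream: jitter + noise, one seeded draw sequence
  set.seed(cfg$seed + 1000003L)
  frames <- vector("list", cfg$n_timepoints)
  masks <- if (keep_masks) vector("list", cfg$n_timepoints) else NULL
  areas <- integer(cfg$n_timepoints)
  for (t in seq_len(cfg$n_timepoints)) {
    jit <- if (cfg$jitter_sd > 0) rnorm(2L, 0, cfg$jitter_sd) else c(0, 0)
    cov <- render_phantom_coverage(cfg, t, centre0 + jit, angles)
    mask <- cov >= 0.5
    img <- backdrop * (1 - cov) + cfg$foreground_level * cov
    if (cfg$noise_sd > 0)
      img <- img + rnorm(h * w, 0, cfg$noise_sd)
    img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), h, w)
    frames[[t]] <- img
    areas[t] <- sum(mask)
    if (keep_masks) masks[[t]] <- mask
  }

  series <- frame_series(frames, well_id = "PH01",
                         condition = cfg$phenotype, interval = 1,
                         pixel_size = NA_real_, t0_index = 1L, bit_depth = 8L)
  list(series = series,
       truth = list(masks = masks, areas = areas,
                    phenotype = cfg$phenotype, artifact_mask = artifact,
                    branch_angles = if (cfg$phenotype == "branched") angles
                                    else numeric(0)))
}

#' Generate a full synthetic plate of round and branched wells
#'
#' Mirrors the real experiment's layout: round (self-renewing, `E8`) wells in
#' plate columns 1-3 and branched (differentiating, `KSR_BMP4`) wells in
#' columns 10-12. Each well receives a distinct seed derived from
#' `base_seed`, so wells are independent and the whole plate is reproducible.
#'
#' @param config_round,config_branched [phantom_config()]s for the two
#'   phenotypes (their `phenotype` fields are forced).
#' @param n_wells_per_condition wells per condition (18 reproduces the real
#'   dataset shape of 36 wells).
#' @param base_seed integer; per-well seeds are `base_seed + 101 * index`.
#' @param conditions named character vector mapping phenotype to condition
#'   label, default `c(round = "E8", branched = "KSR_BMP4")`.
#' @param keep_masks keep per-timepoint ground-truth masks per well
#'   (memory-heavy on full plates; default `FALSE`).
#' @return list with `wells` (named list of [frame_series()]), `layout`
#'   (data.frame `well,condition`), and `truth` (named list per well).
#' @export
generate_plate <- function(config_round, config_branched,
                           n_wells_per_condition, base_seed = 1L,
                           conditions = c(round = "E8", branched = "KSR_BMP4"),
                           keep_masks = FALSE) {
  if (n_wells_per_condition < 1L) stop("need >= 1 well per condition")
  config_round$phenotype <- "round"
  config_branched$phenotype <- "branched"
  well_names <- function(cols) {
    n <- n_wells_per_condition
    rows <- LETTERS[((seq_len(n) - 1L) %/% length(cols)) + 1L]
    cc <- cols[((seq_len(n) - 1L) %% length(cols)) + 1L]
    sprintf("%s%02d", rows, cc)
  }
  ids <- c(well_names(1:3), well_names(10:12))
  phen <- rep(c("round", "branched"), each = n_wells_per_condition)
  wells <- list(); truth <- list()
  for (i in seq_along(ids)) {
    cfg <- if (phen[i] == "round") config_round else config_branched
    cfg$seed <- as.integer(base_seed + 101L * i)
    cfg <- validate_phantom_config(cfg)
    gs <- generate_series(cfg, keep_masks = keep_masks)
    gs$series$well_id <- ids[i]
    gs$series$condition <- unname(conditions[phen[i]])
    wells[[ids[i]]] <- gs$series
    truth[[ids[i]]] <- gs$truth
  }
  layout <- data.frame(well = ids, condition = unname(conditions[phen]),
                       stringsAsFactors = FALSE)
  list(wells = wells, layout = layout, truth = truth)
}
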