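#' Segmentation configuration for Delta-based spheroid masks
#'
#' @param threshold intensity difference (native units) at or above which a
#'   pixel is classified as moving spheroid; a difference of 0 is background,
#'   so with the default of 1 any nonzero integer change counts as motion.
#' @param smoothing_sigma Gaussian sigma (pixels) applied to each frame
#'   before subtraction; 0 disables. Real sensors make almost every pixel
#'   differ by >= 1 between frames, so a blur is needed to keep the integer
#'   threshold meaningful: at sigma 1.5 the pre-subtraction blur attenuates
#'   pixel noise of a few native units below the threshold while the moving
#'   spheroid edge still swings tens of units.
#' @param expansion_radius disk radius (pixels) by which surviving objects
#'   are morphologically dilated ("expanding" the spheroid pixels).
#' @param min_object_area connected components (8-connectivity) smaller than
#'   this (px^2) are removed before expansion.
#' @param keep `"largest_object"` (default: one spheroid per well) or
#'   `"all_objects"`.
#' @param low_conf_factor a Delta whose 99th-percentile value exceeds this
#'   multiple of the series-median 99th percentile (e.g. a medium change
#'   shifting global intensity) is flagged low-confidence, not dropped.
#' @return A validated `segmentation_config` list.
#' @export
segmentation_config <- function(threshold = 1, smoothing_sigma = 1.5,
                                expansion_radius = 5L, min_object_area = 50L,
                                keep = c("largest_object", "all_objects"),
                                low_conf_factor = 10) {
  keep <- match.arg(keep)
  if (threshold < 1) stop("threshold must be >= 1 native intensity unit")
  if (expansion_radius < 0) stop("expansion_radius must be >= 0")
  list(threshold = threshold, smoothing_sigma = smoothing_sigma,
       expansion_radius = as.integer(expansion_radius),
       min_object_area = as.integer(min_object_area), keep = keep,
       low_conf_factor = low_conf_factor)
}

#' Compute the Delta image of two consecutive frames
#'
#' The pixel-wise absolute intensity difference |I_t - I_(t-1)|, computed in
#' double precision so unsigned integer inputs cannot wrap around. Pixels
#' whose intensity does not change belong to the static background; pixels
#' that change belong to the moving, growing spheroid. Optionally both
#' frames are Gaussian-smoothed before subtraction.
#'
#' @param frame_prev,frame_next same-shape numeric matrices (native units).
#' @param smoothing_sigma Gaussian sigma in pixels, 0 for none.
#' @param timepoint timepoint assigned to the Delta (convention: the later
#'   frame — the mask describes where the spheroid is now).
#' @return A `delta_image`: list with `values` (non-negative matrix),
#'   `timepoint`, `smoothing_sigma`.
#' @export
compute_delta <- function(frame_prev, frame_next, smoothing_sigma = 0,
                          timepoint = NA_integer_) {
  if (!identical(dim(frame_prev), dim(frame_next)))
    stop("frames must have identical dimensions")
  if (smoothing_sigma < 0) stop("smoothing_sigma must be >= 0")
  a <- matrix(as.double(frame_prev), nrow(frame_prev))
  b <- matrix(as.double(frame_next), nrow(frame_next))
  if (smoothing_sigma > 0) {
    a <- as.matrix(EBImage::gblur(a, sigma = smoothing_sigma))
    b <- as.matrix(EBImage::gblur(b, sigma = smoothing_sigma))
  }
  structure(list(values = abs(b - a), timepoint = as.integer(timepoint),
                 smoothing_sigma = smoothing_sigma),
            class = "delta_image")
}

#' Threshold a Delta image into moving-spheroid vs background
#'
#' A pixel is classified as moving spheroid when its Delta value reaches the
#' threshold; everything below is static background.
#'
#' @param delta a `delta_image` from [compute_delta()].
#' @param threshold intensity difference in native units (>= 1).
#' @return Logical matrix: `TRUE` where moving.
#' @export
threshold_delta <- function(delta, threshold = 1) {
  stopifnot(inherits(delta, "delta_image"))
  if (threshold < 1) stop("threshold must be >= 1")
  delta$values >= threshold
}

#' Refine a raw thresholded mask into a single spheroid mask
#'
#' Pipeline: (1) drop 8-connected components smaller than
#' `min_object_area`; (2) with `keep = "largest_object"`, retain only the
#' largest surviving component; (3) dilate with a disk of
#' `expansion_radius` (pixel expansion); (4) fill holes. Selecting the
#' single object *before* expansion matters: dilating first lets residual
#' noise clusters that sit near the object merge into it and inflate the
#' mask. The centroid is the mean pixel coordinate of the final mask. An
#' empty result is a flagged state, not an error.
#'
#' @param raw logical matrix from [threshold_delta()].
#' @param config a [segmentation_config()].
#' @param timepoint timepoint carried onto the mask.
#' @param low_confidence flag carried onto the mask (see
#'   [segmentation_config()]).
#' @return A `spheroid_mask`: list with `mask`, `timepoint`,
#'   `centroid` (row, col), `area_px`, `empty`, `low_confidence`.
#' @export
refine_mask <- function(raw, config = segmentation_config(),
                        timepoint = NA_integer_, low_confidence = FALSE) {
  stopifnot(is.matrix(raw))
  m <- raw
  if (any(m) && config$min_object_area > 0L) {
    lab <- EBImage::bwlabel(m)
    sz <- tabulate(lab)
    keep_ids <- which(sz >= config$min_object_area)
    m <- matrix(lab %in% keep_ids & lab > 0L, nrow(raw))
  }
  if (!any(m))
    return(new_spheroid_mask(matrix(FALSE, nrow(raw), ncol(raw)),
                             timepoint, low_confidence))
  if (config$keep == "largest_object") {
    lab <- EBImage::bwlabel(m)
    sz <- tabulate(lab)
    m <- matrix(as.vector(lab == which.max(sz)), nrow(raw))
  }
  if (config$expansion_radius > 0L) {
    brush <- EBImage::makeBrush(2L * config$expansion_radius + 1L, "disc")
    m <- as.matrix(EBImage::dilate(m, brush)) > 0
  }
  m <- as.matrix(EBImage::fillHull(EBImage::Image(m * 1))) > 0
  if (config$keep == "largest_object") {
    lab <- EBImage::bwlabel(m)
    sz <- tabulate(lab)
    m <- matrix(as.vector(lab == which.max(sz)), nrow(raw))
  }
  new_spheroid_mask(m, timepoint, low_confidence)
}

new_spheroid_mask <- function(mask, timepoint, low_confidence = FALSE) {
  area <- sum(mask)
  centroid <- if (area > 0L) {
    idx <- which(mask, arr.ind = TRUE)
    c(mean(idx[, 1L]), mean(idx[, 2L]))
  } else c(NA_real_, NA_real_)
  structure(list(mask = mask, timepoint = as.integer(timepoint),
                 centroid = centroid, area_px = as.integer(area),
                 empty = area == 0L,
                 low_confidence = isTRUE(low_confidence)),
            class = "spheroid_mask")
}

#' @export
print.spheroid_mask <- function(x, ...) {
  if (x$empty) cat(sprintf("spheroid_mask: t=%d, empty\n", x$timepoint))
  else cat(sprintf("spheroid_mask: t=%d, area=%d px, centroid=(%.1f, %.1f)%s\n",
                   x$timepoint, x$area_px, x$centroid[1L], x$centroid[2L],
                   if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Segment a whole frame series via consecutive-frame Deltas
#'
#' A series of T frames yields T-1 Delta images and masks, assigned to
#' timepoints `t0+1 ... t0+T-1` (each Delta belongs to the later frame; the
#' first timepoint has no mask). Frame pairs are processed independently, so
#' results do not depend on evaluation order. Deltas whose 99th-percentile
#' value exceeds `low_conf_factor` times the series median of that statistic
#' (global intensity shifts, e.g. a medium change) are flagged
#' low-confidence.
#'
#' @param series a [frame_series()].
#' @param config a [segmentation_config()].
#' @return List of `spheroid_mask`, one per timepoint from `t0+1`.
#' @export
segment_series <- function(series, config = segmentation_config()) {
  stopifnot(inherits(series, "frame_series"))
  n <- length(series$frames)
  if (n < 2L) stop("need at least 2 frames to compute Deltas")
  deltas <- vector("list", n - 1L)
  p99 <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    deltas[[i]] <- compute_delta(series$frames[[i]], series$frames[[i + 1L]],
                                 smoothing_sigma = config$smoothing_sigma,
                                 timepoint = series$t0_index + i)
    p99[i] <- stats::quantile(deltas[[i]]$values, 0.99, names = FALSE)
  }
  ref <- stats::median(p99)
  masks <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    low_conf <- ref > 0 && p99[i] > config$low_conf_factor * ref
    raw <- threshold_delta(deltas[[i]], config$threshold)
    masks[[i]] <- refine_mask(raw, config,
                              timepoint = series$t0_index + i,
                              low_confidence = low_conf)
  }
  masks
}

#' Write per-timepoint masks and an index CSV
#'
#' Masks are written as 0/255 PNG files named
#' `<well>_t<timepoint>_mask.png`; the index CSV has one row per mask.
#'
#' @param masks list of `spheroid_mask` from [segment_series()].
#' @param well_id well the masks belong to.
#' @param out_dir output directory.
#' @return Invisibly, the index data.frame.
#' @export
write_masks <- function(masks, well_id, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  idx <- do.call(rbind, lapply(masks, function(m) {
    data.frame(well = well_id, timepoint = m$timepoint,
               area_px = m$area_px,
               centroid_row = m$centroid[1L], centroid_col = m$centroid[2L],
               empty = m$empty, low_confidence = m$low_confidence)
  }))
  for (m in masks)
    png::writePNG(m$mask * 1,
                  file.path(out_dir,
                            sprintf("%s_t%03d_mask.png", well_id, m$timepoint)))
  utils::write.csv(idx, file.path(out_dir,
                                  sprintf("%s_masks_index.csv", well_id)),
                   row.names = FALSE, quote = FALSE)
  invisible(idx)
}
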