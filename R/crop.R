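#' Crop a square window centred on the Delta-mask centroid
#'
#' The classifier never sees whole wells: each stored image is a square
#' window centred on the centroid of the segmented Delta mask, so the
#' spheroid is always at the centre of the crop. Out-of-bounds regions are
#' padded with `pad_value`; intensities are rescaled to `[0, 1]` by the
#' native bit-depth maximum.
#'
#' @param frame integer matrix in native units.
#' @param mask a `spheroid_mask`; if empty, the image centre is used as
#'   fallback (flagged via attribute `fallback_centre`).
#' @param output_size side of the square crop (>= 32).
#' @param pad_value intensity (native units) for out-of-bounds pixels.
#' @param bit_depth 8 or 16, sets the rescaling maximum.
#' @return `output_size` x `output_size` numeric matrix in `[0, 1]`.
#' @export
crop_on_centroid <- function(frame, mask, output_size = 96L, pad_value = 0,
                             bit_depth = 8L) {
  if (output_size < 32L) stop("output_size must be >= 32")
  fallback <- is.null(mask) || mask$empty
  ctr <- if (fallback) (dim(frame) + 1) / 2 else mask$centroid
  s <- as.integer(output_size)
  r0 <- round(ctr[1L]) - s %/% 2L
  c0 <- round(ctr[2L]) - s %/% 2L
  out <- matrix(as.numeric(pad_value), s, s)
  rows <- (r0 + 1L):(r0 + s)
  cols <- (c0 + 1L):(c0 + s)
  rin <- rows >= 1L & rows <= nrow(frame)
  cin <- cols >= 1L & cols <= ncol(frame)
  out[rin, cin] <- frame[rows[rin], cols[cin]]
  out <- out / (2^bit_depth - 1)
  attr(out, "fallback_centre") <- fallback
  out
}

#' Build a crop dataset from a segmented series
#'
#' One crop per timepoint from `t0+1` (the first frame has no Delta mask).
#' By default the raw frame at the mask's timepoint is cropped, guided by
#' the Delta centroid; `source = "delta"` crops the Delta magnitude image
#' instead.
#'
#' @param series a [frame_series()].
#' @param masks output of [segment_series()] for the same series.
#' @param output_size,pad_value see [crop_on_centroid()].
#' @param source `"frame"` (default) or `"delta"`.
#' @return list with `x` (array `output_size` x `output_size` x 1 x T-1),
#'   `well`, `timepoint`, `condition` vectors.
#' @export
build_crop_dataset <- function(series, masks, output_size = 96L,
                               pad_value = 0, source = c("frame", "delta")) {
  source <- match.arg(source)
  stopifnot(inherits(series, "frame_series"))
  n <- length(masks)
  x <- array(0, dim = c(output_size, output_size, 1L, n))
  tps <- integer(n)
  for (i in seq_len(n)) {
    m <- masks[[i]]
    fi <- m$timepoint - series$t0_index + 1L
    img <- if (source == "frame") series$frames[[fi]]
           else {
             d <- compute_delta(series$frames[[fi - 1L]], series$frames[[fi]])
             matrix(as.integer(round(d$values)), nrow(d$values))
           }
    x[, , 1L, i] <- crop_on_centroid(img, m, output_size, pad_value,
                                     series$bit_depth)
    tps[i] <- m$timepoint
  }
  list(x = x, well = rep(series$well_id, n), timepoint = tps,
       condition = rep(series$condition, n))
}

#' Concatenate crop datasets from several wells
#' @param datasets list of outputs of [build_crop_dataset()].
#' @return A single dataset list of the same shape.
#' @export
bind_crop_datasets <- function(datasets) {
  s <- dim(datasets[[1L]]$x)[1L]
  n <- sum(vapply(datasets, function(d) dim(d$x)[4L], integer(1)))
  x <- array(0, dim = c(s, s, 1L, n))
  well <- character(n); tp <- integer(n); cond <- character(n)
  at <- 0L
  for (d in datasets) {
    k <- dim(d$x)[4L]
    x[, , , at + seq_len(k)] <- d$x
    well[at + seq_len(k)] <- d$well
    tp[at + seq_len(k)] <- d$timepoint
    cond[at + seq_len(k)] <- d$condition
    at <- at + k
  }
  list(x = x, well = well, timepoint = tp, condition = cond)
}

#' Split a crop dataset by whole wells
#'
#' The evaluation set is all timepoints of `n_holdout_wells_per_group`
#' randomly selected wells from each condition group; the training set is
#' all timepoints of the remaining wells. The split is decided at well
#' level, never image level: frames that are one hour apart are near
#' duplicates, so any image-level split would leak the evaluation wells
#' into training.
#'
#' @param dataset a crop dataset (see [bind_crop_datasets()]).
#' @param n_holdout_wells_per_group wells held out per condition (default 4).
#' @param seed integer seed deciding the random well selection.
#' @return list with `train` and `eval` datasets plus `train_wells`,
#'   `eval_wells`.
#' @export
split_by_well <- function(dataset, n_holdout_wells_per_group = 4L,
                          seed = 1L) {
  wells <- unique(data.frame(well = dataset$well,
                             condition = dataset$condition,
                             stringsAsFactors = FALSE))
  set.seed(seed)
  eval_wells <- unlist(lapply(split(wells$well, wells$condition), function(w) {
    if (length(w) <= n_holdout_wells_per_group)
      stop("a group has only ", length(w), " wells; cannot hold out ",
           n_holdout_wells_per_group)
    sample(w, n_holdout_wells_per_group)
  }), use.names = FALSE)
  train_wells <- setdiff(wells$well, eval_wells)
  stopifnot(length(intersect(train_wells, eval_wells)) == 0L)
  subset_ds <- function(sel) {
    list(x = dataset$x[, , , sel, drop = FALSE],
         well = dataset$well[sel], timepoint = dataset$timepoint[sel],
         condition = dataset$condition[sel])
  }
  list(train = subset_ds(dataset$well %in% train_wells),
       eval = subset_ds(dataset$well %in% eval_wells),
       train_wells = sort(train_wells), eval_wells = sort(eval_wells))
}

#' Augment one training image
#'
#' Random horizontal flip (p = 0.5), random vertical flip (p = 0.5), a
#' random exact right-angle rotation (0/90/180/270, uniform), and a random
#' crop to 87.5% of the side followed by bilinear resize back to the
#' original size. Used during training only; the evaluation path applies no
#' augmentation. The rotation matters when each specimen carries a fixed
#' random orientation (as budding spheroids do): without it a classifier
#' can memorize the orientations of the training wells instead of learning
#' orientation-general morphology, and then fails on unseen wells.
#'
#' @param img square numeric matrix in `[0, 1]`.
#' @param flip,rotate,random_crop logical switches.
#' @return Augmented matrix, same dimensions as the input.
#' @export
augment_image <- function(img, flip = TRUE, rotate = TRUE,
                          random_crop = TRUE) {
  s <- nrow(img)
  if (flip) {
    if (runif(1) < 0.5) img <- img[, rev(seq_len(s))]   # horizontal
    if (runif(1) < 0.5) img <- img[rev(seq_len(s)), ]   # vertical
  }
  if (rotate) {
    k <- sample(0:3, 1L)
    for (i in seq_len(k)) img <- t(img)[rev(seq_len(s)), ]  # 90 deg CCW
  }
  if (random_crop) {
    cs <- as.integer(round(0.875 * s))
    r0 <- sample.int(s - cs + 1L, 1L) - 1L
    c0 <- sample.int(s - cs + 1L, 1L) - 1L
    sub <- img[r0 + seq_len(cs), c0 + seq_len(cs)]
    img <- as.matrix(EBImage::resize(sub, w = s, h = s))
  }
  img
}
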