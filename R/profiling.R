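#' Standardize a feature table into a z-scored matrix
#'
#' Empty-flagged records are excluded; each remaining feature column is
#' centred and scaled to unit variance over all included records (the
#' features mix units — px^2, px, dimensionless ratios — so z-scoring puts
#' them on a common footing before PCA). Zero-variance columns are dropped
#' with a warning.
#'
#' @param table feature table from [assemble_table()].
#' @param features feature columns to use; defaults to the full shape set.
#' @return list with `matrix` (records x features, z-scored), `info`
#'   (data.frame `well`, `timepoint`, `condition` aligned to rows), and
#'   `features` (retained column names).
#' @export
standardize_features <- function(table,
                                 features = c("area_px2", "perimeter",
                                              "form_factor", "eccentricity",
                                              "solidity", "extent",
                                              "major_axis_len",
                                              "minor_axis_len",
                                              "width_to_length_ratio")) {
  stopifnot(is.data.frame(table))
  keep <- !table$empty
  if (sum(keep) < 2L)
    stop("need at least 2 non-empty records to standardize")
  df <- table[keep, , drop = FALSE]
  x <- as.matrix(df[, features, drop = FALSE])
  sds <- apply(x, 2L, stats::sd)
  dead <- sds == 0 | is.na(sds)
  if (any(dead)) {
    warning("dropping zero-variance feature(s): ",
            paste(features[dead], collapse = ", "))
    x <- x[, !dead, drop = FALSE]
    features <- features[!dead]
  }
  if (!ncol(x)) stop("no features with nonzero variance")
  x <- scale(x)
  attr(x, "scaled:center") <- NULL; attr(x, "scaled:scale") <- NULL
  list(matrix = x,
       info = data.frame(well = df$well, timepoint = df$timepoint,
                         condition = df$condition,
                         stringsAsFactors = FALSE),
       features = features)
}

#' Principal component analysis of standardized shape features
#'
#' Covariance-eigendecomposition PCA over all (well, timepoint) records
#' pooled across the time course. Deterministic: each component's sign is
#' fixed so its largest-magnitude loading is positive.
#'
#' @param std output of [standardize_features()] (or a bare numeric matrix).
#' @param k number of components (default `min(dim)`).
#' @return A `pca_result`: `scores` (records x k), `loadings`
#'   (features x k), `explained_variance_ratio`, plus the row `info` when
#'   available.
#' @export
run_pca <- function(std, k = NULL) {
  x <- if (is.list(std)) std$matrix else std
  info <- if (is.list(std)) std$info else NULL
  p <- ncol(x)
  if (is.null(k)) k <- min(dim(x))
  if (k > p) stop("k = ", k, " exceeds number of retained features (", p, ")")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ## sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = load,
                 explained_variance_ratio = evr[seq_len(k)],
                 info = info),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d records, %d components; var explained: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}

#' Quantify how the two conditions separate over time in PC space
#'
#' At each timepoint, the records of that timepoint are sliced out of the
#' pooled PCA and two statistics are computed on their first-two-component
#' scores: the Euclidean distance between the two condition centroids, and
#' the mean silhouette width of the condition labels. Timepoints at which
#' only one condition is present are omitted with a warning.
#'
#' @param result a `pca_result` carrying row `info` (from [run_pca()] on a
#'   [standardize_features()] output).
#' @return data.frame with `timepoint`, `centroid_distance`, `silhouette`,
#'   `n_records`.
#' @export
separation_over_time <- function(result) {
  stopifnot(inherits(result, "pca_result"), !is.null(result$info))
  info <- result$info
  conds <- sort(unique(info$condition))
  if (length(conds) != 2L)
    stop("separation requires exactly 2 condition labels, got ",
         length(conds))
  s2 <- result$scores[, 1:2, drop = FALSE]
  tps <- sort(unique(info$timepoint))
  rows <- lapply(tps, function(tp) {
    sel <- info$timepoint == tp
    cond <- info$condition[sel]
    if (length(unique(cond)) < 2L) {
      warning("timepoint ", tp, " has a single condition; omitted")
      return(NULL)
    }
    x <- s2[sel, , drop = FALSE]
    c1 <- colMeans(x[cond == conds[1L], , drop = FALSE])
    c2 <- colMeans(x[cond == conds[2L], , drop = FALSE])
    sil <- if (all(table(cond) >= 2L)) {
      mean(cluster::silhouette(as.integer(factor(cond, levels = conds)),
                               stats::dist(x))[, "sil_width"])
    } else NA_real_
    data.frame(timepoint = tp,
               centroid_distance = sqrt(sum((c1 - c2)^2)),
               silhouette = sil, n_records = sum(sel))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Centred rolling mean with truncated edge windows
#'
#' Window of width `window` centred on each index; at the edges the window
#' is truncated, so the output has the same length as the input.
#'
#' @param x numeric vector.
#' @param window window width (default 10, the 10-hour smoothing used for
#'   accuracy and separation curves).
#' @return Numeric vector, same length as `x`.
#' @export
rolling_mean <- function(x, window = 10L) {
  n <- length(x)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half_lo):min(n, i + half_hi)], na.rm = TRUE)
  }, numeric(1))
}
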