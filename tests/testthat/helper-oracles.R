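# Independent reference implementations used as oracles. These stay
# deliberately naive (double loops, direct definitions) and never call the
# package's own code paths.

# pixel-by-pixel absolute difference
oracle_delta <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(a))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(a)))
      out[i, j] <- abs(as.numeric(b[i, j]) - as.numeric(a[i, j]))
  out
}

# count of pixels at or above a threshold
oracle_threshold_count <- function(delta, thr) {
  n <- 0L
  for (v in as.vector(delta)) if (v >= thr) n <- n + 1L
  n
}

# rasterized disk mask by direct pixel test
oracle_disk <- function(h, w, cy, cx, r) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(h))
    for (j in seq_len(w))
      if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- TRUE
  m
}

random_frame <- function(h, w, max = 255L) {
  matrix(sample.int(max + 1L, h * w, replace = TRUE) - 1L, h, w)
}

# spheroid_mask wrapper for hand-built masks
as_mask <- function(m, timepoint = 1L) {
  deltasphere:::new_spheroid_mask(m, timepoint)
}
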