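# deterministic separable fixture: bright disk vs bright cross on a dim
# noisy background, organized into wells so well-level splitting applies
make_shape_dataset <- function(n = 200L, size = 48L, n_wells = 20L,
                               seed = 99L) {
  set.seed(seed)
  kinds <- rep(c("disk", "cross"), each = n / 2)
  x <- array(0, c(size, size, 1L, n))
  ctr <- (size + 1) / 2
  d2 <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, `+`)
  for (i in seq_len(n)) {
    img <- matrix(0.1 + rnorm(size * size, 0, 0.02), size, size)
    if (kinds[i] == "disk") {
      img[d2 <= (size / 4)^2] <- 0.8
    } else {
      arm <- round(size * c(0.42, 0.58)); span <- round(size * c(0.15, 0.85))
      img[arm[1]:arm[2], span[1]:span[2]] <- 0.8
      img[span[1]:span[2], arm[1]:arm[2]] <- 0.8
    }
    x[, , 1L, i] <- img
  }
  wells <- paste0(ifelse(kinds == "disk", "D", "C"),
                  rep_len(seq_len(n_wells / 2), n))
  list(x = x, well = wells, timepoint = rep_len(1:10, n), condition = kinds)
}

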