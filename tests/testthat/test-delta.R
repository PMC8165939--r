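test_that("identical frames give an all-zero Delta at any smoothing", {
  set.seed(1)
  f <- random_frame(32, 32)
  for (sg in c(0, 1, 2.5)) {
    d <- compute_delta(f, f, smoothing_sigma = sg)
    expect_true(all(d$values == 0))
    expect_true(all(threshold_delta(d, 1) == FALSE))
  }
})

test_that("a uniform intensity step yields a constant Delta", {
  a <- matrix(10L, 12, 12); b <- matrix(13L, 12, 12)
  d <- compute_delta(a, b, smoothing_sigma = 0)
  expect_true(all(d$values == 3))
  expect_error(compute_delta(a, matrix(0L, 10, 12)), "dimensions")
})

test_that("compute_delta matches the brute-force pixel oracle", {
  set.seed(42)
  for (i in 1:10) {
    a <- random_frame(32, 32); b <- random_frame(32, 32)
    expect_identical(compute_delta(a, b, 0)$values, oracle_delta(a, b))
  }
})

test_that("thresholding keeps exactly the pixels at or above threshold", {
  set.seed(5)
  for (i in 1:5) {
    a <- random_frame(24, 24, max = 8L); b <- random_frame(24, 24, max = 8L)
    d <- compute_delta(a, b, 0)
    for (thr in c(1, 2, 5))
      expect_identical(sum(threshold_delta(d, thr)),
                       oracle_threshold_count(d$values, thr))
  }
})

test_that("delta is symmetric and shift-equivariant", {
  set.seed(9)
  a <- random_frame(20, 20); b <- random_frame(20, 20)
  expect_identical(compute_delta(a, b, 0)$values, compute_delta(b, a, 0)$values)
  # translate both frames by (2, 3): interior of the Delta translates too
  sh <- function(m, dy, dx) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  d0 <- compute_delta(a, b, 0)$values
  d1 <- compute_delta(sh(a, 2, 3), sh(b, 2, 3), 0)$values
  expect_identical(d1[3:20, 4:20], d0[1:18, 1:17])
})

test_that("mask pixel count is non-increasing in the threshold", {
  set.seed(11)
  a <- random_frame(30, 30); b <- random_frame(30, 30)
  d <- compute_delta(a, b, 1)
  counts <- vapply(1:20, function(thr) sum(threshold_delta(d, thr)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("refine_mask removes specks, expands, and fills holes", {
  raw <- matrix(FALSE, 60, 60)
  raw[20:30, 20:30] <- TRUE          # 121-px blob
  raw[25, 25] <- FALSE               # hole
  raw[45:47, 45:47] <- TRUE          # 9-px speck
  cfg <- segmentation_config(expansion_radius = 2L, min_object_area = 50L)
  out <- refine_mask(raw, cfg)
  # oracle from independent morphological steps
  keep <- matrix(FALSE, 60, 60); keep[20:30, 20:30] <- TRUE
  keep[25, 25] <- FALSE
  brush <- EBImage::makeBrush(5L, "disc")
  oracle <- as.matrix(EBImage::fillHull(EBImage::dilate(keep, brush))) > 0
  expect_identical(out$mask, matrix(as.vector(oracle), 60))
  expect_false(any(out$mask[40:52, 40:52]))
  expect_false(out$empty)
  expect_equal(out$area_px, sum(oracle))
})

test_that("refine_mask flags an empty result instead of failing", {
  out <- refine_mask(matrix(FALSE, 10, 10), segmentation_config())
  expect_true(out$empty)
  expect_equal(out$area_px, 0L)
  expect_true(all(is.na(out$centroid)))
})

test_that("with no expansion or size filter a solid blob only gets hole-filled", {
  raw <- matrix(FALSE, 30, 30)
  raw[10:20, 8:22] <- TRUE
  raw[14, 15] <- FALSE
  cfg <- segmentation_config(expansion_radius = 0L, min_object_area = 0L)
  out <- refine_mask(raw, cfg)
  filled <- raw; filled[14, 15] <- TRUE
  expect_identical(out$mask, matrix(as.vector(filled), 30))
})

test_that("segment_series yields T-1 masks assigned to the later frame", {
  cfg <- phantom_config(image_size = c(128L, 128L), n_timepoints = 12L,
                        noise_sd = 0, seed = 3)
  gs <- generate_series(cfg)
  masks <- segment_series(gs$series)
  expect_length(masks, 11L)
  expect_identical(vapply(masks, `[[`, integer(1), "timepoint"), 2:12)
  s1 <- gs$series; s1$frames <- s1$frames[1]
  expect_error(segment_series(structure(s1, class = "frame_series")),
               "2 frames")
})

test_that("a static series segments to all-empty masks", {
  cfg <- phantom_config(image_size = c(128L, 128L), n_timepoints = 8L,
                        growth_rate = 0, noise_sd = 0, jitter_sd = 0,
                        seed = 2)
  masks <- segment_series(generate_series(cfg)$series)
  expect_true(all(vapply(masks, `[[`, logical(1), "empty")))
})

test_that("noiseless growing phantom: every mask present, centroid on target", {
  cfg <- phantom_config(noise_sd = 0, seed = 5)
  gs <- generate_series(cfg, keep_masks = FALSE)
  masks <- segment_series(gs$series)
  expect_false(any(vapply(masks, `[[`, logical(1), "empty")))
  for (m in masks)
    expect_lt(sqrt(sum((m$centroid - 128.5)^2)), 3)
})

test_that("a global intensity shift is flagged low-confidence, not dropped", {
  cfg <- phantom_config(image_size = c(128L, 128L), n_timepoints = 10L,
                        seed = 8)
  gs <- generate_series(cfg)
  # simulate a medium change: one frame jumps by 40 native units
  gs$series$frames[[6]] <- gs$series$frames[[6]] + 40L
  masks <- segment_series(gs$series)
  lc <- vapply(masks, `[[`, logical(1), "low_confidence")
  expect_true(lc[5] || lc[6])       # deltas 5->6 and 6->7 both spike
  expect_false(any(lc[1:3]))
})
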