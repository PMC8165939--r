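fake_table <- function(n_wells = 6L, n_tp = 8L, shift = 0, seed = 1L,
                       conditions = c("E8", "KSR_BMP4")) {
  # synthetic feature table: two conditions, optional mean shift on half
  set.seed(seed)
  wells <- sprintf("W%02d", seq_len(n_wells))
  cond <- rep(conditions, each = n_wells / 2)
  rows <- list()
  for (i in seq_along(wells)) for (tp in 2:(n_tp + 1L)) {
    mu <- if (cond[i] == conditions[2L]) shift else 0
    rows[[length(rows) + 1L]] <- data.frame(
      well = wells[i], timepoint = tp, condition = cond[i],
      area_px2 = 500 + rnorm(1, mu * 100, 20),
      perimeter = 80 + rnorm(1, mu * 10, 3),
      form_factor = 0.9 + rnorm(1, -mu * 0.1, 0.02),
      eccentricity = 0.3 + rnorm(1, mu * 0.1, 0.05),
      solidity = 0.95 + rnorm(1, 0, 0.01),
      extent = 0.7 + rnorm(1, 0, 0.02),
      major_axis_len = 30 + rnorm(1, mu * 5, 2),
      minor_axis_len = 27 + rnorm(1, 0, 2),
      width_to_length_ratio = 0.9 + rnorm(1, -mu * 0.05, 0.02),
      centroid_row = 64, centroid_col = 64, empty = FALSE,
      low_confidence = FALSE)
  }
  do.call(rbind, rows)
}

test_that("standardized features have zero mean and unit variance", {
  std <- standardize_features(fake_table())
  mus <- colMeans(std$matrix)
  sds <- apply(std$matrix, 2, sd)
  expect_true(all(abs(mus) < 1e-9))
  expect_true(all(abs(sds - 1) < 1e-9))
  expect_equal(nrow(std$info), nrow(std$matrix))
})

test_that("zero-variance features are dropped with a warning", {
  tab <- fake_table()
  tab$extent <- 0.5
  expect_warning(std <- standardize_features(tab), "extent")
  expect_false("extent" %in% std$features)
})

test_that("standardize rejects degenerate tables", {
  tab <- fake_table()[1, ]
  expect_error(standardize_features(tab), "at least 2")
  tab2 <- fake_table()[1:4, ]
  tab2$empty <- TRUE
  expect_error(standardize_features(tab2), "at least 2")
})

test_that("PCA on collinear data loads one component", {
  x <- cbind(seq(-2, 2, length.out = 50))
  x <- cbind(x, 3 * x)
  x <- scale(x)
  res <- run_pca(x, k = 2)
  expect_equal(res$explained_variance_ratio[1], 1, tolerance = 1e-9)
  expect_error(run_pca(x, k = 5), "exceeds")
})

test_that("isotropic data splits variance evenly", {
  set.seed(20)
  x <- matrix(rnorm(2000), 1000, 2)
  res <- run_pca(scale(x), k = 2)
  expect_equal(res$explained_variance_ratio[1], 0.5, tolerance = 0.1)
  expect_equal(sum(res$explained_variance_ratio), 1, tolerance = 1e-9)
})

test_that("loadings are orthonormal and reconstruct the data", {
  std <- standardize_features(fake_table(shift = 1))
  k <- length(std$features)
  res <- run_pca(std, k = k)
  gram <- crossprod(res$loadings)
  expect_equal(gram, diag(k), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(res$explained_variance_ratio) <= 1e-12))
  recon <- res$scores %*% t(res$loadings)
  expect_equal(recon, std$matrix, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA scores are invariant under record permutation", {
  std <- standardize_features(fake_table(shift = 1))
  res <- run_pca(std, k = 2)
  set.seed(3)
  perm <- sample(nrow(std$matrix))
  std2 <- list(matrix = std$matrix[perm, ], info = std$info[perm, ],
               features = std$features)
  res2 <- run_pca(std2, k = 2)
  expect_equal(res2$scores, res$scores[perm, ], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("identical condition distributions give near-zero silhouette", {
  tab <- fake_table(n_wells = 36L, n_tp = 4L, shift = 0, seed = 8)
  res <- run_pca(standardize_features(tab), k = 2)
  sep <- separation_over_time(res)
  expect_true(all(abs(sep$silhouette) < 0.15))
})

test_that("well-separated conditions give silhouette near 1", {
  # two point clouds displaced on every feature, within-spread << shift
  tab <- fake_table(n_wells = 8L, n_tp = 4L, shift = 100, seed = 9)
  set.seed(10)
  off <- as.numeric(tab$condition == "KSR_BMP4")
  for (cn in c("solidity", "extent", "minor_axis_len"))
    tab[[cn]] <- tab[[cn]] + off * 50 * stats::sd(tab[[cn]])
  res <- run_pca(standardize_features(tab), k = 2)
  sep <- separation_over_time(res)
  expect_true(all(sep$silhouette > 0.9))
  expect_true(all(sep$centroid_distance > 0))
})

test_that("timepoints with a single condition are omitted with a warning", {
  tab <- fake_table(shift = 1)
  tab <- tab[!(tab$condition == "E8" & tab$timepoint == 3), ]
  res <- run_pca(standardize_features(tab), k = 2)
  expect_warning(sep <- separation_over_time(res), "single condition")
  expect_false(3 %in% sep$timepoint)
})

test_that("rolling mean preserves constants and length", {
  expect_equal(rolling_mean(rep(0.7, 30), 10), rep(0.7, 30))
  x <- rnorm(25)
  expect_length(rolling_mean(x, 10), 25)
  expect_equal(rolling_mean(x, 10)[13], mean(x[9:18]))
})
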