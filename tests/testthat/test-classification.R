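test_that("crop_on_centroid extracts a centred window and pads edges", {
  set.seed(4)
  frame <- random_frame(100, 100)
  m <- matrix(FALSE, 100, 100); m[46:54, 46:54] <- TRUE
  mask <- as_mask(m)
  crop <- crop_on_centroid(frame, mask, output_size = 40L)
  expect_identical(dim(crop), c(40L, 40L))
  expect_equal(crop, frame[31:70, 31:70] / 255, ignore_attr = TRUE)
  expect_false(attr(crop, "fallback_centre"))

  # centroid near the left edge: leading columns padded
  m2 <- matrix(FALSE, 100, 100); m2[48:52, 3:7] <- TRUE
  crop2 <- crop_on_centroid(frame, as_mask(m2), output_size = 64L,
                            pad_value = 0)
  expect_true(all(crop2[, 1:27] == 0))
  expect_gt(mean(crop2[, 28:64] > 0), 0.9)

  # constant frame rescales to the constant
  crop3 <- crop_on_centroid(matrix(51L, 80, 80), mask, output_size = 40L)
  expect_true(all(abs(crop3 - 51 / 255) < 1e-12))

  # empty mask falls back to the frame centre, flagged
  crop4 <- crop_on_centroid(frame, as_mask(matrix(FALSE, 100, 100)),
                            output_size = 40L)
  expect_true(attr(crop4, "fallback_centre"))
  expect_error(crop_on_centroid(frame, mask, output_size = 16L), ">= 32")
})

test_that("split_by_well holds out whole wells, deterministically", {
  ds <- make_shape_dataset()
  sp <- split_by_well(ds, n_holdout_wells_per_group = 2L, seed = 5L)
  expect_length(sp$eval_wells, 4L)
  expect_length(intersect(sp$train_wells, sp$eval_wells), 0L)
  expect_setequal(unique(ds$well), c(sp$train_wells, sp$eval_wells))
  # every image of an eval well is in eval
  expect_setequal(unique(sp$eval$well), sp$eval_wells)
  sp2 <- split_by_well(ds, n_holdout_wells_per_group = 2L, seed = 5L)
  expect_identical(sp$eval_wells, sp2$eval_wells)
  expect_error(split_by_well(ds, n_holdout_wells_per_group = 10L, seed = 1L),
               "cannot hold out")
})

test_that("augmentation is identity when disabled and preserves shape", {
  set.seed(6)
  img <- matrix(runif(48 * 48), 48, 48)
  expect_identical(
    augment_image(img, flip = FALSE, rotate = FALSE, random_crop = FALSE),
    img)
  # four successive quarter-rotations restore the image
  rot <- function(m) t(m)[rev(seq_len(nrow(m))), ]
  expect_identical(rot(rot(rot(rot(img)))), img)
  out <- augment_image(img, flip = TRUE, random_crop = TRUE)
  expect_identical(dim(out), dim(img))
  expect_true(all(out >= min(img) - 1e-9 & out <= max(img) + 1e-9))
  # flipping is an involution
  flipped <- img[, rev(seq_len(48))]
  expect_identical(flipped[, rev(seq_len(48))], img)
})

test_that("an untrained classifier is uninformed; training separates shapes", {
  ds <- make_shape_dataset()
  set.seed(1)
  layers <- build_network("small_cnn")
  out <- deltasphere:::net_forward(layers, ds$x[, , , 1:32, drop = FALSE])$out
  loss0 <- deltasphere:::cross_entropy(out,
                                       match(ds$condition[1:32],
                                             c("cross", "disk")))$loss
  expect_equal(loss0, log(2), tolerance = 0.15)

  mod <- train_classifier(ds, model_config(epochs = 5L, seed = 3L))
  probs <- deltasphere:::predict_probs(mod, ds$x)
  expect_true(all(abs(colSums(probs) - 1) < 1e-6))
  acc <- mean(mod$classes[apply(probs, 2, which.max)] == ds$condition)
  expect_gte(acc, 0.95)
})

test_that("training is reproducible given the seed", {
  ds <- make_shape_dataset(n = 64L)
  cfg <- model_config(epochs = 1L, seed = 21L)
  m1 <- train_classifier(ds, cfg)
  m2 <- train_classifier(ds, cfg)
  expect_identical(deltasphere:::net_params(m1$layers),
                   deltasphere:::net_params(m2$layers))
  expect_error(train_classifier(list(x = ds$x, well = ds$well,
                                     timepoint = ds$timepoint,
                                     condition = rep("disk", 64L)),
                                cfg),
               "2 classes")
})

test_that("evaluation reports per-timepoint accuracy and blocks leakage", {
  ds <- make_shape_dataset(n = 240L, n_wells = 24L, seed = 13L)
  sp <- split_by_well(ds, n_holdout_wells_per_group = 3L, seed = 2L)
  mod <- train_classifier(sp$train, model_config(epochs = 5L, seed = 3L))
  ev <- evaluate_classifier(mod, sp$eval)
  expect_true(all(ev$accuracy_curve$accuracy >= 0.9))   # separable classes
  expect_true(all(ev$accuracy_curve$rolling_accuracy >= 0.9))
  pc <- ev$predictions[, c("p_cross", "p_disk")]
  expect_true(all(abs(rowSums(pc) - 1) < 1e-6))
  expect_identical(nrow(ev$accuracy_curve),
                   length(unique(sp$eval$timepoint)))
  # evaluating on any training well raises
  expect_error(evaluate_classifier(mod, sp$train), "leakage")
})

test_that("a label-permuted evaluation stays inside the chance band", {
  ds <- make_shape_dataset(n = 240L, n_wells = 24L, seed = 13L)
  sp <- split_by_well(ds, n_holdout_wells_per_group = 3L, seed = 2L)
  mod <- train_classifier(sp$train, model_config(epochs = 5L, seed = 3L))
  flipped <- sp$eval
  flipped$condition <- ifelse(flipped$condition == "disk", "cross", "disk")
  ev <- evaluate_classifier(mod, flipped)
  # a near-perfect model scored against flipped labels inverts to ~0
  expect_true(mean(ev$accuracy_curve$accuracy) < 0.1)
})

test_that("checkpoints are stored and restorable", {
  ds <- make_shape_dataset(n = 64L)
  mod <- train_classifier(ds, model_config(epochs = 2L, seed = 8L,
                                           checkpoint_every = 1L))
  expect_gte(length(mod$checkpoints), 4L)
  early <- load_checkpoint(mod, 1L)
  expect_false(identical(deltasphere:::net_params(early$layers),
                         deltasphere:::net_params(mod$layers)))
  restored <- load_checkpoint(mod, length(mod$checkpoints))
  expect_identical(deltasphere:::net_params(restored$layers),
                   deltasphere:::net_params(mod$layers))
})
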