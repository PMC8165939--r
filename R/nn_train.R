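#' Classifier training configuration
#'
#' @param backbone `"small_cnn"` (default, desk scale) or `"resnet18_like"`.
#' @param learning_rate ADAM step size.
#' @param batch_size images per step.
#' @param epochs passes over the training set.
#' @param checkpoint_every store a weight snapshot every this many steps
#'   (`Inf` keeps only the final weights).
#' @param flip,rotate,random_crop training-time augmentation switches.
#' @param seed seeds weight initialization, shuffling and augmentation.
#' @return A `model_config` list.
#' @export
model_config <- function(backbone = c("small_cnn", "resnet18_like"),
                         learning_rate = 1e-2, batch_size = 32L,
                         epochs = 10L, checkpoint_every = Inf,
                         flip = TRUE, rotate = TRUE, random_crop = TRUE,
                         seed = 1L) {
  list(backbone = match.arg(backbone), learning_rate = learning_rate,
       batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       checkpoint_every = checkpoint_every, flip = flip, rotate = rotate,
       random_crop = random_crop, seed = as.integer(seed))
}

#' Train the binary phenotype classifier
#'
#' Minimizes mean cross-entropy of the softmax output against the two
#' condition bins with the ADAM optimizer. Fully seeded: weight
#' initialization, epoch shuffling and augmentation draws all come from
#' `config$seed`, so two runs with the same seed produce identical weights.
#' Weight snapshots are stored every `checkpoint_every` steps.
#'
#' @param dataset training crop dataset (see [split_by_well()]); must
#'   contain both classes.
#' @param config a [model_config()].
#' @param verbose print per-epoch mean loss.
#' @return A `spheroid_classifier`: layers, class levels, the wells trained
#'   on (consulted by [evaluate_classifier()] to enforce the anti-leakage
#'   rule), checkpoints and the loss history.
#' @export
train_classifier <- function(dataset, config = model_config(),
                             verbose = FALSE) {
  classes <- sort(unique(dataset$condition))
  if (length(classes) != 2L)
    stop("training set must contain exactly 2 classes, got ",
         length(classes))
  labels <- match(dataset$condition, classes)
  n <- length(labels)
  set.seed(config$seed)
  layers <- build_network(config$backbone, n_classes = 2L)
  state <- adam_init(net_params(layers))
  checkpoints <- list()
  losses <- numeric(0)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      sel <- perm[start:min(start + config$batch_size - 1L, n)]
      xb <- dataset$x[, , , sel, drop = FALSE]
      if (config$flip || config$rotate || config$random_crop)
        for (j in seq_along(sel))
          xb[, , 1L, j] <- augment_image(xb[, , 1L, j],
                                         flip = config$flip,
                                         rotate = config$rotate,
                                         random_crop = config$random_crop)
      fw <- net_forward(layers, xb, train = TRUE)
      layers <- fw$layers   # batch-norm running statistics advance
      ce <- cross_entropy(fw$out, labels[sel])
      bw <- net_backward(layers, fw$caches, ce$grad)
      upd <- adam_step(net_params(layers), bw$grads, state,
                       lr = config$learning_rate)
      layers <- net_set_params(layers, upd$params)
      state <- upd$state
      step <- step + 1L
      epoch_loss <- epoch_loss + ce$loss; nb <- nb + 1L
      if (is.finite(config$checkpoint_every) &&
          step %% config$checkpoint_every == 0L)
        checkpoints[[length(checkpoints) + 1L]] <-
          list(step = step, layers = layers)
    }
    losses <- c(losses, epoch_loss / nb)
    if (verbose)
      message(sprintf("epoch %d/%d: mean loss %.4f", epoch, config$epochs,
                      losses[epoch]))
  }
  ## final pass: replace the lagging exponential running averages with exact
  ## batch-statistic means so evaluation mode matches the trained weights
  layers <- bn_recalibrate(layers, dataset$x, config$batch_size)
  checkpoints[[length(checkpoints) + 1L]] <-
    list(step = step, layers = layers)
  structure(list(layers = layers, classes = classes, config = config,
                 train_wells = sort(unique(dataset$well)),
                 checkpoints = checkpoints, loss_history = losses),
            class = "spheroid_classifier")
}

#' @export
print.spheroid_classifier <- function(x, ...) {
  cat(sprintf("spheroid_classifier (%s): classes %s; %d training wells; %d checkpoints\n",
              x$config$backbone, paste(x$classes, collapse = " vs "),
              length(x$train_wells), length(x$checkpoints)))
  invisible(x)
}

predict_probs <- function(model, x, batch_size = 64L) {
  n <- dim(x)[4L]
  probs <- matrix(NA_real_, 2L, n)
  for (start in seq(1L, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, n)
    out <- net_forward(model$layers, x[, , , sel, drop = FALSE],
                       train = FALSE)$out
    probs[, sel] <- softmax_cols(out)
  }
  probs
}

#' Evaluate the classifier on held-out wells
#'
#' Applies the model without augmentation, checks (not assumes) that no
#' evaluation well was seen in training — temporally adjacent frames of the
#' same spheroid are near-duplicates, so any overlap would leak — and
#' reports per-image softmax probabilities, per-timepoint accuracy over the
#' held-out wells, and its 10-timepoint rolling mean (the accuracy-vs-time
#' readout).
#'
#' @param model a `spheroid_classifier`.
#' @param dataset evaluation crop dataset.
#' @param phenotypes optional named map from condition label to phenotype
#'   name used for probability column names (default maps `E8` to round and
#'   `KSR_BMP4` to branched when applicable).
#' @param window rolling-mean window in timepoints.
#' @return list with `predictions` (data.frame: well, timepoint,
#'   p_<class> columns, predicted, actual, correct) and `accuracy_curve`
#'   (data.frame: timepoint, accuracy, rolling_accuracy, n).
#' @export
evaluate_classifier <- function(model, dataset,
                                phenotypes = c(E8 = "round",
                                               KSR_BMP4 = "branched"),
                                window = 10L) {
  stopifnot(inherits(model, "spheroid_classifier"))
  overlap <- intersect(model$train_wells, unique(dataset$well))
  if (length(overlap))
    stop("evaluation wells overlap training wells (leakage): ",
         paste(overlap, collapse = ", "))
  probs <- predict_probs(model, dataset$x)
  predicted <- model$classes[apply(probs, 2L, which.max)]
  pname <- if (all(model$classes %in% names(phenotypes)))
    paste0("p_", unname(phenotypes[model$classes]))
  else paste0("p_", model$classes)
  predictions <- data.frame(well = dataset$well,
                            timepoint = dataset$timepoint,
                            stringsAsFactors = FALSE)
  predictions[[pname[1L]]] <- probs[1L, ]
  predictions[[pname[2L]]] <- probs[2L, ]
  predictions$predicted <- predicted
  predictions$actual <- dataset$condition
  predictions$correct <- predicted == dataset$condition
  tps <- sort(unique(predictions$timepoint))
  acc <- vapply(tps, function(tp) {
    mean(predictions$correct[predictions$timepoint == tp])
  }, numeric(1))
  nrec <- vapply(tps, function(tp) sum(predictions$timepoint == tp),
                 integer(1))
  curve <- data.frame(timepoint = tps, accuracy = acc,
                      rolling_accuracy = rolling_mean(acc, window),
                      n = nrec)
  list(predictions = predictions, accuracy_curve = curve)
}

#' Restore a stored checkpoint into a classifier
#'
#' @param model a `spheroid_classifier`.
#' @param checkpoint index into `model$checkpoints`.
#' @return The classifier with that checkpoint's weights.
#' @export
load_checkpoint <- function(model, checkpoint) {
  model$layers <- model$checkpoints[[checkpoint]]$layers
  model
}
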