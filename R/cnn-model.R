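#' CNN hyperparameters under optimization
#'
#' The four tunable hyperparameters of the classifier and their search
#' bounds: convolution filter size in \{3, 5, 7\} (shared by all three
#' convolutional layers), SGD learning rate in `[1e-3, 1]` (log scale),
#' SGD momentum in `[0.9, 0.98]`, and L2 weight-penalty coefficient in
#' `[1e-10, 1e-2]` (log scale).
#'
#' @param filter_size odd kernel side, one of 3, 5, 7.
#' @param learning_rate SGD step size.
#' @param momentum SGD momentum coefficient.
#' @param l2 L2 penalty coefficient (added to the loss as
#'   `l2 * sum(weights^2)`).
#' @return A `cnn_hyperparams` list.
#' @export
cnn_hyperparams <- function(filter_size = 5, learning_rate = 0.01,
                            momentum = 0.9, l2 = 1e-6) {
  if (!filter_size %in% c(3, 5, 7)) stop("`filter_size` must be 3, 5 or 7")
  if (learning_rate < 1e-3 || learning_rate > 1)
    stop("`learning_rate` must lie in [1e-3, 1]")
  if (momentum < 0.9 || momentum > 0.98)
    stop("`momentum` must lie in [0.9, 0.98]")
  if (l2 < 1e-10 || l2 > 1e-2) stop("`l2` must lie in [1e-10, 1e-2]")
  structure(list(filter_size = as.integer(filter_size),
                 learning_rate = learning_rate, momentum = momentum, l2 = l2),
            class = "cnn_hyperparams")
}

#' Fixed architecture configuration of the classifier
#'
#' The network skeleton is fixed: three `conv('same', k) -> ReLU ->
#' maxpool(2, stride 2)` stages with a shared kernel size, dropout on the
#' last convolutional layer, then a dense 2-way softmax. Only kernel
#' size, learning rate, momentum and L2 are tuned ([cnn_hyperparams()]);
#' everything here is a fixed (but configurable) default.
#'
#' @param input_side image side length; must be at least 8 so the grid
#'   survives three stride-2 poolings.
#' @param channels 1 (grayscale) or 3 (color).
#' @param conv_filters filter counts of the three conv layers.
#' @param dropout dropout probability applied to the last conv layer's
#'   activations during training.
#' @param batch_size SGD minibatch size.
#' @param max_epochs training epoch cap (60 by default).
#' @param patience early-stopping patience: training stops after this
#'   many epochs without a new best validation accuracy. Set to
#'   `max_epochs` to disable.
#' @param seed seed for weight initialization, shuffling and dropout.
#' @return A `cnn_config` list with derived per-stage spatial sizes in
#'   `$sides` (sizes entering each conv stage) and `$final_side`.
#' @export
cnn_config <- function(input_side, channels, conv_filters = c(32, 64, 128),
                       dropout = 0.5, batch_size = 128, max_epochs = 60,
                       patience = 10, seed = 1L) {
  if (input_side < 8)
    stop("`input_side` must be >= 8 to survive three stride-2 poolings")
  if (!channels %in% c(1, 3)) stop("`channels` must be 1 or 3")
  if (length(conv_filters) != 3) stop("`conv_filters` must have 3 entries")
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)")
  if (max_epochs < 1 || max_epochs > 60)
    stop("`max_epochs` must be in 1..60")
  sides <- integer(4)
  sides[1] <- as.integer(input_side)
  for (i in 2:4) sides[i] <- sides[i - 1] %/% 2L
  structure(list(input_side = as.integer(input_side),
                 channels = as.integer(channels),
                 conv_filters = as.integer(conv_filters),
                 dropout = dropout, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 sides = sides, final_side = sides[4]),
            class = "cnn_config")
}

#' Stratified train/validation/test split
#'
#' Splits sample indices into disjoint, exhaustive partitions with the
#' requested ratios, stratified by label so each partition keeps the
#' class balance (within rounding), reproducibly under `seed`.
#'
#' @param labels factor/character of class labels.
#' @param ratios length-3 positive weights for train/val/test; default
#'   the classic 6:2:2.
#' @param seed integer seed.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(labels, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  ratios <- ratios / sum(ratios)
  labels <- as.factor(labels)
  set.seed(seed)
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    n <- length(idx)
    base <- floor(n * ratios)
    rem <- n - sum(base)
    if (rem > 0) {
      frac <- n * ratios - base
      base[order(-frac, seq_along(frac))[seq_len(rem)]] <-
        base[order(-frac, seq_along(frac))[seq_len(rem)]] + 1L
    }
    if (any(base < 1))
      stop("too few '", lv, "' samples (", n, ") for a ",
           paste(round(ratios, 2), collapse = ":"), " split")
    cuts <- cumsum(base)
    parts$train <- c(parts$train, idx[seq_len(cuts[1])])
    parts$val <- c(parts$val, idx[(cuts[1] + 1):cuts[2]])
    parts$test <- c(parts$test, idx[(cuts[2] + 1):cuts[3]])
  }
  lapply(parts, sort)
}

#' Classification metrics from a confusion matrix
#'
#' The positive class is `case`. Precision, recall and F1 are defined as
#' 0 (with a warning) when their denominator is 0.
#'
#' @param truth,predicted factors/characters of `"case"`/`"control"`.
#' @return A `cnn_metrics` list: `accuracy`, `recall`, `precision`, `f1`,
#'   and counts `tp`, `fp`, `fn`, `tn`.
#' @export
eval_metrics <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted), length(truth) > 0)
  tp <- sum(predicted == "case" & truth == "case")
  fp <- sum(predicted == "case" & truth == "control")
  fn <- sum(predicted == "control" & truth == "case")
  tn <- sum(predicted == "control" & truth == "control")
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (0 denominator); reporting 0"); 0 }
    else num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("f1 undefined (0 denominator); reporting 0"); 0
  } else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = (tp + tn) / length(truth),
                 recall = recall, precision = precision, f1 = f1,
                 tp = tp, fp = fp, fn = fn, tn = tn),
            class = "cnn_metrics")
}

#' @export
print.cnn_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f  recall %.4f  precision %.4f  F1 %.4f\n",
              x$accuracy, x$recall, x$precision, x$f1))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

# derived dimensions shared by forward/backward
cnn_dims <- function(config) {
  list(sides = config$sides,
       chans = c(config$channels, config$conv_filters))
}

#' Build an untrained CNN
#'
#' Initializes the fixed three-stage architecture with He-normal weights
#' under `config$seed`.
#'
#' @param config a [cnn_config()].
#' @param hp a [cnn_hyperparams()].
#' @return An untrained `geno_cnn` object.
#' @export
cnn_build <- function(config, hp = cnn_hyperparams()) {
  stopifnot(inherits(config, "cnn_config"), inherits(hp, "cnn_hyperparams"))
  if (config$final_side < 1)
    stop("input side ", config$input_side, " too small: collapses to 0 after pooling")
  dims <- cnn_dims(config)
  k <- hp$filter_size
  set.seed(config$seed)
  Wc <- vector("list", 3); bc <- vector("list", 3)
  for (i in 1:3) {
    fan_in <- k * k * dims$chans[i]
    Wc[[i]] <- matrix(rnorm(dims$chans[i + 1] * fan_in, 0, sqrt(2 / fan_in)),
                      dims$chans[i + 1], fan_in)
    bc[[i]] <- rep(0, dims$chans[i + 1])
  }
  d_flat <- config$final_side^2 * dims$chans[4]
  Wd <- matrix(rnorm(2 * d_flat, 0, sqrt(2 / d_flat)), 2, d_flat)
  bd <- rep(0, 2)
  structure(list(weights = list(Wc = Wc, bc = bc, Wd = Wd, bd = bd),
                 dims = dims, hp = hp, config = config,
                 levels = c("control", "case"),
                 trained = FALSE, history = NULL, best_epoch = NA_integer_),
            class = "geno_cnn")
}

#' @export
print.geno_cnn <- function(x, ...) {
  cfg <- x$config; hp <- x$hp
  cat("Genotype-image CNN (", if (x$trained) "trained" else "untrained", ")\n",
      sep = "")
  cat(sprintf("  input %d x %d x %d; conv filters %s (k = %d); dropout %.2f\n",
              cfg$input_side, cfg$input_side, cfg$channels,
              paste(cfg$conv_filters, collapse = "/"), hp$filter_size,
              cfg$dropout))
  cat(sprintf("  SGD lr %.4g, momentum %.3f, L2 %.3g, batch %d, max %d epochs\n",
              hp$learning_rate, hp$momentum, hp$l2, cfg$batch_size,
              cfg$max_epochs))
  if (x$trained) {
    cat(sprintf("  best epoch %d: validation accuracy %.4f\n", x$best_epoch,
                max(x$history$val_accuracy)))
    if (!is.null(x$metrics))
      cat(sprintf("  test accuracy %.4f (F1 %.4f)\n",
                  x$metrics$accuracy, x$metrics$f1))
  }
  invisible(x)
}

#' @export
summary.geno_cnn <- function(object, ...) {
  print(object)
  if (object$trained) {
    cat("\nTraining history (last 5 epochs):\n")
    print(tail(object$history, 5), row.names = FALSE)
    if (!is.null(object$metrics)) { cat("\nTest metrics:\n"); print(object$metrics) }
  }
  invisible(object)
}

#' @export
coef.geno_cnn <- function(object, ...) object$weights

#' @export
plot.geno_cnn <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::plot(h$epoch, h$val_accuracy, type = "b", pch = 16,
                 xlab = "epoch", ylab = "validation accuracy",
                 ylim = range(c(h$val_accuracy, 0.5, 1)), ...)
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey50")
  invisible(x)
}
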