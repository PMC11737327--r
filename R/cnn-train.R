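# Forward pass over a batch. X is a raw 0..255 pixel matrix (D x N) in the
# package's column-major image layout; scaling by 1/255 happens here, at the
# model boundary. Returns softmax probabilities plus the caches the backward
# pass (and Grad-CAM) need.
cnn_forward <- function(model, X, train = FALSE) {
  w <- model$weights; dims <- model$dims
  cfg <- model$config; k <- model$hp$filter_size
  A <- X / 255
  N <- ncol(A)
  caches <- vector("list", 3)
  for (i in 1:3) {
    s <- dims$sides[i]; Fo <- dims$chans[i + 1]
    colm <- im2col_same(A, s, s, dims$chans[i], k)
    Z <- w$Wc[[i]] %*% colm + w$bc[[i]]
    P <- s * s
    dim(Z) <- c(Fo, P, N); Z <- aperm(Z, c(2, 1, 3)); dim(Z) <- c(P * Fo, N)
    relu <- Z > 0
    A <- Z * relu
    drop <- NULL
    if (i == 3 && train && cfg$dropout > 0) {
      drop <- (matrix(runif(length(A)), nrow(A)) >= cfg$dropout) /
        (1 - cfg$dropout)
      A <- A * drop
    }
    A3 <- if (i == 3) A else NULL
    mp <- maxpool2(A, s, s, Fo)
    caches[[i]] <- list(colm = colm, relu = relu, drop = drop,
                        argmax = mp$argmax, act = A3)
    A <- mp$out
  }
  logits <- w$Wd %*% A + w$bd
  mx <- pmax(logits[1, ], logits[2, ])
  el <- exp(logits - rep(mx, each = 2))
  p <- el / rep(colSums(el), each = 2)
  list(p = p, flat = A, caches = caches)
}

# Backward pass: gradients of mean cross-entropy + L2 penalty.
# y_idx: 1 = control, 2 = case.
cnn_backward <- function(model, fwd, y_idx) {
  w <- model$weights; dims <- model$dims
  k <- model$hp$filter_size; l2 <- model$hp$l2
  N <- length(y_idx)
  G <- fwd$p
  G[cbind(y_idx, seq_len(N))] <- G[cbind(y_idx, seq_len(N))] - 1
  G <- G / N
  gWd <- G %*% t(fwd$flat) + 2 * l2 * w$Wd
  gbd <- rowSums(G)
  gWc <- vector("list", 3); gbc <- vector("list", 3)
  dA <- t(w$Wd) %*% G
  for (i in 3:1) {
    s <- dims$sides[i]; Fo <- dims$chans[i + 1]
    ca <- fwd$caches[[i]]
    dPre <- maxpool2_backward(dA, ca$argmax, s, s, Fo)
    if (!is.null(ca$drop)) dPre <- dPre * ca$drop
    dZ <- dPre * ca$relu
    P <- s * s
    dim(dZ) <- c(P, Fo, N); dZ <- aperm(dZ, c(2, 1, 3)); dim(dZ) <- c(Fo, P * N)
    gWc[[i]] <- dZ %*% t(ca$colm) + 2 * l2 * w$Wc[[i]]
    gbc[[i]] <- rowSums(dZ)
    if (i > 1) {
      dcol <- crossprod(w$Wc[[i]], dZ)
      dA <- col2im_same(dcol, s, s, dims$chans[i], k, N)
    }
  }
  list(Wc = gWc, bc = gbc, Wd = gWd, bd = gbd)
}

cnn_loss <- function(model, p, y_idx) {
  w <- model$weights
  ce <- -mean(log(pmax(p[cbind(y_idx, seq_along(y_idx))], 1e-300)))
  pen <- model$hp$l2 *
    (sum(vapply(w$Wc, function(m) sum(m^2), numeric(1))) + sum(w$Wd^2))
  ce + pen
}

# Raw class probabilities in evaluation batches.
cnn_probs <- function(model, X) {
  bs <- model$config$batch_size
  n <- ncol(X)
  p <- matrix(NA_real_, 2, n)
  for (start in seq(1, n, by = bs)) {
    idx <- start:min(start + bs - 1, n)
    p[, idx] <- cnn_forward(model, X[, idx, drop = FALSE])$p
  }
  p
}

as_pixel_matrix <- function(x) {
  if (inherits(x, "genotype_image_set")) x$x
  else if (inherits(x, "genotype_image")) matrix(as.numeric(x$pixels), ncol = 1)
  else if (is.matrix(x)) x
  else matrix(x, ncol = 1)
}

#' Train the CNN with momentum SGD
#'
#' Minimizes 2-class cross-entropy plus the L2 weight penalty by
#' minibatch SGD with momentum, tracking validation accuracy each epoch
#' and returning the weight snapshot of the best validation epoch.
#' Training stops at `config$max_epochs` or when validation accuracy has
#' not improved for `config$patience` epochs. A non-finite training loss
#' aborts with a condition of class `cnn_divergence` (the Bayesian
#' optimizer reports such trials as failed rather than fatal).
#'
#' @param model an untrained [cnn_build()] model.
#' @param x_train,x_val pixel matrices (`(side^2*channels) x n`, 0..255)
#'   or `genotype_image_set`s.
#' @param y_train,y_val labels (`"case"`/`"control"`); taken from the
#'   image sets when omitted.
#' @param verbose print per-epoch progress.
#' @return The trained `geno_cnn`: best-epoch weights, `$history`
#'   (`epoch`, `loss`, `val_accuracy`) and `$best_epoch`.
#' @export
cnn_train <- function(model, x_train, y_train = NULL, x_val, y_val = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(model, "geno_cnn"))
  if (is.null(y_train) && inherits(x_train, "genotype_image_set"))
    y_train <- x_train$labels
  if (is.null(y_val) && inherits(x_val, "genotype_image_set"))
    y_val <- x_val$labels
  Xtr <- as_pixel_matrix(x_train); Xva <- as_pixel_matrix(x_val)
  if (ncol(Xtr) == 0 || ncol(Xva) == 0)
    stop("training and validation sets must be non-empty")
  ytr <- match(as.character(y_train), model$levels)
  yva <- match(as.character(y_val), model$levels)
  stopifnot(!anyNA(ytr), !anyNA(yva))
  cfg <- model$config; hp <- model$hp
  set.seed(cfg$seed + 1L)
  vel <- rapply(model$weights, function(x) x * 0, how = "replace")
  n <- ncol(Xtr)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_accuracy = numeric(0))
  best <- list(acc = -Inf, weights = model$weights, epoch = NA_integer_)
  since_best <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      fwd <- cnn_forward(model, Xtr[, idx, drop = FALSE], train = TRUE)
      loss <- cnn_loss(model, fwd$p, ytr[idx])
      if (!is.finite(loss)) {
        stop(errorCondition(
          sprintf("training diverged (non-finite loss at epoch %d)", epoch),
          class = c("cnn_divergence", "error", "condition")))
      }
      losses <- c(losses, loss)
      gr <- cnn_backward(model, fwd, ytr[idx])
      for (i in 1:3) {
        vel$Wc[[i]] <- hp$momentum * vel$Wc[[i]] - hp$learning_rate * gr$Wc[[i]]
        model$weights$Wc[[i]] <- model$weights$Wc[[i]] + vel$Wc[[i]]
        vel$bc[[i]] <- hp$momentum * vel$bc[[i]] - hp$learning_rate * gr$bc[[i]]
        model$weights$bc[[i]] <- model$weights$bc[[i]] + vel$bc[[i]]
      }
      vel$Wd <- hp$momentum * vel$Wd - hp$learning_rate * gr$Wd
      model$weights$Wd <- model$weights$Wd + vel$Wd
      vel$bd <- hp$momentum * vel$bd - hp$learning_rate * gr$bd
      model$weights$bd <- model$weights$bd + vel$bd
    }
    pva <- cnn_probs(model, Xva)
    acc <- mean((apply(pva, 2, which.max)) == yva)
    hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                   val_accuracy = acc))
    if (verbose)
      message(sprintf("epoch %2d: loss %.4f, val accuracy %.4f",
                      epoch, mean(losses), acc))
    if (acc > best$acc) {
      best <- list(acc = acc, weights = model$weights, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$patience) break
    }
  }
  model$weights <- best$weights
  model$history <- hist
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model
}

#' Predict case/control status for new images
#'
#' @param object a trained `geno_cnn`.
#' @param newdata a `genotype_image_set`, single `genotype_image`, or
#'   pixel matrix (0..255).
#' @param type `"class"` for predicted labels, `"prob"` for a 2-column
#'   matrix of class probabilities.
#' @param ... unused.
#' @return Factor of predicted labels, or a probability matrix.
#' @export
predict.geno_cnn <- function(object, newdata,
                             type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_pixel_matrix(newdata)
  p <- cnn_probs(object, X)
  if (type == "prob") {
    out <- t(p); colnames(out) <- object$levels
    return(out)
  }
  factor(object$levels[apply(p, 2, which.max)], levels = object$levels)
}

#' Evaluate a trained CNN on a test set
#'
#' @param model a trained `geno_cnn`.
#' @param x_test images; `y_test` defaults to the set's labels.
#' @param y_test true labels.
#' @return [eval_metrics()] of the predictions.
#' @export
cnn_evaluate <- function(model, x_test, y_test = NULL) {
  if (is.null(y_test) && inherits(x_test, "genotype_image_set"))
    y_test <- x_test$labels
  X <- as_pixel_matrix(x_test)
  if (ncol(X) == 0) stop("test set must be non-empty")
  pred <- predict(model, X)
  eval_metrics(y_test, pred)
}

#' Fit the genotype-image CNN classifier
#'
#' The one-stop fitting interface: stratified 6:2:2
#' train/validation/test split, architecture construction, momentum-SGD
#' training with best-validation-epoch selection, and test-set
#' evaluation — returning a single fitted-model object.
#'
#' @param images a `genotype_image_set` (from [encode_dataset()] or
#'   [read_image_set()]).
#' @param hp a [cnn_hyperparams()].
#' @param config a [cnn_config()]; defaults to the standard architecture
#'   sized from `images`.
#' @param split length-3 train/val/test ratios.
#' @param seed seed controlling the split and (through `config`) weights,
#'   shuffling and dropout.
#' @param verbose print training progress.
#' @return A trained `geno_cnn` with `$metrics` (test-set
#'   [eval_metrics()]) and `$split` (the index partition).
#' @examples
#' d <- simulate_genotypes(simulation_spec(
#'   n_cases = 60, n_controls = 60, n_null_snps = 50, n_risk_snps = 14,
#'   rr_het = 3, seed = 7))
#' imgs <- encode_dataset(d, "cc")
#' fit <- geno_cnn(imgs, config = cnn_config(imgs$side, imgs$channels,
#'   conv_filters = c(4, 8, 8), batch_size = 16, max_epochs = 3, seed = 7))
#' fit$metrics$accuracy
#' @export
geno_cnn <- function(images, hp = cnn_hyperparams(), config = NULL,
                     split = c(0.6, 0.2, 0.2), seed = 1L, verbose = FALSE) {
  stopifnot(inherits(images, "genotype_image_set"))
  if (is.null(config))
    config <- cnn_config(images$side, images$channels, seed = seed)
  idx <- split_dataset(images$labels, split, seed = seed)
  model <- cnn_build(config, hp)
  model <- cnn_train(model,
                     images$x[, idx$train, drop = FALSE],
                     images$labels[idx$train],
                     images$x[, idx$val, drop = FALSE],
                     images$labels[idx$val],
                     verbose = verbose)
  model$metrics <- cnn_evaluate(model, images$x[, idx$test, drop = FALSE],
                                images$labels[idx$test])
  model$split <- idx
  model
}
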