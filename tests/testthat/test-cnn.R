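test_that("stratified splits are disjoint, exhaustive and balanced", {
  labels <- rep(c("case", "control"), each = 4000)
  idx <- split_dataset(labels, seed = 1)
  expect_identical(lengths(idx), c(train = 4800L, val = 1600L, test = 1600L))
  all_idx <- sort(unname(unlist(idx)))
  expect_identical(all_idx, seq_along(labels))
  for (part in idx)
    expect_identical(sum(labels[part] == "case"), length(part) %/% 2L)

  # reproducible under the seed
  expect_identical(split_dataset(labels, seed = 7), split_dataset(labels, seed = 7))
  expect_false(identical(split_dataset(labels, seed = 7),
                         split_dataset(labels, seed = 8)))

  # 10 samples (5/5) split 6:2:2 with classes balanced
  small <- split_dataset(rep(c("case", "control"), 5), seed = 2)
  expect_identical(lengths(small), c(train = 6L, val = 2L, test = 2L))
  expect_error(split_dataset(rep(c("case", "control"), 2)), "too few")
})

test_that("architecture spatial sizes follow the three stride-2 poolings", {
  cfg <- cnn_config(45, 3)
  expect_identical(cfg$sides, c(45L, 22L, 11L, 5L))
  expect_identical(cfg$final_side, 5L)
  # grayscale input builds too
  m <- cnn_build(cnn_config(45, 1), cnn_hyperparams(5))
  expect_identical(dim(m$weights$Wc[[1]]), c(32L, 25L))
  expect_error(cnn_config(7, 3), ">= 8")

  # parameter count changes with filter_size only in the conv kernels
  m3 <- cnn_build(cnn_config(16, 3), cnn_hyperparams(3))
  m7 <- cnn_build(cnn_config(16, 3), cnn_hyperparams(7))
  expect_identical(dim(m3$weights$Wd), dim(m7$weights$Wd))
  expect_identical(ncol(m7$weights$Wc[[1]]) / ncol(m3$weights$Wc[[1]]),
                   49 / 9)
})

test_that("hyperparameters are validated against the search bounds", {
  expect_error(cnn_hyperparams(filter_size = 4), "3, 5 or 7")
  expect_error(cnn_hyperparams(learning_rate = 2), "1e-3")
  expect_error(cnn_hyperparams(momentum = 0.5), "momentum")
  expect_error(cnn_hyperparams(l2 = 1), "l2")
})

test_that("metrics match hand-computed values and handle degenerate cases", {
  truth <- rep(c("case", "control"), c(45, 55))
  pred <- c(rep("case", 40), rep("control", 5),    # TP 40, FN 5
            rep("case", 10), rep("control", 45))   # FP 10, TN 45
  m <- eval_metrics(truth, pred)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 40 / 45)
  expect_equal(m$f1, 2 * (0.8 * 40 / 45) / (0.8 + 40 / 45))
  expect_identical(c(m$tp, m$fp, m$fn, m$tn), c(40L, 10L, 5L, 45L))

  perfect <- eval_metrics(truth, truth)
  expect_equal(unlist(perfect[c("accuracy", "recall", "precision", "f1")]),
               c(accuracy = 1, recall = 1, precision = 1, f1 = 1))

  ws <- capture_warnings(z <- eval_metrics(rep("control", 5),
                                           rep("control", 5)))
  expect_length(ws, 3)  # precision, recall and f1 all degenerate
  expect_match(ws, "undefined", all = TRUE)
  expect_equal(z$precision, 0)
})

test_that("metrics agree with a brute-force confusion oracle", {
  set.seed(13)
  for (i in 1:100) {
    truth <- sample(c("case", "control"), 30, replace = TRUE)
    pred <- sample(c("case", "control"), 30, replace = TRUE)
    if (!any(pred == "case") || !any(truth == "case")) next
    m <- eval_metrics(truth, pred)
    tp <- sum(truth == "case" & pred == "case")
    fp <- sum(truth == "control" & pred == "case")
    fn <- sum(truth == "case" & pred == "control")
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    expect_equal(m$accuracy, mean(truth == pred), tolerance = 1e-12)
    expect_equal(m$precision, prec, tolerance = 1e-12)
    expect_equal(m$recall, rec, tolerance = 1e-12)
    if (prec + rec > 0)
      expect_equal(m$f1, 2 * prec * rec / (prec + rec), tolerance = 1e-12)
  }
})

test_that("backpropagation matches numerical gradients", {
  set.seed(42)
  cfg <- cnn_config(8, 3, conv_filters = c(2, 3, 4), dropout = 0,
                    batch_size = 4, seed = 9)
  hp <- cnn_hyperparams(3, 0.01, 0.9, 1e-4)
  m <- cnn_build(cfg, hp)
  X <- matrix(runif(8 * 8 * 3 * 4, 0, 255), ncol = 4)
  y <- c(1L, 2L, 1L, 2L)
  fwd <- gwascnn:::cnn_forward(m, X)
  gr <- gwascnn:::cnn_backward(m, fwd, y)
  loss_at <- function(mm) {
    f <- gwascnn:::cnn_forward(mm, X)
    gwascnn:::cnn_loss(mm, f$p, y)
  }
  eps <- 1e-5
  check <- function(getter, setter, grad, n_probe = 4) {
    w0 <- getter(m)
    for (i in sample(length(w0), n_probe)) {
      mp <- m; mq <- m
      wp <- getter(mp); wp[i] <- wp[i] + eps; mp <- setter(mp, wp)
      wq <- getter(mq); wq[i] <- wq[i] - eps; mq <- setter(mq, wq)
      num <- (loss_at(mp) - loss_at(mq)) / (2 * eps)
      expect_equal(grad[i], num, tolerance = 1e-4)
    }
  }
  for (l in 1:3) {
    check(function(mm) mm$weights$Wc[[l]],
          function(mm, w) { mm$weights$Wc[[l]][] <- w; mm }, gr$Wc[[l]])
    check(function(mm) mm$weights$bc[[l]],
          function(mm, w) { mm$weights$bc[[l]][] <- w; mm }, gr$bc[[l]], 2)
  }
  check(function(mm) mm$weights$Wd,
        function(mm, w) { mm$weights$Wd[] <- w; mm }, gr$Wd)
  check(function(mm) mm$weights$bd,
        function(mm, w) { mm$weights$bd[] <- w; mm }, gr$bd, 2)
})

test_that("a separable toy problem reaches perfect validation accuracy", {
  fit <- local_separable_fit()$fit
  expect_equal(max(fit$history$val_accuracy), 1)
  expect_equal(fit$metrics$accuracy, 1)
  # best-epoch selection is monotone in the tracked metric
  expect_gte(max(fit$history$val_accuracy), fit$history$val_accuracy[1])
})

test_that("training under permuted labels stays at chance on the test set", {
  set.seed(17)
  n <- 120
  codes <- matrix(sample(0:2, n * 64, replace = TRUE), n, 64)
  d <- genotype_dataset(codes, sample(rep(c("case", "control"), n / 2)))
  imgs <- encode_dataset(d, "cc")
  fit <- suppressWarnings(
    geno_cnn(imgs, hp = cnn_hyperparams(3, 0.01, 0.9, 1e-6),
             config = cnn_config(8, 3, conv_filters = c(2, 3, 4),
                                 batch_size = 16, max_epochs = 8,
                                 patience = 8, seed = 17),
             seed = 17))
  n_test <- with(fit$metrics, tp + fp + fn + tn)
  expect_lt(abs(fit$metrics$accuracy - 0.5), 3 * sqrt(0.25 / n_test) + 1e-9)
})

test_that("training is reproducible under a fixed seed", {
  run <- function() {
    set.seed(23)
    codes <- rbind(matrix(rbinom(20 * 64, 2, 0.2), 20, 64),
                   matrix(rbinom(20 * 64, 2, 0.5), 20, 64))
    d <- genotype_dataset(codes, rep(c("control", "case"), each = 20))
    imgs <- encode_dataset(d, "cc")
    suppressWarnings(
      geno_cnn(imgs, hp = cnn_hyperparams(3, 0.01, 0.9, 1e-6),
               config = cnn_config(8, 3, conv_filters = c(2, 2, 2),
                                   batch_size = 8, max_epochs = 3,
                                   patience = 3, seed = 23),
               seed = 23))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
})

test_that("evaluation is invariant to sample order", {
  sep <- local_separable_fit()
  idx <- sep$fit$split$test
  x <- sep$imgs$x[, idx, drop = FALSE]
  y <- sep$imgs$labels[idx]
  perm <- sample(length(idx))
  m1 <- cnn_evaluate(sep$fit, x, y)
  m2 <- cnn_evaluate(sep$fit, x[, perm, drop = FALSE], y[perm])
  expect_identical(m1, m2)
})

test_that("predict returns aligned classes and probabilities", {
  sep <- local_separable_fit()
  x <- sep$imgs$x[, 1:4, drop = FALSE]
  pr <- predict(sep$fit, x, type = "prob")
  cl <- predict(sep$fit, x)
  expect_identical(colnames(pr), c("control", "case"))
  expect_equal(rowSums(pr), rep(1, 4), tolerance = 1e-12)
  expect_identical(as.character(cl),
                   colnames(pr)[apply(pr, 1, which.max)])
})
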