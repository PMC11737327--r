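#' Hyperparameter search space
#'
#' The default box: filter size in \{3, 5, 7\} (categorical), learning
#' rate log-uniform on `[1e-3, 1]`, momentum uniform on `[0.9, 0.98]`,
#' L2 log-uniform on `[1e-10, 1e-2]`.
#'
#' @param filter_sizes candidate kernel sides.
#' @param lr_range,l2_range ranges (searched on log10 scale).
#' @param momentum_range range (searched linearly).
#' @return An `hp_space` list.
#' @export
hp_space <- function(filter_sizes = c(3, 5, 7), lr_range = c(1e-3, 1),
                     momentum_range = c(0.9, 0.98),
                     l2_range = c(1e-10, 1e-2)) {
  structure(list(filter_sizes = filter_sizes,
                 lr_log10 = log10(lr_range),
                 momentum = momentum_range,
                 l2_log10 = log10(l2_range)),
            class = "hp_space")
}

# unit-cube coordinates <-> hyperparameters
hp_from_unit <- function(u, space) {
  nf <- length(space$filter_sizes)
  lev <- pmin(nf, pmax(1, round(u[1] * (nf - 1)) + 1))
  cnn_hyperparams(
    filter_size = space$filter_sizes[lev],
    learning_rate = 10^(space$lr_log10[1] + u[2] * diff(space$lr_log10)),
    momentum = space$momentum[1] + u[3] * diff(space$momentum),
    l2 = 10^(space$l2_log10[1] + u[4] * diff(space$l2_log10)))
}

hp_to_unit <- function(hp, space) {
  nf <- length(space$filter_sizes)
  c((match(hp$filter_size, space$filter_sizes) - 1) / (nf - 1),
    (log10(hp$learning_rate) - space$lr_log10[1]) / diff(space$lr_log10),
    (hp$momentum - space$momentum[1]) / diff(space$momentum),
    (log10(hp$l2) - space$l2_log10[1]) / diff(space$l2_log10))
}

snap_unit <- function(u, space) {
  nf <- length(space$filter_sizes)
  u[1] <- (pmin(nf, pmax(1, round(u[1] * (nf - 1)) + 1)) - 1) / (nf - 1)
  pmin(1, pmax(0, u))
}

# Gaussian-process regression with an isotropic squared-exponential kernel
# on the unit cube; length-scale and nugget picked by marginal likelihood
# over a small grid. y is standardized internally.
gp_fit <- function(X, y) {
  mu <- mean(y); sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  ys <- (y - mu) / sdy
  n <- length(ys)
  D2 <- as.matrix(stats::dist(X))^2
  best <- NULL
  for (ell in c(0.1, 0.2, 0.3, 0.5, 1.0)) {
    for (nug in c(1e-6, 1e-4, 1e-2)) {
      K <- exp(-D2 / (2 * ell^2)) + diag(nug, n)
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) next
      alpha <- backsolve(ch, forwardsolve(t(ch), ys))
      ll <- -0.5 * sum(ys * alpha) - sum(log(diag(ch))) - n / 2 * log(2 * pi)
      if (is.null(best) || ll > best$ll)
        best <- list(ll = ll, ell = ell, nug = nug, chol = ch, alpha = alpha)
    }
  }
  c(best, list(X = X, mu = mu, sdy = sdy))
}

gp_predict <- function(fit, Xnew) {
  D2 <- outer(rowSums(Xnew^2), rowSums(fit$X^2), "+") -
    2 * Xnew %*% t(fit$X)
  Ks <- exp(-pmax(D2, 0) / (2 * fit$ell^2))
  mean_s <- Ks %*% fit$alpha
  v <- forwardsolve(t(fit$chol), t(Ks))
  var_s <- pmax(1 + fit$nug - colSums(v^2), 1e-12)
  list(mean = fit$mu + fit$sdy * as.vector(mean_s),
       sd = fit$sdy * sqrt(var_s))
}

expected_improvement <- function(mean, sd, best, xi = 0.01) {
  imp <- mean - best - xi
  z <- imp / sd
  ei <- imp * pnorm(z) + sd * dnorm(z)
  ei[sd <= 0] <- 0
  ei
}

#' Bayesian hyperparameter optimization (GP + expected improvement)
#'
#' Sequential model-based optimization over the hyperparameter box: an
#' initial Latin-hypercube design, then a Gaussian-process surrogate
#' fitted to the (hyperparameters, objective) pairs with each next trial
#' chosen by maximizing expected improvement over a candidate cloud. The
#' categorical filter size is handled by snapping its coordinate to the
#' nearest level; learning rate and L2 are searched on the log10 scale.
#' Trials whose objective errors (e.g. training divergence) or returns a
#' non-finite value are recorded as failed and excluded from the
#' surrogate. The best hyperparameters over all evaluated trials are
#' returned.
#'
#' @param objective function taking a [cnn_hyperparams()] and returning a
#'   scalar to maximize (typically validation accuracy).
#' @param space an [hp_space()].
#' @param n_trials total number of objective evaluations (>= 1).
#' @param n_init size of the initial Latin-hypercube design.
#' @param seed integer seed making the whole search reproducible.
#' @return A `bayes_opt` list: `best_hp`, `best_value`, and `trials`
#'   (one row per trial: hyperparameters, `value`, `status`).
#' @export
bayes_optimize <- function(objective, space = hp_space(), n_trials = 20,
                           n_init = NULL, seed = 1L) {
  stopifnot(inherits(space, "hp_space"), n_trials >= 1)
  if (is.null(n_init)) n_init <- min(n_trials, max(4, ceiling(n_trials / 3)))
  set.seed(seed)
  U <- matrix(NA_real_, n_trials, 4)
  init <- lhs::maximinLHS(n_init, 4)
  vals <- rep(NA_real_, n_trials)
  status <- character(n_trials)
  hps <- vector("list", n_trials)
  eval_one <- function(t, u) {
    u <- snap_unit(u, space)
    hp <- hp_from_unit(u, space)
    v <- tryCatch(objective(hp), error = function(e) {
      if (inherits(e, "cnn_divergence")) NA_real_ else stop(e)
    })
    U[t, ] <<- u; hps[[t]] <<- hp
    if (is.null(v) || !is.finite(v)) {
      vals[t] <<- NA_real_; status[t] <<- "failed"
    } else {
      vals[t] <<- v; status[t] <<- "ok"
    }
  }
  for (t in seq_len(min(n_init, n_trials))) eval_one(t, init[t, ])
  if (n_trials > n_init) {
    for (t in (n_init + 1):n_trials) {
      ok <- which(status == "ok")
      cand <- matrix(runif(256 * 4), ncol = 4)
      if (length(ok) >= 2) {
        jit <- matrix(rep(U[ok[which.max(vals[ok])], ], each = 32), ncol = 4) +
          matrix(rnorm(32 * 4, 0, 0.05), ncol = 4)
        jit <- matrix(pmin(1, pmax(0, jit)), ncol = 4)
        cand <- rbind(cand, jit)
        cand <- t(apply(cand, 1, snap_unit, space = space))
        fit <- gp_fit(U[ok, , drop = FALSE], vals[ok])
        pr <- gp_predict(fit, cand)
        ei <- expected_improvement(pr$mean, pr$sd, max(vals[ok]))
        u_next <- cand[which.max(ei), ]
      } else {
        u_next <- cand[1, ]
      }
      eval_one(t, u_next)
    }
  }
  trials <- data.frame(
    filter_size = vapply(hps, `[[`, numeric(1), "filter_size"),
    learning_rate = vapply(hps, `[[`, numeric(1), "learning_rate"),
    momentum = vapply(hps, `[[`, numeric(1), "momentum"),
    l2 = vapply(hps, `[[`, numeric(1), "l2"),
    value = vals, status = status, stringsAsFactors = FALSE)
  if (!any(status == "ok")) {
    stop(errorCondition("all optimization trials failed",
                        trials = trials,
                        class = c("bayes_opt_all_failed", "error", "condition")))
  }
  best_t <- which.max(ifelse(status == "ok", vals, -Inf))
  structure(list(best_hp = hps[[best_t]], best_value = vals[best_t],
                 trials = trials),
            class = "bayes_opt")
}

#' @export
print.bayes_opt <- function(x, ...) {
  cat("Bayesian hyperparameter optimization: ", nrow(x$trials), " trials (",
      sum(x$trials$status == "ok"), " ok)\n", sep = "")
  cat(sprintf("  best value %.4f at filter %d, lr %.4g, momentum %.3f, l2 %.3g\n",
              x$best_value, x$best_hp$filter_size, x$best_hp$learning_rate,
              x$best_hp$momentum, x$best_hp$l2))
  invisible(x)
}
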