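# Small shared fixtures, built in code.

# A dataset crafted to exact allele counts per group: each element of
# `case_codes` / `ctrl_codes` is a genotype code repeated per its count.
dataset_from_codes <- function(case_codes, ctrl_codes) {
  g <- matrix(c(case_codes, ctrl_codes), ncol = 1)
  genotype_dataset(g, rep(c("case", "control"),
                          c(length(case_codes), length(ctrl_codes))))
}

# Tiny trained model on a strongly separable encoding problem (8x8 color
# images, all-AA vs all-aa samples), cached per session.
local_separable_fit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(99)
    n <- 60
    codes <- rbind(matrix(0L, n / 2, 64), matrix(2L, n / 2, 64))
    d <- genotype_dataset(codes, rep(c("control", "case"), each = n / 2))
    imgs <- encode_dataset(d, "cc")
    fit <- geno_cnn(imgs,
                    hp = cnn_hyperparams(3, 0.05, 0.9, 1e-6),
                    config = cnn_config(8, 3, conv_filters = c(2, 3, 4),
                                        batch_size = 16, max_epochs = 20,
                                        patience = 20, seed = 99),
                    seed = 99)
    cache <<- list(fit = fit, imgs = imgs, d = d)
    cache
  }
})

# Independent bilinear upsampling oracle (explicit loops, cell-centre
# alignment), used to cross-check the package's Grad-CAM resampling.
oracle_upsample <- function(A, s_out) {
  s_in <- nrow(A)
  out <- matrix(0, s_out, s_out)
  coord <- function(i) min(max((i - 0.5) * s_in / s_out - 0.5, 0), s_in - 1)
  for (i in seq_len(s_out)) {
    for (j in seq_len(s_out)) {
      y <- coord(i); x <- coord(j)
      y0 <- floor(y); x0 <- floor(x)
      y1 <- min(y0 + 1, s_in - 1); x1 <- min(x0 + 1, s_in - 1)
      wy <- y - y0; wx <- x - x0
      out[i, j] <- A[y0 + 1, x0 + 1] * (1 - wy) * (1 - wx) +
        A[y1 + 1, x0 + 1] * wy * (1 - wx) +
        A[y0 + 1, x1 + 1] * (1 - wy) * wx +
        A[y1 + 1, x1 + 1] * wy * wx
    }
  }
  out
}
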