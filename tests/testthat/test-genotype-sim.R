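test_that("simulated datasets have the requested shape and are reproducible", {
  spec <- simulation_spec(n_cases = 4000, n_controls = 4000,
                          n_null_snps = 1800, n_risk_snps = 200, seed = 5)
  d <- simulate_genotypes(spec)
  expect_s3_class(d, "genotype_dataset")
  expect_identical(dim(d), c(8000L, 2000L))
  expect_identical(sum(d$labels == "case"), 4000L)
  expect_identical(sum(d$snps$is_risk), 200L)
  # risk SNPs form one contiguous block (PLINK-style set output)
  r <- which(d$snps$is_risk)
  expect_identical(r, seq(min(r), max(r)))
  expect_true(all(d$genotypes %in% 0:2))

  d2 <- simulate_genotypes(spec)
  expect_identical(d$genotypes, d2$genotypes)
  d3 <- simulate_genotypes(simulation_spec(n_cases = 4000, n_controls = 4000,
                                           n_null_snps = 1800,
                                           n_risk_snps = 200, seed = 6))
  expect_false(identical(d$genotypes, d3$genotypes))
})

test_that("null genotype frequencies follow Hardy-Weinberg at the MAF", {
  # maf fixed at 0.3, no risk effect: both groups near (0.49, 0.42, 0.09)
  spec <- simulation_spec(n_cases = 6000, n_controls = 6000,
                          n_null_snps = 1, n_risk_snps = 0,
                          maf_low = 0.3, maf_high = 0.3, seed = 11)
  d <- simulate_genotypes(spec)
  exp_p <- c(0.49, 0.42, 0.09)
  for (grp in c("case", "control")) {
    g <- d$genotypes[d$labels == grp, 1]
    obs <- tabulate(g + 1L, 3L) / length(g)
    se <- sqrt(exp_p * (1 - exp_p) / length(g))
    expect_true(all(abs(obs - exp_p) < 3 * se),
                info = paste("group", grp))
  }
})

test_that("case genotypes follow the retrospective distribution P(g)*RR(g)", {
  # hand-derived: p = (0.49, 0.42, 0.09), RR = (1, 2, 4)
  # => case probs = (0.49, 0.84, 0.36) / 1.69
  pr <- genotype_probs(0.3, rr_het = 2, rr_hom = 4)
  expect_equal(pr$case, c(0.49, 0.84, 0.36) / 1.69, tolerance = 1e-12)
  expect_equal(pr$control, c(0.49, 0.42, 0.09), tolerance = 1e-12)

  spec <- simulation_spec(n_cases = 20000, n_controls = 100,
                          n_null_snps = 0, n_risk_snps = 1,
                          maf_low = 0.3, maf_high = 0.3,
                          rr_het = 2, rr_hom = 4, seed = 12)
  d <- simulate_genotypes(spec)
  g <- d$genotypes[d$labels == "case", 1]
  obs <- tabulate(g + 1L, 3L) / length(g)
  se <- sqrt(pr$case * (1 - pr$case) / length(g))
  expect_true(all(abs(obs - pr$case) < 3 * se))
})

test_that("invalid simulation specs name the offending field", {
  expect_error(simulation_spec(maf_low = 0), "maf_low")
  expect_error(simulation_spec(maf_high = 0.6), "maf_high")
  expect_error(simulation_spec(missing_rate = 1), "missing_rate")
  expect_error(simulation_spec(n_cases = -1), "n_cases")
  expect_error(simulation_spec(rr_het = -2), "rr_het")
})

test_that("missingness is planted at the requested rate", {
  d <- simulate_genotypes(simulation_spec(
    n_cases = 500, n_controls = 500, n_null_snps = 100, n_risk_snps = 0,
    missing_rate = 0.1, seed = 4))
  rate <- mean(d$genotypes == -1L)
  expect_true(abs(rate - 0.1) < 3 * sqrt(0.1 * 0.9 / length(d$genotypes)))
})

test_that("HWE chi-square matches hand-derived values", {
  # exact HWE proportions at q = 0.5 and q = 0.4
  expect_equal(hwe_test(25, 50, 25)$chi2, 0)
  expect_equal(hwe_test(25, 50, 25)$p, 1)
  expect_equal(hwe_test(36, 48, 16)$chi2, 0, tolerance = 1e-12)
  # (50, 0, 50): expected (25, 50, 25), chi2 = 25 + 50 + 25 = 100
  h <- hwe_test(50, 0, 50)
  expect_equal(h$chi2, 100)
  expect_lt(h$p, 1e-15)
  # monomorphic sample fits HWE exactly
  expect_equal(hwe_test(100, 0, 0)$p, 1)
  expect_error(hwe_test(0, 0, 0), "zero")
})

test_that("allelic test reproduces the brute-force 2x2 chi-square", {
  # cases minor/major 300/700 (500 samples: 300 het + 200 AA),
  # controls 200/800: chi2 = 2000*(300*800-700*200)^2 /
  # (1000*1000*500*1500) = 26.6667
  d <- dataset_from_codes(rep(c(1L, 0L), c(300, 200)),
                          rep(c(1L, 0L), c(200, 300)))
  res <- allelic_assoc_test(d, 1)
  expect_equal(res$chi2, 2000 * (300 * 800 - 700 * 200)^2 /
                 (1000 * 1000 * 500 * 1500), tolerance = 1e-12)
  expect_equal(res$df, 1L)
  # identical allele frequencies: chi2 = 0, p = 1
  d0 <- dataset_from_codes(rep(c(0L, 1L), 25), rep(c(0L, 1L), 25))
  r0 <- allelic_assoc_test(d0, 1)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
})

test_that("monomorphic SNPs report p = 1 with a warning flag", {
  d <- dataset_from_codes(rep(0L, 20), rep(0L, 20))
  expect_warning(res <- allelic_assoc_test(d, 1), "monomorphic")
  expect_true(res$monomorphic)
  expect_equal(res$p, 1)
})

test_that("prescreen keeps p <= threshold in original order", {
  res <- data.frame(snp_id = paste0("s", 1:5), p = c(0.2, 0.001, 1, 0.04, 0.01))
  expect_identical(prescreen(res, 1)$snp_id, res$snp_id)
  expect_identical(nrow(prescreen(res, 0)), 0L)
  expect_identical(prescreen(res, 0.05)$snp_id, c("s2", "s4", "s5"))
})

test_that("planted risk SNPs are detected with high power", {
  # reduced-scale power check: rr_het 2 (rr_hom 4), maf >= 0.2, n = 800
  d <- simulate_genotypes(simulation_spec(
    n_cases = 400, n_controls = 400, n_null_snps = 60, n_risk_snps = 40,
    maf_low = 0.2, maf_high = 0.5, rr_het = 2, seed = 21))
  scan <- assoc_scan(d)
  expect_true(all(scan$p[d$snps$is_risk] < 0.01))
})

test_that("qc_filter applies each stage and is idempotent", {
  set.seed(31)
  d <- simulate_genotypes(simulation_spec(
    n_cases = 100, n_controls = 100, n_null_snps = 40, n_risk_snps = 0,
    maf_low = 0.2, maf_high = 0.45, seed = 31))
  # clean data passes unchanged
  q <- qc_filter(d)
  expect_identical(dim(q), dim(d))
  expect_s3_class(attr(q, "qc_log"), "data.frame")

  # one SNP with 6% missing at a 5% threshold is removed, the rest kept
  d2 <- d
  d2$genotypes[1:12, 3] <- -1L  # 12/200 = 6%
  q2 <- qc_filter(d2)
  expect_identical(ncol(q2$genotypes), ncol(d$genotypes) - 1L)
  expect_false("snp00003" %in% q2$snps$snp_id)

  # control genotypes (50, 0, 50) violate HWE at p_min 0.01
  d3 <- d
  ctrl <- which(d3$labels == "control")
  d3$genotypes[ctrl, 5] <- rep(c(0L, 2L), each = 50)
  q3 <- qc_filter(d3)
  expect_false("snp00005" %in% q3$snps$snp_id)

  # monotone and idempotent
  expect_true(all(dim(qc_filter(q)) <= dim(q)))
  expect_identical(qc_filter(q)$genotypes, q$genotypes)
})

test_that("low-MAF SNPs are removed by the MAF filter", {
  set.seed(41)
  g <- cbind(matrix(rbinom(200 * 2, 2, 0.3), 200, 2),
             rbinom(200, 2, 0.01))
  d <- genotype_dataset(g, rep(c("case", "control"), 100))
  q <- qc_filter(d)
  expect_identical(ncol(q$genotypes), 2L)
})

test_that("the genotype TSV dialect round-trips", {
  d <- simulate_genotypes(simulation_spec(
    n_cases = 20, n_controls = 20, n_null_snps = 15, n_risk_snps = 5,
    missing_rate = 0.05, seed = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_geno_tsv(d, path)
  d2 <- read_geno_tsv(path)
  expect_identical(unname(d2$genotypes), unname(d$genotypes))
  expect_identical(as.character(d2$labels), as.character(d$labels))
  expect_identical(d2$snps$snp_id, d$snps$snp_id)
})
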