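#' Specify a case/control genotype simulation
#'
#' Defines the generative model for a simulated GWAS dataset: biallelic
#' SNPs with MAFs drawn uniformly from `[maf_low, maf_high]`, genotypes in
#' Hardy-Weinberg proportions in the population, and a planted
#' multiplicative risk model at the risk SNPs. Controls are drawn from the
#' population genotype distribution `P(g)` (rare-disease approximation);
#' cases from the retrospective distribution `P(g | case)` proportional to
#' `P(g) * RR(g)` with `RR(0) = 1`, `RR(1) = rr_het`, `RR(2) = rr_hom`.
#'
#' The default dimensions mirror a standard simulated GWAS benchmark:
#' 4,000 cases and 4,000 controls typed at 2,000 SNPs of which 200 carry
#' risk. Effect sizes are multiplicative (`rr_hom = rr_het^2`) with
#' `rr_het = 1.5` by default.
#'
#' @param n_cases,n_controls sample counts.
#' @param n_null_snps,n_risk_snps SNP counts without / with planted risk.
#' @param maf_low,maf_high MAF sampling range, `0 < maf_low <= maf_high <= 0.5`.
#' @param rr_het relative risk of the heterozygote vs the major homozygote.
#' @param rr_hom relative risk of the minor homozygote; defaults to
#'   `rr_het^2` (multiplicative model).
#' @param missing_rate independent per-genotype missingness probability.
#' @param seed integer seed; the simulation is bit-reproducible under it.
#'
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_cases = 4000, n_controls = 4000,
                            n_null_snps = 1800, n_risk_snps = 200,
                            maf_low = 0.05, maf_high = 0.5,
                            rr_het = 1.5, rr_hom = rr_het^2,
                            missing_rate = 0, seed = 1L) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid simulation spec: `", field, "` ", msg,
                          call. = FALSE)
  }
  for (f in c("n_cases", "n_controls", "n_null_snps", "n_risk_snps")) {
    v <- get(f)
    chk(is.numeric(v) && length(v) == 1 && v >= 0 && v == floor(v),
        f, "must be a nonnegative integer count")
  }
  chk(n_cases + n_controls > 0, "n_cases", "and `n_controls` cannot both be 0")
  chk(n_null_snps + n_risk_snps > 0, "n_null_snps",
      "and `n_risk_snps` cannot both be 0")
  chk(is.numeric(maf_low) && maf_low > 0, "maf_low", "must be > 0")
  chk(maf_low <= maf_high, "maf_low", "must be <= maf_high")
  chk(maf_high <= 0.5, "maf_high", "must be <= 0.5")
  chk(rr_het >= 0, "rr_het", "must be >= 0")
  chk(rr_hom >= 0, "rr_hom", "must be >= 0")
  chk(missing_rate >= 0 && missing_rate < 1, "missing_rate", "must be in [0, 1)")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_null_snps = as.integer(n_null_snps),
                 n_risk_snps = as.integer(n_risk_snps),
                 maf_low = maf_low, maf_high = maf_high,
                 rr_het = rr_het, rr_hom = rr_hom,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Genotype probabilities under the simulation model
#'
#' Population (Hardy-Weinberg) and retrospective case genotype
#' distributions at one SNP.
#'
#' @param maf minor allele frequency `q`.
#' @param rr_het,rr_hom relative risks of the heterozygote and minor
#'   homozygote.
#' @return A list with `control` and `case`, each a length-3 probability
#'   vector over codes (0, 1, 2).
#' @export
genotype_probs <- function(maf, rr_het = 1, rr_hom = 1) {
  q <- maf
  p0 <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  w <- p0 * c(1, rr_het, rr_hom)
  list(control = p0, case = w / sum(w))
}

#' Simulate a case/control genotype dataset
#'
#' Draws genotypes per the model documented in [simulation_spec()]. Risk
#' SNPs occupy one contiguous block at a seeded random position — the
#' block structure PLINK's \code{--simulate} produces, where each
#' configured SNP set is written out consecutively. SNP order is the
#' canonical order used by downstream image layouts.
#'
#' @param spec a [simulation_spec()].
#' @return A [genotype_dataset()] whose `snps` table records each SNP's
#'   true MAF, risk status and planted relative risks.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  m <- spec$n_null_snps + spec$n_risk_snps
  n <- spec$n_cases + spec$n_controls
  maf <- runif(m, spec$maf_low, spec$maf_high)
  # Risk SNPs form one contiguous block at a random position, mirroring how
  # PLINK's --simulate writes each SNP set out as a consecutive run.
  is_risk <- rep(FALSE, m)
  if (spec$n_risk_snps > 0) {
    start <- sample.int(m - spec$n_risk_snps + 1L, 1L)
    is_risk[start:(start + spec$n_risk_snps - 1L)] <- TRUE
  }
  rr_het <- ifelse(is_risk, spec$rr_het, 1)
  rr_hom <- ifelse(is_risk, spec$rr_hom, 1)
  labels <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
  is_case <- labels == "case"
  g <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    pr <- genotype_probs(maf[j], rr_het[j], rr_hom[j])
    col <- integer(n)
    if (spec$n_cases > 0)
      col[is_case] <- sample.int(3L, spec$n_cases, replace = TRUE,
                                 prob = pr$case) - 1L
    if (spec$n_controls > 0)
      col[!is_case] <- sample.int(3L, spec$n_controls, replace = TRUE,
                                  prob = pr$control) - 1L
    g[, j] <- col
  }
  if (spec$missing_rate > 0) {
    g[runif(length(g)) < spec$missing_rate] <- -1L
  }
  snps <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                     chrom = "1", pos = seq_len(m) * 1000L,
                     maf = maf, is_risk = is_risk,
                     rr_het = rr_het, rr_hom = rr_hom,
                     allele_major = "A", allele_minor = "C",
                     stringsAsFactors = FALSE)
  genotype_dataset(g, labels, snps = snps,
                   sample_ids = sprintf("S%05d", seq_len(n)))
}
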