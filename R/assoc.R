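#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against Hardy-Weinberg proportions at the sample allele frequency,
#' using the closed form
#' `chi2 = N * (4*n_AA*n_aa - n_Aa^2)^2 / ((2*n_AA + n_Aa)^2 * (2*n_aa + n_Aa)^2)`.
#' A monomorphic sample fits HWE exactly (`chi2 = 0`, `p = 1`).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return A list with `chi2`, `df` (1) and `p`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0)) stop("genotype counts must be nonnegative")
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  d1 <- 2 * n_AA + n_Aa
  d2 <- 2 * n_aa + n_Aa
  chi2 <- if (d1 == 0 || d2 == 0) 0
          else n * (4 * n_AA * n_aa - n_Aa^2)^2 / (d1^2 * d2^2)
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# 2x2 allelic chi-square without continuity correction (vectorized).
# a/b: minor/major allele counts in cases; c/d: in controls.
allelic_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- n * (a * d - b * c)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  ifelse(den > 0, num / den, NA_real_)
}

#' Allelic case/control association test at one SNP
#'
#' One-degree-of-freedom chi-square on the 2x2 allele-count table
#' (minor/major allele x case/control), without continuity correction —
#' the classic GWAS allelic test. Genotype code `g` contributes `g` minor
#' and `2 - g` major alleles; missing genotypes are dropped. A SNP that is
#' monomorphic after dropping missing data has an undefined statistic and
#' is reported with `p = 1` and `monomorphic = TRUE`, with a warning.
#'
#' @param d a [genotype_dataset()].
#' @param snp_index column index of the SNP to test.
#' @return A one-row `data.frame`: `snp_id`, `chi2`, `df`, `p`,
#'   `monomorphic`.
#' @export
allelic_assoc_test <- function(d, snp_index) {
  stopifnot(inherits(d, "genotype_dataset"),
            snp_index >= 1, snp_index <= ncol(d$genotypes))
  res <- assoc_scan(d, snp_indices = snp_index, warn = TRUE)
  res
}

#' Allelic association scan over all (or selected) SNPs
#'
#' @param d a [genotype_dataset()].
#' @param snp_indices columns to test; default all.
#' @param warn warn on monomorphic SNPs.
#' @return `data.frame` with one row per SNP: `snp_id`, `chi2`, `df`, `p`,
#'   `monomorphic`, in the input SNP order.
#' @export
assoc_scan <- function(d, snp_indices = NULL, warn = FALSE) {
  stopifnot(inherits(d, "genotype_dataset"))
  if (is.null(snp_indices)) snp_indices <- seq_len(ncol(d$genotypes))
  if (!all(levels(d$labels) %in% as.character(unique(d$labels))))
    stop("both case and control labels must be present")
  g <- d$genotypes[, snp_indices, drop = FALSE]
  case <- d$labels == "case"
  obs <- g >= 0L
  gz <- g * obs
  minor_case <- colSums(gz[case, , drop = FALSE])
  minor_ctrl <- colSums(gz[!case, , drop = FALSE])
  tot_case <- 2 * colSums(obs[case, , drop = FALSE])
  tot_ctrl <- 2 * colSums(obs[!case, , drop = FALSE])
  a <- minor_case; b <- tot_case - minor_case
  cc <- minor_ctrl; dd <- tot_ctrl - minor_ctrl
  chi2 <- allelic_chi2(a, b, cc, dd)
  mono <- (a + cc == 0) | (b + dd == 0)
  chi2[mono] <- NA_real_
  p <- ifelse(mono, 1, pchisq(chi2, df = 1, lower.tail = FALSE))
  if (warn && any(mono))
    warning(sum(mono), " monomorphic SNP(s): statistic undefined, p set to 1")
  data.frame(snp_id = d$snps$snp_id[snp_indices],
             chi2 = chi2, df = 1L, p = p, monomorphic = mono,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pre-screen SNPs on association p-value
#'
#' Keeps SNPs with `p <= p_threshold`, preserving the original order —
#' the association pre-screen used to shrink a GWAS panel before image
#' conversion.
#'
#' @param results `data.frame` from [assoc_scan()].
#' @param p_threshold retention threshold in `(0, 1]` (0 yields an empty set).
#' @return The filtered `data.frame`, original order preserved.
#' @export
prescreen <- function(results, p_threshold) {
  stopifnot(is.data.frame(results), !is.null(results$p),
            p_threshold >= 0, p_threshold <= 1)
  results[results$p <= p_threshold, , drop = FALSE]
}

#' Standard GWAS quality-control filter
#'
#' Applies, in order: (1) drop individuals with genotype missingness
#' above `ind_miss_max`; (2) drop SNPs with missingness above
#' `snp_miss_max`; (3) drop SNPs with MAF below `maf_min` (computed on
#' cases and controls combined); (4) drop SNPs with a Hardy-Weinberg
#' p-value below `hwe_p_min`, computed on controls only (the usual GWAS
#' practice, since risk effects distort case genotype frequencies). The
#' removal count of each stage is recorded in the `qc_log` attribute.
#'
#' @param d a [genotype_dataset()].
#' @param snp_miss_max,ind_miss_max,maf_min,hwe_p_min filter cutoffs.
#' @return The filtered `genotype_dataset` with attribute `qc_log`, a
#'   `data.frame` of per-stage removals.
#' @export
qc_filter <- function(d, snp_miss_max = 0.05, ind_miss_max = 0.05,
                      maf_min = 0.05, hwe_p_min = 0.01) {
  stopifnot(inherits(d, "genotype_dataset"))
  log <- list()
  note <- function(stage, removed, kept)
    data.frame(stage = stage, removed = removed, kept = kept)

  miss_ind <- rowMeans(d$genotypes == -1L)
  keep_i <- miss_ind <= ind_miss_max
  log[[1]] <- note("individual_missingness", sum(!keep_i), sum(keep_i))
  if (!any(keep_i)) stop("QC removed every individual (missingness filter)")
  d <- subset_dataset(d, samples = which(keep_i))

  miss_snp <- colMeans(d$genotypes == -1L)
  keep_s <- miss_snp <= snp_miss_max
  log[[2]] <- note("snp_missingness", sum(!keep_s), sum(keep_s))

  st <- snp_stats(d)
  keep_maf <- !is.na(st$maf) & st$maf >= maf_min
  log[[3]] <- note("maf", sum(keep_s & !keep_maf), NA)

  ctrl <- d$genotypes[d$labels == "control", , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(ctrl)), function(j) {
    gj <- ctrl[, j]; gj <- gj[gj >= 0L]
    if (length(gj) == 0) return(1)
    hwe_test(sum(gj == 0L), sum(gj == 1L), sum(gj == 2L))$p
  }, numeric(1))
  keep_hwe <- hwe_p >= hwe_p_min
  log[[4]] <- note("hwe_controls", sum(keep_s & keep_maf & !keep_hwe), NA)

  keep <- keep_s & keep_maf & keep_hwe
  log[[3]]$kept <- NA; log[[4]]$kept <- sum(keep)
  if (!any(keep)) stop("QC removed every SNP")
  out <- subset_dataset(d, snps = which(keep))
  attr(out, "qc_log") <- do.call(rbind, log)
  out
}
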