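#' Construct a case/control genotype dataset
#'
#' Bundles a samples x SNPs matrix of minor-allele dosage codes with
#' case/control labels and per-SNP metadata. Codes are `0` (major
#' homozygote AA), `1` (heterozygote Aa), `2` (minor homozygote aa) and
#' `-1` for missing. The column order of `genotypes` is the canonical SNP
#' order used by every downstream image layout.
#'
#' @param genotypes integer matrix, one row per sample, one column per SNP,
#'   entries in `{-1, 0, 1, 2}`.
#' @param labels character or factor of `"case"`/`"control"`, one per sample.
#' @param snps optional `data.frame` of per-SNP metadata with at least
#'   `snp_id`; columns `chrom`, `pos`, `maf`, `is_risk`, `rr_het`, `rr_hom`,
#'   `allele_major`, `allele_minor` are filled with defaults when absent.
#' @param sample_ids optional character vector of sample identifiers.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `genotypes`, `labels` (factor with levels `control`, `case`),
#'   `sample_ids` and `snps`.
#' @export
genotype_dataset <- function(genotypes, labels, snps = NULL, sample_ids = NULL) {
  if (!is.matrix(genotypes)) stop("`genotypes` must be a matrix")
  storage.mode(genotypes) <- "integer"
  bad <- !(genotypes %in% c(-1L, 0L, 1L, 2L))
  if (any(bad)) {
    stop("`genotypes` contains codes outside {-1, 0, 1, 2} (first offender at index ",
         which(bad)[1], ")")
  }
  n <- nrow(genotypes); m <- ncol(genotypes)
  if (length(labels) != n) stop("`labels` length (", length(labels),
                                ") does not match number of samples (", n, ")")
  labels <- factor(as.character(labels), levels = c("control", "case"))
  if (anyNA(labels)) stop("`labels` must be 'case' or 'control'")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(genotypes)
    if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  }
  if (length(sample_ids) != n) stop("`sample_ids` length does not match samples")
  if (is.null(snps)) {
    ids <- colnames(genotypes)
    if (is.null(ids)) ids <- sprintf("snp%05d", seq_len(m))
    snps <- data.frame(snp_id = ids, stringsAsFactors = FALSE)
  }
  if (nrow(snps) != m) stop("`snps` rows (", nrow(snps),
                            ") do not match number of SNP columns (", m, ")")
  defaults <- list(chrom = "1", pos = seq_len(m), maf = NA_real_,
                   is_risk = FALSE, rr_het = 1, rr_hom = 1,
                   allele_major = "A", allele_minor = "C")
  for (nm in names(defaults)) if (is.null(snps[[nm]])) snps[[nm]] <- defaults[[nm]]
  rownames(genotypes) <- sample_ids
  colnames(genotypes) <- snps$snp_id
  structure(list(genotypes = genotypes, labels = labels,
                 sample_ids = sample_ids, snps = snps),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat("Genotype dataset: ", nrow(x$genotypes), " samples (",
      tab[["case"]], " cases, ", tab[["control"]], " controls) x ",
      ncol(x$genotypes), " SNPs\n", sep = "")
  miss <- mean(x$genotypes == -1L)
  cat(sprintf("  risk SNPs: %d; missing genotypes: %.2f%%\n",
              sum(x$snps$is_risk), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

#' Subset a genotype dataset by samples and/or SNPs
#'
#' @param x a [genotype_dataset()].
#' @param samples,snps integer or logical indices; default keeps all.
#' @return A `genotype_dataset`.
#' @export
subset_dataset <- function(x, samples = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_dataset"))
  if (is.null(samples)) samples <- seq_len(nrow(x$genotypes))
  if (is.null(snps)) snps <- seq_len(ncol(x$genotypes))
  genotype_dataset(x$genotypes[samples, snps, drop = FALSE],
                   x$labels[samples],
                   snps = x$snps[snps, , drop = FALSE],
                   sample_ids = x$sample_ids[samples])
}

#' Per-SNP minor allele frequency and missingness
#'
#' MAF is the folded empirical allele frequency `min(q, 1 - q)` where `q`
#' is the mean dosage over non-missing genotypes divided by two.
#'
#' @param x a [genotype_dataset()] or a code matrix.
#' @return `data.frame` with `snp_id`, `maf`, `missing_rate`.
#' @export
snp_stats <- function(x) {
  g <- if (inherits(x, "genotype_dataset")) x$genotypes else x
  obs <- g >= 0L
  n_obs <- colSums(obs)
  dos <- colSums(g * obs)
  q <- ifelse(n_obs > 0, dos / (2 * n_obs), NA_real_)
  data.frame(snp_id = colnames(g) %||% sprintf("snp%05d", seq_len(ncol(g))),
             maf = pmin(q, 1 - q),
             missing_rate = 1 - n_obs / nrow(g),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read the package's genotype TSV dialect
#'
#' Header row: `sample_id`, `label`, then one column per SNP id; one row
#' per sample with dosage codes (`-1` marks missing).
#'
#' @param x a [genotype_dataset()].
#' @param path file path.
#' @return `write_geno_tsv()` returns `path` invisibly; `read_geno_tsv()`
#'   returns a `genotype_dataset`.
#' @export
write_geno_tsv <- function(x, path) {
  stopifnot(inherits(x, "genotype_dataset"))
  dt <- data.table::data.table(sample_id = x$sample_ids,
                               label = as.character(x$labels))
  dt <- cbind(dt, data.table::as.data.table(x$genotypes))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  g <- as.matrix(dt[, -(1:2)])
  storage.mode(g) <- "integer"
  genotype_dataset(g, dt$label, sample_ids = dt$sample_id)
}
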