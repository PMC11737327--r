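#' Read / write PLINK text pedigree files (.ped/.map)
#'
#' `write_plink_text()` emits the whitespace-delimited PLINK text format:
#' a `.map` with `chrom snp_id 0 pos` and a `.ped` with the six leading
#' columns (`FID IID PAT MAT SEX PHENO`; phenotype 1 = control,
#' 2 = case) followed by two allele letters per SNP. Missing genotypes are
#' written as `0 0`.
#'
#' `read_plink_text()` maps allele letters back to dosage codes by the
#' empirical majority allele per SNP (PLINK's own minor-allele
#' convention): the more frequent allele is coded as the major allele,
#' ties broken alphabetically. A SNP showing more than two alleles is a
#' parse error. Note that the majority rule means a write/read round trip
#' recovers the original codes only while each SNP's sample minor-allele
#' frequency stays below 0.5.
#'
#' @param d a [genotype_dataset()].
#' @param ped_path,map_path file paths.
#' @return `write_plink_text()` invisibly returns the two paths;
#'   `read_plink_text()` returns a `genotype_dataset`.
#' @export
write_plink_text <- function(d, ped_path, map_path) {
  stopifnot(inherits(d, "genotype_dataset"))
  map <- data.frame(chrom = d$snps$chrom, snp_id = d$snps$snp_id,
                    cm = 0L, pos = d$snps$pos)
  data.table::fwrite(map, map_path, sep = "\t", col.names = FALSE)
  maj <- d$snps$allele_major; mnr <- d$snps$allele_minor
  n <- nrow(d$genotypes); m <- ncol(d$genotypes)
  # allele pair strings per code, per SNP
  alle <- matrix("0 0", n, m)
  for (j in seq_len(m)) {
    gj <- d$genotypes[, j]
    pair <- c(paste(maj[j], maj[j]), paste(maj[j], mnr[j]),
              paste(mnr[j], mnr[j]))
    alle[gj >= 0L, j] <- pair[gj[gj >= 0L] + 1L]
  }
  lead <- cbind(d$sample_ids, d$sample_ids, "0", "0", "0",
                ifelse(d$labels == "case", "2", "1"))
  lines <- apply(cbind(lead, alle), 1, paste, collapse = " ")
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' @rdname write_plink_text
#' @export
read_plink_text <- function(ped_path, map_path) {
  map <- data.table::fread(map_path, header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"))
  m <- nrow(map)
  lines <- readLines(ped_path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6 + 2 * m
  lens <- lengths(toks)
  if (any(lens != want)) {
    stop("ragged .ped row(s): line ", which(lens != want)[1], " has ",
         lens[which(lens != want)[1]], " fields, expected ", want)
  }
  tok <- do.call(rbind, toks)
  sample_ids <- tok[, 2]
  pheno <- tok[, 6]
  labels <- ifelse(pheno == "2", "case", "control")
  a1 <- tok[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  a2 <- tok[, 6 + 2 * seq_len(m), drop = FALSE]
  n <- length(sample_ids)
  g <- matrix(-1L, n, m)
  maj <- character(m); mnr <- character(m)
  for (j in seq_len(m)) {
    obs <- a1[, j] != "0" & a2[, j] != "0"
    al <- c(a1[obs, j], a2[obs, j])
    tab <- sort(table(al), decreasing = TRUE)
    if (length(tab) > 2) {
      stop("SNP ", map$snp_id[j], " (column ", j, ") has ", length(tab),
           " alleles; only biallelic SNPs are supported")
    }
    if (length(tab) == 0) { maj[j] <- "A"; mnr[j] <- "C"; next }
    nm <- names(tab)
    if (length(tab) == 2 && tab[1] == tab[2]) nm <- sort(nm)
    maj[j] <- nm[1]
    mnr[j] <- if (length(nm) > 1) nm[2] else NA_character_
    dos <- (a1[obs, j] != maj[j]) + (a2[obs, j] != maj[j])
    g[obs, j] <- as.integer(dos)
  }
  mono <- is.na(mnr)
  mnr[mono] <- ifelse(maj[mono] == "C", "T", "C")
  snps <- data.frame(snp_id = map$snp_id, chrom = as.character(map$chrom),
                     pos = map$pos, allele_major = maj, allele_minor = mnr,
                     stringsAsFactors = FALSE)
  genotype_dataset(g, labels, snps = snps, sample_ids = sample_ids)
}
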