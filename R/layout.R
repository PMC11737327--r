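#' Minimal square image side for a SNP count
#'
#' The smallest integer `s` with `s^2 >= n`: 2,000 SNPs fit a 45 x 45
#' image, 6,492 an 81 x 81, 25,220 a 159 x 159.
#'
#' @param n number of pixels (SNPs) that must fit.
#' @return Integer side length.
#' @export
side_length <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != floor(n))
    stop("`n` must be a positive integer")
  s <- as.integer(ceiling(sqrt(n)))
  while (s > 1L && (s - 1L)^2 >= n) s <- s - 1L  # guard against sqrt rounding
  s
}

new_layout <- function(side, row, col, snp_ids = NULL) {
  side <- as.integer(side)
  mask <- matrix(TRUE, side, side)
  mask[cbind(row, col)] <- FALSE
  structure(list(side = side, row = as.integer(row), col = as.integer(col),
                 n_snps = length(row),
                 snp_ids = snp_ids %||% sprintf("snp%05d", seq_along(row)),
                 padding_mask = mask),
            class = "snp_layout")
}

#' @export
print.snp_layout <- function(x, ...) {
  cat("SNP layout: ", x$n_snps, " SNPs on a ", x$side, " x ", x$side,
      " grid (", sum(x$padding_mask), " padding cells)\n", sep = "")
  invisible(x)
}

#' Row-major end-to-end SNP layout
#'
#' Places SNP `i` at `(i div side, i mod side)` (row-major scan), with
#' chromosomes simply concatenated; the cells after the last SNP are
#' padding. This is the layout used by the color encoding.
#'
#' @param n_snps number of SNPs.
#' @param side grid side; defaults to [side_length()] of `n_snps`.
#' @param snp_ids optional SNP identifiers carried in the layout.
#' @return An `snp_layout`: `side`, per-SNP `row`/`col` (1-based),
#'   `padding_mask` (`TRUE` where no SNP backs the cell).
#' @export
layout_end_to_end <- function(n_snps, side = side_length(n_snps),
                              snp_ids = NULL) {
  stopifnot(n_snps >= 1)
  if (side^2 < n_snps)
    stop("side ", side, " too small for ", n_snps,
         " SNPs (needs at least ", side_length(n_snps), ")")
  i0 <- seq_len(n_snps) - 1L
  new_layout(side, i0 %/% side + 1L, i0 %% side + 1L, snp_ids)
}

#' Chromosome-per-row SNP layout
#'
#' Each chromosome starts at column 1 of a fresh row, wraps across as
#' many full rows as it needs, and pads the remainder of its last row —
#' the layout used by the grayscale base-pair encoding. The minimal
#' feasible side is the smallest `s` with
#' `sum(ceiling(chrom_lengths / s)) <= s`.
#'
#' @param chrom_lengths ordered SNP counts per chromosome.
#' @param side grid side; defaults to the minimal feasible side.
#' @param snp_ids optional SNP identifiers.
#' @return An `snp_layout`.
#' @export
layout_chromosome_rows <- function(chrom_lengths, side = NULL, snp_ids = NULL) {
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths >= 1))
  rows_needed <- function(s) sum(ceiling(chrom_lengths / s))
  s_min <- side_length(sum(chrom_lengths))
  while (rows_needed(s_min) > s_min) s_min <- s_min + 1L
  if (is.null(side)) side <- s_min
  if (rows_needed(side) > side)
    stop("side ", side, " infeasible for this chromosome layout; ",
         "minimal feasible side is ", s_min)
  row <- integer(0); col <- integer(0)
  r <- 1L
  for (len in chrom_lengths) {
    i0 <- seq_len(len) - 1L
    row <- c(row, r + i0 %/% side)
    col <- c(col, i0 %% side + 1L)
    r <- r + as.integer(ceiling(len / side))
  }
  new_layout(side, row, col, snp_ids)
}

#' Serialize / load a layout as TSV
#'
#' Columns `snp_id`, `row`, `col`; the side is stored in a `#side=` header
#' comment line.
#'
#' @param layout an `snp_layout`.
#' @param path file path.
#' @return `write_layout()` returns `path` invisibly; `read_layout()` an
#'   `snp_layout`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "snp_layout"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#side=", layout$side), con)
  writeLines("snp_id\trow\tcol", con)
  writeLines(paste(layout$snp_ids, layout$row, layout$col, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  first <- readLines(path, n = 1)
  side <- as.integer(sub("^#side=", "", first))
  df <- data.table::fread(path, skip = 1, header = TRUE, sep = "\t")
  new_layout(side, df$row, df$col, df$snp_id)
}
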