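#' Genotype-to-pixel encoder tables
#'
#' Three encoders are supported:
#' \describe{
#'   \item{`cc`}{color encoding: AA, Aa, aa map to RGB triples
#'     `(0, 0, 255)` (blue), `(0, 170, 0)` (green) and `(85, 0, 0)` (dark
#'     red); padding and missing are black `(0, 0, 0)`. Every genotype is
#'     distinguishable from padding.}
#'   \item{`chen`}{grayscale dosage encoding: AA, Aa, aa map to 0, 154,
#'     254. The AA value collides with the padding value 0 by
#'     construction — a documented weakness of this scheme that the color
#'     encoding removes.}
#'   \item{`yue`}{grayscale base-pair encoding: the 10 unordered base
#'     pairs over \{A, C, G, T\} are coded 1..10 in lexicographic order
#'     (AA, AC, AG, AT, CC, CG, CT, GG, GT, TT) and multiplied by 25;
#'     padding is 0.}
#' }
#'
#' @format `cc_palette` is a 3 x 3 integer matrix (rows AA/Aa/aa, columns
#'   R/G/B); `chen_palette` a named length-3 integer vector.
#' @name encoders
NULL

#' @rdname encoders
#' @export
cc_palette <- matrix(c(0L, 0L, 255L,
                       0L, 170L, 0L,
                       85L, 0L, 0L),
                     nrow = 3, byrow = TRUE,
                     dimnames = list(c("AA", "Aa", "aa"), c("R", "G", "B")))

#' @rdname encoders
#' @export
chen_palette <- c(AA = 0L, Aa = 154L, aa = 254L)

yue_pairs <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")

#' Base-pair genotype class code for the grayscale base-pair encoder
#'
#' Unordered pairs over \{A, C, G, T\} are ranked lexicographically
#' (AA, AC, AG, AT, CC, CG, CT, GG, GT, TT) as classes 1..10; the pixel
#' value is 25 times the class.
#'
#' @param a1,a2 allele letters (order-insensitive).
#' @return Integer class in 1..10.
#' @export
yue_class <- function(a1, a2) {
  bad <- setdiff(unique(c(a1, a2)), c("A", "C", "G", "T"))
  if (length(bad)) stop("invalid base: ", paste(bad, collapse = ", "))
  key <- paste0(pmin(a1, a2), pmax(a1, a2))
  match(key, yue_pairs)
}

#' Encode one sample's genotypes as an image
#'
#' Maps a vector of genotype codes onto the layout grid under one of the
#' three encoders (see [encoders]). Missing genotypes (`-1`) render as the
#' padding value in every encoder. For the base-pair encoder the per-SNP
#' major/minor allele letters must be supplied so codes can be expanded
#' to base pairs.
#'
#' @param codes integer vector in `{-1, 0, 1, 2}`, one per layout SNP.
#' @param layout an `snp_layout` with `layout$n_snps == length(codes)`.
#' @param encoder `"cc"`, `"chen"` or `"yue"`.
#' @param alleles for `encoder = "yue"`: a list/data.frame with
#'   `allele_major` and `allele_minor` character vectors per SNP.
#' @param sample_id,label carried into the result.
#' @return A `genotype_image`: list with `pixels` (side x side x channels
#'   integer array in 0..255), `encoder`, `side`, `channels`, `sample_id`,
#'   `label`.
#' @export
encode_genotypes <- function(codes, layout, encoder = c("cc", "chen", "yue"),
                             alleles = NULL, sample_id = NA_character_,
                             label = NA_character_) {
  encoder <- match.arg(encoder)
  stopifnot(inherits(layout, "snp_layout"))
  if (length(codes) != layout$n_snps)
    stop("length(codes) (", length(codes), ") != layout SNPs (", layout$n_snps, ")")
  if (!all(codes %in% c(-1L, 0L, 1L, 2L)))
    stop("genotype codes must be in {-1, 0, 1, 2}")
  s <- layout$side
  idx <- cbind(layout$row, layout$col)
  obs <- codes >= 0L
  if (encoder == "cc") {
    px <- array(0L, c(s, s, 3L))
    for (ch in 1:3) {
      plane <- matrix(0L, s, s)
      plane[idx[obs, , drop = FALSE]] <- cc_palette[codes[obs] + 1L, ch]
      px[, , ch] <- plane
    }
    channels <- 3L
  } else if (encoder == "chen") {
    plane <- matrix(0L, s, s)
    plane[idx[obs, , drop = FALSE]] <- unname(chen_palette[codes[obs] + 1L])
    px <- array(plane, c(s, s, 1L))
    channels <- 1L
  } else {
    if (is.null(alleles))
      stop("encoder 'yue' needs per-SNP `alleles` (allele_major/allele_minor)")
    maj <- alleles$allele_major; mnr <- alleles$allele_minor
    a1 <- ifelse(codes >= 1L, mnr, maj)
    a2 <- ifelse(codes == 2L, mnr, maj)
    vals <- integer(length(codes))
    vals[obs] <- 25L * yue_class(a1[obs], a2[obs])
    plane <- matrix(0L, s, s)
    plane[idx[obs, , drop = FALSE]] <- vals[obs]
    px <- array(plane, c(s, s, 1L))
    channels <- 1L
  }
  structure(list(pixels = px, encoder = encoder, side = s,
                 channels = channels, sample_id = sample_id, label = label),
            class = "genotype_image")
}

#' @export
print.genotype_image <- function(x, ...) {
  cat("Genotype image (", x$encoder, "): ", x$side, " x ", x$side, " x ",
      x$channels, ", sample ", x$sample_id, " [", x$label, "]\n", sep = "")
  invisible(x)
}

#' Decode an image back to genotype codes
#'
#' Inverts [encode_genotypes()] on the layout cells. The color palette is
#' bijective, so decoding is exact: black on a non-padding cell is a
#' missing genotype. The grayscale dosage palette collides AA with
#' padding/missing (value 0), so 0 on a non-padding cell decodes as AA
#' and the result carries attribute `collision = TRUE` when such cells
#' exist. The base-pair encoder decodes to class codes 1..10 (attribute
#' `yue_classes`) and to dosages where the biallelic expansion is
#' unambiguous.
#'
#' @param img a `genotype_image`.
#' @param layout the `snp_layout` it was encoded with.
#' @param alleles for base-pair images: per-SNP `allele_major` /
#'   `allele_minor`, used to map decoded classes back to dosages.
#' @return Integer vector of genotype codes per layout SNP.
#' @export
decode_image <- function(img, layout, alleles = NULL) {
  stopifnot(inherits(img, "genotype_image"), inherits(layout, "snp_layout"),
            img$side == layout$side)
  idx <- cbind(layout$row, layout$col)
  if (img$encoder == "cc") {
    r <- img$pixels[, , 1][idx]
    g <- img$pixels[, , 2][idx]
    b <- img$pixels[, , 3][idx]
    key <- paste(r, g, b)
    pal <- c("0 0 0" = -1L,
             "0 0 255" = 0L, "0 170 0" = 1L, "85 0 0" = 2L)
    codes <- pal[key]
    if (anyNA(codes))
      stop("pixel color (", key[which(is.na(codes))[1]],
           ") not in the color palette")
    unname(codes)
  } else if (img$encoder == "chen") {
    v <- img$pixels[, , 1][idx]
    pal <- c(`0` = 0L, `154` = 1L, `254` = 2L)
    codes <- pal[as.character(v)]
    if (anyNA(codes))
      stop("gray value ", v[which(is.na(codes))[1]], " not in the palette")
    codes <- unname(codes)
    attr(codes, "collision") <- any(v == 0L)
    codes
  } else {
    v <- img$pixels[, , 1][idx]
    if (!all(v %in% c(0L, 25L * 1:10)))
      stop("gray value ", v[which(!(v %in% c(0L, 25L * 1:10)))[1]],
           " not in the base-pair palette")
    cls <- as.integer(v / 25L)
    codes <- rep(NA_integer_, length(cls))
    codes[cls == 0L] <- -1L
    if (!is.null(alleles)) {
      maj <- alleles$allele_major; mnr <- alleles$allele_minor
      per_dose <- cbind(yue_class(maj, maj), yue_class(maj, mnr),
                        yue_class(mnr, mnr))
      for (dose in 0:2) {
        hit <- cls == per_dose[, dose + 1L]
        codes[hit] <- dose
      }
    }
    attr(codes, "yue_classes") <- cls
    codes
  }
}

#' Encode a whole dataset into an in-memory image set
#'
#' Encodes every sample of a [genotype_dataset()] under one encoder and a
#' shared layout. Images are stored flattened as an
#' `(side * side * channels) x n_samples` matrix of 0..255 values — the
#' form the CNN consumes directly — with the pixel at (h, w, c) of sample
#' j at row `h + side * (w - 1) + side^2 * (c - 1)`.
#'
#' By default the color and grayscale-dosage encoders use the end-to-end
#' row-major layout; the base-pair encoder uses the chromosome-per-row
#' layout (a single-chromosome panel makes the two coincide).
#'
#' @param d a [genotype_dataset()].
#' @param encoder `"cc"`, `"chen"` or `"yue"`.
#' @param layout optional `snp_layout`; defaults as described above.
#' @return A `genotype_image_set`: list with `x` (pixel matrix), `labels`,
#'   `sample_ids`, `layout`, `encoder`, `side`, `channels`.
#' @export
encode_dataset <- function(d, encoder = c("cc", "chen", "yue"), layout = NULL) {
  encoder <- match.arg(encoder)
  stopifnot(inherits(d, "genotype_dataset"))
  m <- ncol(d$genotypes)
  if (is.null(layout)) {
    layout <- if (encoder == "yue") {
      lens <- as.vector(table(factor(d$snps$chrom, levels = unique(d$snps$chrom))))
      layout_chromosome_rows(lens, snp_ids = d$snps$snp_id)
    } else {
      layout_end_to_end(m, snp_ids = d$snps$snp_id)
    }
  }
  n <- nrow(d$genotypes)
  ch <- if (encoder == "cc") 3L else 1L
  x <- matrix(0L, layout$side^2 * ch, n)
  alle <- d$snps[, c("allele_major", "allele_minor")]
  for (i in seq_len(n)) {
    img <- encode_genotypes(d$genotypes[i, ], layout, encoder,
                            alleles = alle, sample_id = d$sample_ids[i],
                            label = as.character(d$labels[i]))
    x[, i] <- as.integer(img$pixels)
  }
  structure(list(x = x, labels = d$labels, sample_ids = d$sample_ids,
                 layout = layout, encoder = encoder, side = layout$side,
                 channels = ch),
            class = "genotype_image_set")
}

#' @export
print.genotype_image_set <- function(x, ...) {
  cat("Image set (", x$encoder, "): ", length(x$labels), " images of ",
      x$side, " x ", x$side, " x ", x$channels, "\n", sep = "")
  invisible(x)
}

#' Extract one image from an image set
#'
#' @param set a `genotype_image_set`.
#' @param i sample index.
#' @return A `genotype_image`.
#' @export
get_image <- function(set, i) {
  stopifnot(inherits(set, "genotype_image_set"), i >= 1, i <= length(set$labels))
  px <- array(set$x[, i], c(set$side, set$side, set$channels))
  structure(list(pixels = px, encoder = set$encoder, side = set$side,
                 channels = set$channels, sample_id = set$sample_ids[i],
                 label = as.character(set$labels[i])),
            class = "genotype_image")
}
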