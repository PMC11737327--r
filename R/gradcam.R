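# Bilinear upsampling of a square matrix (cell-centre alignment).
upsample_bilinear <- function(A, side_out) {
  side_in <- nrow(A)
  if (side_in == side_out) return(A)
  pos <- (seq_len(side_out) - 0.5) * side_in / side_out - 0.5
  pos <- pmin(pmax(pos, 0), side_in - 1)
  lo <- floor(pos); hi <- pmin(lo + 1, side_in - 1); w <- pos - lo
  lo <- lo + 1; hi <- hi + 1
  # rows then columns
  Ar <- A[lo, , drop = FALSE] * (1 - w) + A[hi, , drop = FALSE] * w
  Ar[, lo, drop = FALSE] * rep(1 - w, each = side_out) +
    Ar[, hi, drop = FALSE] * rep(w, each = side_out)
}

#' Grad-CAM attribution map for one image
#'
#' Gradient-weighted class activation mapping at the last convolutional
#' layer: with activations `A^k` (post-ReLU) of channel `k`, the channel
#' weights are `alpha_k = ` spatial mean of the gradient of the target
#' class score with respect to `A^k`; the map is
#' `ReLU(sum_k alpha_k A^k)`, bilinearly upsampled to the input
#' resolution. Entries are nonnegative by construction.
#'
#' The class score is the target class's logit minus the other class's
#' logit (the log-odds). In a two-way softmax only this difference is
#' identified — adding any shared component to both logits leaves the
#' classifier unchanged — so gradients of a raw logit would carry an
#' arbitrary non-discriminative term, while log-odds gradients are
#' well-defined class evidence.
#'
#' @param model a trained `geno_cnn`.
#' @param image a `genotype_image`, pixel vector or 1-column matrix.
#' @param target_class class whose evidence is mapped (default `"case"`).
#' @return A `cam_map`: list with `grid` (input side x side, >= 0) and
#'   `sample_id`.
#' @export
gradcam <- function(model, image, target_class = "case") {
  stopifnot(inherits(model, "geno_cnn"))
  cls <- match(target_class, model$levels)
  if (is.na(cls)) stop("unknown target class '", target_class, "'")
  sid <- if (inherits(image, "genotype_image")) image$sample_id else NA_character_
  X <- as_pixel_matrix(image)
  stopifnot(ncol(X) == 1)
  fwd <- cnn_forward(model, X)
  s3 <- model$dims$sides[3]; f3 <- model$dims$chans[4]
  # d(log-odds of cls)/d(flattened pooled activations), routed through pool 3
  g_flat <- matrix(model$weights$Wd[cls, ] - model$weights$Wd[3 - cls, ],
                   ncol = 1)
  dA3 <- maxpool2_backward(g_flat, fwd$caches[[3]]$argmax, s3, s3, f3)
  dA3 <- matrix(dA3, s3 * s3, f3)
  alpha <- colMeans(dA3)
  A3 <- matrix(fwd$caches[[3]]$act, s3 * s3, f3)
  cam <- matrix(pmax(A3 %*% alpha, 0), s3, s3)
  grid <- upsample_bilinear(cam, model$config$input_side)
  structure(list(grid = grid, sample_id = sid), class = "cam_map")
}

#' Accumulate Grad-CAM maps over predicted cases
#'
#' Sums the Grad-CAM maps of exactly those samples the model
#' *predicts* as cases (regardless of their true label) — the screening
#' signal is built from what the classifier relies on when it calls a
#' sample diseased.
#'
#' @param model a trained `geno_cnn`.
#' @param images a `genotype_image_set` or pixel matrix.
#' @return The accumulated grid (input side x side) with attribute
#'   `n_predicted_cases`.
#' @export
accumulate_cams <- function(model, images) {
  X <- as_pixel_matrix(images)
  if (ncol(X) == 0) stop("image set must be non-empty")
  pred <- predict(model, X)
  case_idx <- which(pred == "case")
  if (length(case_idx) == 0)
    stop(errorCondition("no test sample is predicted as a case; nothing to screen",
                        class = c("no_predicted_cases", "error", "condition")))
  s <- model$config$input_side
  acc <- matrix(0, s, s)
  for (i in case_idx) {
    acc <- acc + gradcam(model, X[, i, drop = FALSE])$grid
  }
  attr(acc, "n_predicted_cases") <- length(case_idx)
  acc
}

#' Min-max normalize an accumulated attribution grid
#'
#' `(x - min) / (max - min)`, giving per-pixel contributions in `[0, 1]`.
#' A constant grid normalizes to all ones with attribute
#' `degenerate = TRUE` (every SNP stays selection-eligible).
#'
#' @param grid nonnegative matrix.
#' @return Matrix in `[0, 1]`.
#' @export
normalize_weights <- function(grid) {
  stopifnot(is.matrix(grid), all(grid >= 0))
  rng <- range(grid)
  if (rng[1] == rng[2]) {
    out <- matrix(1, nrow(grid), ncol(grid))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (grid - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- FALSE
  out
}

#' Map pixel weights back to SNP weights
#'
#' Each SNP inherits the weight of its layout cell; padding cells carry
#' no SNP and are dropped.
#'
#' @param grid normalized weight matrix (side x side).
#' @param layout the `snp_layout` used for encoding.
#' @return Named numeric vector of per-SNP weights in layout SNP order.
#' @export
pixel_weights_to_snps <- function(grid, layout) {
  stopifnot(inherits(layout, "snp_layout"))
  if (nrow(grid) != layout$side || ncol(grid) != layout$side)
    stop("grid side (", nrow(grid), ") does not match layout side (",
         layout$side, ")")
  w <- grid[cbind(layout$row, layout$col)]
  names(w) <- layout$snp_ids
  w
}

#' Select the top fraction of SNPs by weight
#'
#' Takes `ceiling(fraction * n)` SNPs sorted by weight descending, ties
#' broken by ascending SNP index for reproducibility.
#'
#' @param weights per-SNP weights (named or not).
#' @param fraction fraction in `(0, 1]`; default the classic top 5%.
#' @return `data.frame` with `rank`, `snp_index`, `snp_id`, `weight`.
#' @export
select_top <- function(weights, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- length(weights)
  k <- ceiling(fraction * n)
  ord <- order(-weights, seq_len(n))[seq_len(k)]
  data.frame(rank = seq_len(k), snp_index = ord,
             snp_id = names(weights)[ord] %||% sprintf("snp%05d", ord),
             weight = unname(weights[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

read_annotation <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1) {
    annotation <- data.table::fread(annotation, sep = "\t", header = TRUE,
                                    data.table = FALSE)
  }
  stopifnot(is.data.frame(annotation))
  names(annotation)[1:2] <- c("snp_id", "gene")
  annotation
}

read_gene_list <- function(reference) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) reference <- readLines(reference)
  unique(reference[nzchar(reference)])
}

#' Gene-level annotation and risk-gene ratio of a SNP selection
#'
#' Maps selected SNPs to genes via an offline SNP-to-gene annotation
#' table, drops unannotated SNPs from the gene-level report (they remain
#' in the SNP table), deduplicates genes, and scores the selection as
#' `risk-gene ratio = |genes in reference| / |genes|` against an offline
#' reference disease-gene list.
#'
#' @param selected `data.frame` from [select_top()].
#' @param annotation TSV path or `data.frame` with columns `snp_id`,
#'   `gene` (one row per pair).
#' @param reference_genes path to a one-symbol-per-line file, or a
#'   character vector of reference risk genes.
#' @return A `screen_report`: `snp_table` (selection plus `gene`),
#'   `genes`, `genes_in_reference`, `risk_gene_ratio` (`NA` when no
#'   selected SNP is annotated), `n_selected`, `n_annotated`.
#' @export
annotate_and_score <- function(selected, annotation, reference_genes) {
  ann <- read_annotation(annotation)
  ref <- read_gene_list(reference_genes)
  if (nrow(ann) == 0) warning("empty annotation: gene-level report is empty")
  snp_table <- selected
  snp_table$gene <- ann$gene[match(snp_table$snp_id, ann$snp_id)]
  genes <- unique(snp_table$gene[!is.na(snp_table$gene)])
  hits <- intersect(genes, ref)
  ratio <- if (length(genes) == 0) NA_real_ else length(hits) / length(genes)
  if (length(genes) == 0)
    message("no selected SNP has a gene annotation; risk-gene ratio is NA")
  structure(list(snp_table = snp_table, genes = genes,
                 genes_in_reference = hits, risk_gene_ratio = ratio,
                 n_selected = nrow(snp_table),
                 n_annotated = sum(!is.na(snp_table$gene))),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Risk-SNP screen: ", x$n_selected, " SNPs selected, ",
      x$n_annotated, " with gene annotation, ", length(x$genes),
      " distinct genes\n", sep = "")
  if (is.na(x$risk_gene_ratio)) cat("  risk-gene ratio: not applicable\n")
  else cat(sprintf("  risk-gene ratio: %d / %d = %.3f\n",
                   length(x$genes_in_reference), length(x$genes),
                   x$risk_gene_ratio))
  invisible(x)
}

#' End-to-end Grad-CAM risk-SNP screen
#'
#' Runs the whole screening stage on a test set: accumulate Grad-CAM
#' maps over predicted cases, min-max normalize to a weight matrix, map
#' pixel weights to SNPs through the layout, select the top fraction,
#' and (optionally) annotate and score against a reference gene list.
#' Deterministic given the trained model and test set.
#'
#' @param model a trained `geno_cnn`.
#' @param images a `genotype_image_set` (its layout is used unless
#'   `layout` is supplied).
#' @param layout optional `snp_layout` override.
#' @param fraction selection fraction (default 0.05).
#' @param annotation,reference_genes optional; see [annotate_and_score()].
#' @return A `snp_screen` list: `weights` (all SNPs), `selected`
#'   (from [select_top()]), `report` (a `screen_report` or `NULL`),
#'   `degenerate`, `n_predicted_cases`.
#' @export
screen_risk_snps <- function(model, images, layout = NULL, fraction = 0.05,
                             annotation = NULL, reference_genes = NULL) {
  if (is.null(layout) && inherits(images, "genotype_image_set"))
    layout <- images$layout
  if (is.null(layout)) stop("a `snp_layout` is required")
  acc <- accumulate_cams(model, images)
  norm <- normalize_weights(acc)
  w <- pixel_weights_to_snps(norm, layout)
  sel <- select_top(w, fraction)
  report <- if (!is.null(annotation) && !is.null(reference_genes))
    annotate_and_score(sel, annotation, reference_genes) else NULL
  structure(list(weights = w, selected = sel, report = report,
                 degenerate = isTRUE(attr(norm, "degenerate")),
                 n_predicted_cases = attr(acc, "n_predicted_cases")),
            class = "snp_screen")
}

#' @export
print.snp_screen <- function(x, ...) {
  cat("SNP screen over ", x$n_predicted_cases, " predicted cases: top ",
      nrow(x$selected), " of ", length(x$weights), " SNPs\n", sep = "")
  print(head(x$selected, 5), row.names = FALSE)
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Write a screen's per-SNP table as TSV
#'
#' Columns: `snp_id`, `weight`, `rank` (NA when unselected), `selected`,
#' `gene` (when annotated).
#'
#' @param screen a `snp_screen`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(screen, path) {
  stopifnot(inherits(screen, "snp_screen"))
  tab <- data.frame(snp_id = names(screen$weights),
                    weight = unname(screen$weights),
                    rank = NA_integer_, selected = FALSE,
                    stringsAsFactors = FALSE)
  tab$rank[screen$selected$snp_index] <- screen$selected$rank
  tab$selected[screen$selected$snp_index] <- TRUE
  if (!is.null(screen$report)) {
    tab$gene <- screen$report$snp_table$gene[
      match(tab$snp_id, screen$report$snp_table$snp_id)]
  }
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}
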