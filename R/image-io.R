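#' Lossless image file I/O
#'
#' Images are written as 8-bit PNG (lossless); a write/read round trip
#' reproduces the pixel grid exactly. Requesting a lossy format is
#' refused.
#'
#' @param img a `genotype_image`.
#' @param path output path; must end in `.png`.
#' @return `write_image()` returns `path` invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "genotype_image"))
  if (!grepl("\\.png$", path, ignore.case = TRUE))
    stop("only lossless PNG output is supported; got '", path, "'")
  px <- img$pixels / 255
  if (img$channels == 1L) px <- px[, , 1]
  png::writePNG(px, path)
  invisible(path)
}

#' @rdname write_image
#' @param encoder encoder id recorded in the returned image.
#' @param sample_id,label metadata carried into the returned image.
#' @export
read_image <- function(path, encoder = c("cc", "chen", "yue"),
                       sample_id = NA_character_, label = NA_character_) {
  encoder <- match.arg(encoder)
  px <- png::readPNG(path)
  px <- round(px * 255)
  if (length(dim(px)) == 2) {
    px <- array(as.integer(px), c(dim(px), 1L))
  } else {
    if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]  # drop alpha
    px <- array(as.integer(px), dim(px))
  }
  want_ch <- if (encoder == "cc") 3L else 1L
  if (dim(px)[3] != want_ch)
    stop("image has ", dim(px)[3], " channel(s); encoder '", encoder,
         "' expects ", want_ch)
  if (dim(px)[1] != dim(px)[2]) stop("image is not square")
  structure(list(pixels = px, encoder = encoder, side = dim(px)[1],
                 channels = want_ch, sample_id = sample_id, label = label),
            class = "genotype_image")
}

#' Write an image set to disk with a manifest
#'
#' Writes one PNG per sample plus `manifest.tsv` (columns `sample_id`,
#' `label`, `path`, `encoder`, `side`, `channels`) and `layout.tsv`. The
#' manifest is the hand-off between the encoding and training stages.
#'
#' @param set a `genotype_image_set`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_image_set <- function(set, dir) {
  stopifnot(inherits(set, "genotype_image_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(set$labels)
  paths <- file.path(dir, paste0(set$sample_ids, ".png"))
  for (i in seq_len(n)) write_image(get_image(set, i), paths[i])
  man <- data.frame(sample_id = set$sample_ids,
                    label = as.character(set$labels),
                    path = basename(paths),
                    encoder = set$encoder, side = set$side,
                    channels = set$channels, stringsAsFactors = FALSE)
  man_path <- file.path(dir, "manifest.tsv")
  data.table::fwrite(man, man_path, sep = "\t")
  write_layout(set$layout, file.path(dir, "layout.tsv"))
  invisible(man_path)
}

#' Read an image set back from a manifest
#'
#' @param manifest_path path to a `manifest.tsv` written by
#'   [write_image_set()]; images and `layout.tsv` are resolved relative
#'   to it.
#' @return A `genotype_image_set`.
#' @export
read_image_set <- function(manifest_path) {
  man <- data.table::fread(manifest_path, sep = "\t", header = TRUE,
                           colClasses = list(character = "sample_id"))
  dir <- dirname(manifest_path)
  encoder <- man$encoder[1]
  side <- man$side[1]; ch <- man$channels[1]
  n <- nrow(man)
  x <- matrix(0L, side * side * ch, n)
  for (i in seq_len(n)) {
    img <- read_image(file.path(dir, man$path[i]), encoder = encoder,
                      sample_id = man$sample_id[i], label = man$label[i])
    if (img$side != side) stop("image side mismatch at ", man$path[i])
    x[, i] <- as.integer(img$pixels)
  }
  layout_path <- file.path(dir, "layout.tsv")
  layout <- if (file.exists(layout_path)) read_layout(layout_path) else NULL
  structure(list(x = x,
                 labels = factor(man$label, levels = c("control", "case")),
                 sample_ids = man$sample_id, layout = layout,
                 encoder = encoder, side = side, channels = ch),
            class = "genotype_image_set")
}
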