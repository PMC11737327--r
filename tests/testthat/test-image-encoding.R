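test_that("side_length returns the minimal square side", {
  expect_identical(side_length(2000), 45L)
  expect_identical(side_length(6492), 81L)
  expect_identical(side_length(25220), 159L)
  expect_identical(side_length(1), 1L)
  expect_identical(side_length(4), 2L)
  expect_identical(side_length(5), 3L)
  expect_error(side_length(0), "positive")
  # (s-1)^2 < n <= s^2 over a range of n
  for (n in c(1:100, sample.int(10^6, 50))) {
    s <- side_length(n)
    expect_true((s - 1)^2 < n && n <= s^2, info = paste("n =", n))
  }
})

test_that("end-to-end layout is row-major with tail padding", {
  l <- layout_end_to_end(4, 2)
  expect_identical(l$row, c(1L, 1L, 2L, 2L))
  expect_identical(l$col, c(1L, 2L, 1L, 2L))
  expect_false(any(l$padding_mask))

  l2 <- layout_end_to_end(2000, 45)
  expect_identical(sum(l2$padding_mask), 25L)  # 45^2 - 2000
  expect_true(all(l2$padding_mask[45, (45 - 24):45]))
  expect_error(layout_end_to_end(10, 3), "too small")
})

test_that("layouts are bijections between SNPs and non-padding cells", {
  for (n in c(1, 7, 50, 400)) {
    l <- layout_end_to_end(n)
    cells <- paste(l$row, l$col)
    expect_identical(anyDuplicated(cells), 0L)
    expect_identical(sum(!l$padding_mask), as.integer(n))
    # snp_at(cell(i)) = i round trip
    grid <- matrix(NA_integer_, l$side, l$side)
    grid[cbind(l$row, l$col)] <- seq_len(n)
    expect_identical(grid[cbind(l$row, l$col)], seq_len(as.integer(n)))
  }
})

test_that("chromosome-rows layout starts each chromosome on a fresh row", {
  # single chromosome degenerates to end-to-end
  l1 <- layout_chromosome_rows(2000, 45)
  l2 <- layout_end_to_end(2000, 45)
  expect_identical(l1$row, l2$row)
  expect_identical(l1$col, l2$col)

  # two chromosomes of 3 SNPs on side 3: rows 1-2 full, row 3 padding
  l3 <- layout_chromosome_rows(c(3, 3), 3)
  expect_identical(l3$row, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_identical(l3$col, rep(1:3, 2))
  expect_true(all(l3$padding_mask[3, ]))

  # (4, 4) needs ceiling(4/3) * 2 = 4 rows of width 3: infeasible
  expect_error(layout_chromosome_rows(c(4, 4), 3), "minimal feasible side is 4")
  l4 <- layout_chromosome_rows(c(4, 4))
  expect_identical(l4$side, 4L)
  expect_identical(l4$row, rep(c(1L, 2L), each = 4))
})

test_that("color encoding uses the documented palette", {
  expect_identical(unname(cc_palette["AA", ]), c(0L, 0L, 255L))
  expect_identical(unname(cc_palette["Aa", ]), c(0L, 170L, 0L))
  expect_identical(unname(cc_palette["aa", ]), c(85L, 0L, 0L))

  l <- layout_end_to_end(4, 2)
  img <- encode_genotypes(c(0L, 1L, 2L, -1L), l, "cc")
  expect_identical(img$channels, 3L)
  expect_identical(img$pixels[1, 1, ], c(0L, 0L, 255L))
  expect_identical(img$pixels[1, 2, ], c(0L, 170L, 0L))
  expect_identical(img$pixels[2, 1, ], c(85L, 0L, 0L))
  expect_identical(img$pixels[2, 2, ], c(0L, 0L, 0L))  # missing -> black

  # all-AA sample is a uniform blue image
  blue <- encode_genotypes(rep(0L, 4), l, "cc")
  expect_true(all(blue$pixels[, , 3] == 255L))
  expect_true(all(blue$pixels[, , 1:2] == 0L))
})

test_that("grayscale dosage encoding collides AA with padding by design", {
  expect_identical(unname(chen_palette), c(0L, 154L, 254L))
  l <- layout_end_to_end(3, 2)  # one padding cell
  img <- encode_genotypes(c(0L, 1L, 2L), l, "chen")
  expect_identical(img$channels, 1L)
  expect_identical(img$pixels[1, 2, 1], 154L)
  expect_identical(img$pixels[2, 1, 1], 254L)
  # all-AA image is indistinguishable from all-padding
  aa <- encode_genotypes(rep(0L, 3), l, "chen")
  expect_true(all(aa$pixels == 0L))
})

test_that("base-pair encoding maps the ten classes to 25..250", {
  expect_identical(yue_class("A", "A"), 1L)
  expect_identical(yue_class("T", "T"), 10L)
  # heterozygote order-insensitivity
  expect_identical(yue_class("C", "A"), yue_class("A", "C"))
  expect_error(yue_class("A", "N"), "invalid base")

  l <- layout_chromosome_rows(4, 2)
  alle <- data.frame(allele_major = c("A", "G", "T", "A"),
                     allele_minor = c("C", "T", "G", "C"))
  img <- encode_genotypes(c(0L, 1L, 2L, -1L), l, "yue", alleles = alle)
  expect_identical(img$pixels[1, 1, 1], 25L * yue_class("A", "A"))   # 25
  expect_identical(img$pixels[1, 2, 1], 25L * yue_class("G", "T"))
  expect_identical(img$pixels[2, 1, 1], 25L * yue_class("G", "G"))
  expect_identical(img$pixels[2, 2, 1], 0L)  # missing -> padding

  # biallelic A/C data occupies only 3 of the 10 classes
  d <- simulate_genotypes(simulation_spec(
    n_cases = 10, n_controls = 10, n_null_snps = 9, n_risk_snps = 0, seed = 2))
  set <- encode_dataset(d, "yue")
  vals <- setdiff(unique(as.vector(set$x)), 0L)
  expect_true(all(vals %in% (25L * c(yue_class("A", "A"), yue_class("A", "C"),
                                     yue_class("C", "C")))))
})

test_that("decode inverts encode for every encoder", {
  set.seed(7)
  l <- layout_end_to_end(40, 7)
  codes <- sample(c(-1L, 0L, 1L, 2L), 40, replace = TRUE)
  # color palette is bijective, missing included
  expect_identical(decode_image(encode_genotypes(codes, l, "cc"), l), codes)
  # grayscale dosage is exact on non-missing codes (missing decodes as AA)
  dec <- decode_image(encode_genotypes(codes, l, "chen"), l)
  expect_identical(unname(dec[codes >= 0]), codes[codes >= 0])
  expect_true(all(dec[codes == -1L] == 0L))
  expect_true(attr(dec, "collision"))
  # base pairs decode through the allele table
  alle <- data.frame(allele_major = rep("A", 40), allele_minor = rep("G", 40))
  decy <- decode_image(encode_genotypes(codes, l, "yue", alleles = alle), l,
                       alleles = alle)
  expect_identical(as.integer(decy), codes)
  # encode -> decode -> encode is a fixed point
  img <- encode_genotypes(codes, l, "cc")
  expect_identical(encode_genotypes(decode_image(img, l), l, "cc")$pixels,
                   img$pixels)
})

test_that("unknown pixel values are palette errors", {
  l <- layout_end_to_end(4, 2)
  img <- encode_genotypes(c(0L, 1L, 2L, 0L), l, "cc")
  img$pixels[1, 1, ] <- c(1L, 2L, 3L)
  expect_error(decode_image(img, l), "palette")
  img2 <- encode_genotypes(c(0L, 1L, 2L, 0L), l, "chen")
  img2$pixels[1, 1, 1] <- 7L
  expect_error(decode_image(img2, l), "palette")
})

test_that("palette separation: color distinct everywhere, one gray collision", {
  states <- rbind(cc_palette, padding = c(0L, 0L, 0L))
  dists <- as.matrix(dist(states, method = "maximum"))
  expect_true(all(dists[upper.tri(dists)] > 0))
  gray <- c(chen_palette, padding = 0L)
  collisions <- sum(outer(gray, gray, "==")[upper.tri(diag(4))])
  expect_identical(collisions, 1L)
})

test_that("PNG image I/O is byte-lossless and refuses lossy formats", {
  l <- layout_end_to_end(9, 3)
  codes <- c(0L, 1L, 2L, -1L, 0L, 1L, 2L, 0L, 1L)
  img <- encode_genotypes(codes, l, "cc", sample_id = "S1", label = "case")
  path <- withr::local_tempfile(fileext = ".png")
  write_image(img, path)
  back <- read_image(path, "cc")
  expect_identical(back$pixels, img$pixels)
  expect_error(write_image(img, sub("png$", "jpg", path)), "lossless")

  gimg <- encode_genotypes(codes, l, "chen")
  gpath <- withr::local_tempfile(fileext = ".png")
  write_image(gimg, gpath)
  expect_identical(read_image(gpath, "chen")$pixels, gimg$pixels)
})

test_that("image sets round-trip through manifest directories", {
  d <- simulate_genotypes(simulation_spec(
    n_cases = 5, n_controls = 5, n_null_snps = 8, n_risk_snps = 1, seed = 3))
  set <- encode_dataset(d, "cc")
  dir <- withr::local_tempdir()
  man <- write_image_set(set, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- read_image_set(file.path(dir, "manifest.tsv"))
  expect_identical(back$x, set$x)
  expect_identical(as.character(back$labels), as.character(set$labels))
  expect_identical(back$sample_ids, set$sample_ids)
  expect_identical(back$layout$row, set$layout$row)
})

test_that("layout TSV serialization round-trips", {
  l <- layout_chromosome_rows(c(5, 4), snp_ids = sprintf("rs%d", 1:9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_layout(l, path)
  l2 <- read_layout(path)
  expect_identical(l2$side, l$side)
  expect_identical(l2$row, l$row)
  expect_identical(l2$col, l$col)
  expect_identical(l2$snp_ids, l$snp_ids)
})
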