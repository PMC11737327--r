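---
title: "Genotype images, convolutional classifiers and Grad-CAM SNP screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype images, convolutional classifiers and Grad-CAM SNP screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gwascnn)
```

## The problem

A case/control genome-wide association study (GWAS) types thousands to
millions of biallelic SNPs, each coded by minor-allele dosage:
0 = major homozygote (AA), 1 = heterozygote (Aa), 2 = minor homozygote
(aa). Convolutional neural networks (CNNs) handle grid-shaped inputs, so
applying them to GWAS requires laying the per-sample genotype vector out
on a square pixel grid. `gwascnn` implements three such encodings, a CNN
case/control classifier over the resulting images, and a
Grad-CAM-based screen that ranks SNPs by their contribution to the
"case" decision.

## Genotype-to-image encodings

All encoders share the same geometry: `side_length(m)` returns the
smallest `s` with `s^2 >= m`, so 2,000 SNPs occupy a 45 x 45 grid,
6,492 an 81 x 81, and 25,220 a 159 x 159. Cells beyond the last SNP are
padding with pixel value 0.

* **Color (`cc`)** — AA, Aa, aa map to RGB triples (0, 0, 255),
  (0, 170, 0) and (85, 0, 0): each genotype class enters a *different*
  color channel, so the first convolution assigns each class its own
  weights, and no genotype collides with the black padding.
  Chromosomes are concatenated end to end in row-major order.
* **Grayscale dosage (`chen`)** — AA, Aa, aa map to gray values 0, 154,
  254. The AA value collides with padding by construction; the package
  preserves this faithfully (it is the documented weakness that the
  color encoding removes).
* **Grayscale base pairs (`yue`)** — the ten unordered base pairs over
  {A, C, G, T} are ranked lexicographically (AA, AC, AG, AT, CC, CG,
  CT, GG, GT, TT) as classes 1..10 and multiplied by 25. Which pair
  gets which integer is not standardized anywhere; the lexicographic
  rule is deterministic and any fixed bijection carries the same
  information. This encoder uses the chromosome-per-row layout (each
  chromosome starts a fresh row); with a single simulated chromosome it
  coincides with the end-to-end layout.

Missing genotypes render as the padding value in every encoder and are
flagged on decoding. Images are stored as exact 8-bit integers; PNG I/O
is lossless, and scaling to [0, 1] happens only at the model boundary so
that files and in-memory sets stay bit-identical.

## The simulator

`simulate_genotypes()` emulates a PLINK-style case/control simulation:

* Each SNP draws a MAF `q` uniformly from [0.05, 0.5] (configurable).
* Controls draw genotypes from Hardy-Weinberg proportions
  `((1-q)^2, 2q(1-q), q^2)` — the rare-disease approximation of the
  population distribution.
* Cases draw from the retrospective distribution
  `P(g | case) ∝ P(g) · RR(g)` with `RR = (1, rr_het, rr_hom)`.
  The default risk model is multiplicative, `rr_hom = rr_het^2` with
  `rr_het = 1.5`.
* Risk SNPs occupy **one contiguous block** at a seeded random
  position. This mirrors PLINK's `--simulate`, which writes each
  configured SNP set out as a consecutive run, and it matters: a
  convolutional classifier can exploit a spatially coherent risk region,
  whereas risk SNPs scattered uniformly over the image can only be used
  through translation-invariant statistics (see *Limitations*).
* Missing genotypes are planted independently at a configurable rate
  (default 0).

The default dimensions — 4,000 cases + 4,000 controls by 2,000 SNPs with
200 risk SNPs, ten replicate sets — are the standard simulated benchmark
this package targets. Effect sizes, MAF ranges and prevalence for that
benchmark are not published anywhere, so the defaults above are this
package's own choice of a realistic regime; published headline
accuracies near 0.97 imply considerably stronger effects than
`rr_het = 1.5`.

Quality control follows standard GWAS practice, in a fixed order:
individuals with > 5% missing genotypes, then SNPs with > 5%
missingness, MAF < 5% (on all samples), and Hardy-Weinberg
`p < 0.01` computed **on controls only** (risk effects legitimately
distort case genotype frequencies). The association pre-screen is the
1-df allelic chi-square on the 2 x 2 allele-count table without
continuity correction (the classic PLINK `--assoc` statistic);
monomorphic SNPs report `p = 1` with a flag rather than erroring
mid-pipeline. The Hardy-Weinberg test is the 1-df chi-square rather than
the exact test — it matches the scale of the pre-screen and is fully
specified; an exact-test upgrade would be a natural extension.

## The classifier

The architecture is deliberately small and fixed:

```
[conv(k x k, 'same') -> ReLU -> maxpool(2x2, stride 2)] x 3
 -> dropout -> flatten -> dense -> 2-way softmax
```

All three convolutions share one kernel size `k`. Training is minibatch
SGD with momentum on cross-entropy plus an L2 weight penalty, at most 60
epochs, returning the weight snapshot with the best validation accuracy.
Data are split 6:2:2 into train/validation/test, stratified by label.
Four hyperparameters are tunable, with `bayes_optimize()` searching
their box by a Gaussian-process surrogate and expected improvement
(Latin-hypercube initial design; learning rate and L2 on the log scale;
the categorical kernel size snapped to its levels):

| parameter      | range            | scale  | default |
|----------------|------------------|--------|---------|
| `filter_size`  | {3, 5, 7}        | —      | 5       |
| `learning_rate`| [1e-3, 1]        | log10  | 0.01    |
| `momentum`     | [0.9, 0.98]      | linear | 0.9     |
| `l2`           | [1e-10, 1e-2]    | log10  | 1e-6    |

Everything the architecture leaves open is a configurable, logged
default: filter counts (32, 64, 128), dropout 0.5 on the last
convolutional layer, ReLU nonlinearity, 'same' padding, batch size 128,
He-normal initialization, a 20-trial optimization budget, and
early stopping after 15 epochs without validation improvement
(set `patience = max_epochs` to disable). Pixel values are divided by
255 at the model input. Precision/recall/F1 use "case" as the positive
class and are defined as 0 (with a warning) when their denominator is 0.

The forward/backward passes are implemented in the package (Rcpp
im2col/col2im/max-pool kernels plus BLAS matrix products) and verified
against numerical gradients in the test suite; training is
bit-reproducible under a fixed seed and a fixed BLAS.

### Scaled-down benchmark sizes

The test suite exercises the full pipeline at a fifth of the standard
benchmark: 2,000 samples by 400 SNPs (risk block of 40, `rr_het = 2`),
20 x 20 images, filter counts (8, 16, 32) (a quarter of the full-scale
default, matching the smaller panel) and batch size 32 — 1,200 training
images at batch 32 give ~38 SGD updates per epoch, the same update
count per epoch as 4,800 images at batch 128. Under these conditions
the data's Bayes accuracy is ≈ 0.91, a logistic-regression oracle on
the raw dosages reaches ≈ 0.90, and the color-encoded CNN reaches
0.83–0.88 depending on the seed — a few points below the linear oracle,
the price of max-pooling's within-window information loss at this small
image size.

## Grad-CAM SNP screening

For test samples the trained model *predicts* as cases (regardless of
their true label), the package computes gradient-weighted class
activation maps at the last convolutional layer: with post-ReLU
activations `A^k`, channel weights `alpha_k` are the spatial mean of
`d(score)/dA^k`, and the map is `ReLU(sum_k alpha_k A^k)`, bilinearly
upsampled to input resolution.

The *score* is the log-odds, `logit(case) - logit(control)`. In a
two-way softmax only this difference is identified — adding any shared
function of the input to both logits leaves the classifier unchanged —
so gradients of a single raw logit would carry an arbitrary,
non-discriminative component. The log-odds gradient is the well-defined
"evidence for case".

Per-sample maps are accumulated first and min-max normalized once
(`(x - min)/(max - min)`); per-sample normalization would re-weight
samples and is deliberately not done. A constant accumulated map
normalizes to all ones with a `degenerate` flag, keeping every SNP
selection-eligible instead of dividing by zero. Each SNP inherits its
layout cell's weight; padding cells carry none. The top
`ceiling(0.05 m)` SNPs are selected, ties broken by ascending SNP index
so results are reproducible. Gene-level reporting maps selected SNPs
through an offline SNP-to-gene TSV (selected SNPs without a gene stay
in the SNP table but leave the gene level), deduplicates genes, and
scores `risk-gene ratio = |genes in reference| / |genes|` against an
offline reference list; with no annotated selection the ratio is
reported as not applicable. No online database is ever queried — the
equivalent published counts depend on database snapshots and would not
be reproducible.

## The pipeline

`run_simulate() -> run_encode() -> run_train() -> run_screen()` (or
`run_all()`, or the `inst/cli/gwascnn` script) communicate only through
files in the run directory — datasets as PLINK text plus a TSV dialect,
images as a manifest with either PNGs or a pixel table, models and JSON
reports — so every stage is resumable and a run directory documents
itself: echoed YAML/JSON config, per-stage log with timestamps, and
explicit seeds (replicate set `i` uses `seed + i - 1`).

## What the simulator does and does not emulate

Passing tests on simulated data show that the machinery — encoding,
optimization, attribution, bookkeeping — behaves as specified under a
known generative model. The simulator draws SNPs independently: there is
no linkage disequilibrium, no population stratification, no relatedness,
no genotyping-batch artifacts, and missingness is uniform rather than
clustered. Real panels after association pre-screening also place
*correlated* SNPs next to each other, which is friendlier to
convolutional models than independent null SNPs. None of the simulated
results therefore quantify performance on real cohorts; they validate
correctness, calibration (type-I error of the allelic test is checked
against its nominal level) and power under the stated model only.

## Limitations

* **Grad-CAM needs spatial headroom.** At the scaled-down 20 x 20
  geometry the third convolution sees a 5 x 5 map with a 5 x 5 kernel:
  every last-layer unit covers the whole image, and the following pool
  discards the map's fifth row and column outright. The attribution map
  then inherits its spatial structure from activations whose peak
  location reflects kernel alignment rather than the risk region, so
  top-5% screening recovery at this scale is unreliable — some seeds
  recover several-fold enrichment, others none. At the 45 x 45 scale
  and above (last conv on 11 x 11, receptive field ≈ ±8 px) the layer
  is genuinely local and the screen behaves as intended. Interpret
  small-image screens with care.
* **Empirical minor-allele coding.** The PLINK text reader determines
  each SNP's major allele by sample majority (ties alphabetical), as
  PLINK itself does; a planted risk SNP whose sample minor-allele
  frequency crosses 0.5 in a case-enriched sample will round-trip with
  flipped homozygote codes.
* The grayscale base-pair encoder applied to strictly biallelic data
  occupies only 3 of its 10 classes; published results in which that
  encoder collapses to chance on simulated data are plausible but not
  reproduced deliberately.
* One published anomaly — a base-pair-encoded simulation run with
  accuracy exactly 0.500 yet precision 0.700 — is internally puzzling
  and out of scope.
* Binary PLINK (.bed), VCF, imputation, covariates, sex chromosomes and
  LD-aware post-processing of the screen are out of scope.
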