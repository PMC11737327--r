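#' Build a pipeline run configuration
#'
#' Assembles the staged pipeline's configuration (simulate -> encode ->
#' train -> screen) with explicit per-stage seeds derived from the master
#' seed. Defaults reproduce the standard simulated benchmark: 10
#' replicate sets of 8,000 samples (4,000 cases, 4,000 controls) by 2,000
#' SNPs with 200 risk SNPs, encoded as 45 x 45 images.
#'
#' @param outdir run output directory.
#' @param seed master seed; replicate set `i` uses `seed + i - 1`.
#' @param simulate,encode,train,screen named lists overriding stage
#'   defaults (see the fields in the returned object).
#' @return A `run_config` list.
#' @export
run_config <- function(outdir = "gwascnn_run", seed = 1L,
                       simulate = list(), encode = list(),
                       train = list(), screen = list()) {
  cfg <- list(
    outdir = outdir, seed = as.integer(seed),
    simulate = modifyList(list(
      sets = 10L, n_cases = 4000L, n_controls = 4000L,
      n_null_snps = 1800L, n_risk_snps = 200L,
      maf_low = 0.05, maf_high = 0.5, rr_het = 1.5, rr_hom = NULL,
      missing_rate = 0), simulate),
    encode = modifyList(list(encoder = "cc", write_png = FALSE), encode),
    train = modifyList(list(
      set = 1L, filter_size = 5, learning_rate = 0.01, momentum = 0.9,
      l2 = 1e-6, conv_filters = c(32L, 64L, 128L), dropout = 0.5,
      batch_size = 128L, max_epochs = 60L, patience = 10L,
      tune = FALSE, tune_trials = 20L), train),
    screen = modifyList(list(
      fraction = 0.05, annotation = NULL, reference_genes = NULL), screen))
  if (is.null(cfg$simulate$rr_hom)) cfg$simulate$rr_hom <- cfg$simulate$rr_het^2
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @param overrides named list merged over the file's values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y <- modifyList(y, overrides)
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

run_log <- function(config, stage, ...) {
  msg <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 stage, paste0(...))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  cat(msg, "\n", file = file.path(config$outdir, "run.log"), append = TRUE)
  message(msg)
}

echo_config <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config),
                       file.path(config$outdir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  write_run_config(config, file.path(config$outdir, "config.yaml"))
}

stage_paths <- function(config, set) {
  d <- config$outdir
  list(tsv = file.path(d, sprintf("dataset_%02d.tsv", set)),
       snps = file.path(d, sprintf("dataset_%02d.snps.tsv", set)),
       ped = file.path(d, sprintf("dataset_%02d.ped", set)),
       map = file.path(d, sprintf("dataset_%02d.map", set)),
       imgdir = file.path(d, sprintf("images_%02d_%s", set,
                                     config$encode$encoder)),
       model = file.path(d, sprintf("model_%02d_%s.rds", set,
                                    config$encode$encoder)),
       report = file.path(d, sprintf("train_report_%02d_%s.json", set,
                                     config$encode$encoder)),
       screen_tsv = file.path(d, sprintf("screen_%02d_%s.tsv", set,
                                         config$encode$encoder)),
       screen_json = file.path(d, sprintf("screen_%02d_%s.json", set,
                                          config$encode$encoder)))
}

#' Pipeline stages
#'
#' Each stage reads its inputs from the run directory (not from memory),
#' so a run is resumable stage by stage; every stage logs to `run.log`
#' and the full configuration is echoed into the run directory.
#' `run_simulate()` writes each replicate dataset as the package TSV
#' dialect plus PLINK .ped/.map; `run_encode()` writes an in-memory or
#' PNG image set with its manifest and layout; `run_train()` fits the CNN
#' (optionally Bayesian-tuned) on the configured set and writes a JSON
#' training report plus the fitted model; `run_screen()` computes the
#' Grad-CAM risk-SNP screen on the test partition.
#'
#' @param config a [run_config()].
#' @param force overwrite existing stage outputs.
#' @return Each stage invisibly returns the paths it wrote; `run_all()`
#'   returns them as a named list.
#' @export
run_simulate <- function(config, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  echo_config(config)
  sc <- config$simulate
  out <- character(0)
  for (i in seq_len(sc$sets)) {
    p <- stage_paths(config, i)
    if (file.exists(p$tsv) && !force)
      stop("output ", p$tsv, " exists; use force = TRUE to overwrite")
    spec <- simulation_spec(sc$n_cases, sc$n_controls, sc$n_null_snps,
                            sc$n_risk_snps, sc$maf_low, sc$maf_high,
                            sc$rr_het, sc$rr_hom, sc$missing_rate,
                            seed = config$seed + i - 1L)
    d <- simulate_genotypes(spec)
    write_geno_tsv(d, p$tsv)
    data.table::fwrite(d$snps, p$snps, sep = "\t")
    write_plink_text(d, p$ped, p$map)
    run_log(config, "simulate", "set ", i, ": ", nrow(d$genotypes),
            " samples x ", ncol(d$genotypes), " SNPs -> ", p$tsv)
    out <- c(out, p$tsv)
  }
  invisible(out)
}

read_stage_dataset <- function(config, set) {
  p <- stage_paths(config, set)
  d <- read_geno_tsv(p$tsv)
  if (file.exists(p$snps)) {
    snps <- data.table::fread(p$snps, sep = "\t", data.table = FALSE)
    d$snps <- snps
  }
  d
}

#' @rdname run_simulate
#' @export
run_encode <- function(config, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  enc <- config$encode$encoder
  out <- character(0)
  for (i in seq_len(config$simulate$sets)) {
    p <- stage_paths(config, i)
    if (!file.exists(p$tsv)) stop("missing dataset ", p$tsv,
                                  "; run run_simulate() first")
    man <- file.path(p$imgdir, "manifest.tsv")
    if (file.exists(man) && !force) {
      run_log(config, "encode", "set ", i, " already encoded; skipping")
      out <- c(out, man); next
    }
    d <- read_stage_dataset(config, i)
    set <- encode_dataset(d, enc)
    if (isTRUE(config$encode$write_png)) {
      write_image_set(set, p$imgdir)
    } else {
      dir.create(p$imgdir, showWarnings = FALSE, recursive = TRUE)
      # matrix-backed set: manifest + layout + one TSV of flattened pixels
      data.table::fwrite(data.table::data.table(
        sample_id = set$sample_ids, label = as.character(set$labels),
        path = NA_character_, encoder = enc, side = set$side,
        channels = set$channels), man, sep = "\t")
      write_layout(set$layout, file.path(p$imgdir, "layout.tsv"))
      data.table::fwrite(data.table::as.data.table(set$x),
                         file.path(p$imgdir, "pixels.tsv"), sep = "\t")
    }
    run_log(config, "encode", "set ", i, " -> ", p$imgdir, " (", enc, ", ",
            set$side, "x", set$side, "x", set$channels, ")")
    out <- c(out, man)
  }
  invisible(out)
}

read_stage_images <- function(config, set) {
  p <- stage_paths(config, set)
  man <- file.path(p$imgdir, "manifest.tsv")
  if (!file.exists(man)) stop("missing manifest ", man,
                              "; run run_encode() first")
  pix <- file.path(p$imgdir, "pixels.tsv")
  if (file.exists(pix)) {
    m <- data.table::fread(man, sep = "\t",
                           colClasses = list(character = "sample_id"))
    x <- as.matrix(data.table::fread(pix, sep = "\t"))
    storage.mode(x) <- "integer"
    structure(list(x = unname(x),
                   labels = factor(m$label, levels = c("control", "case")),
                   sample_ids = m$sample_id,
                   layout = read_layout(file.path(p$imgdir, "layout.tsv")),
                   encoder = m$encoder[1], side = m$side[1],
                   channels = m$channels[1]),
              class = "genotype_image_set")
  } else {
    read_image_set(man)
  }
}

#' @rdname run_simulate
#' @export
run_train <- function(config, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  tc <- config$train
  p <- stage_paths(config, tc$set)
  if (file.exists(p$model) && !force)
    stop("model ", p$model, " exists; use force = TRUE to overwrite")
  images <- read_stage_images(config, tc$set)
  cfg <- cnn_config(images$side, images$channels,
                    conv_filters = tc$conv_filters, dropout = tc$dropout,
                    batch_size = tc$batch_size, max_epochs = tc$max_epochs,
                    patience = tc$patience, seed = config$seed)
  idx <- split_dataset(images$labels, seed = config$seed)
  tune <- NULL
  if (isTRUE(tc$tune)) {
    run_log(config, "train", "Bayesian optimization over ", tc$tune_trials,
            " trials")
    objective <- function(hp) {
      m <- cnn_build(cfg, hp)
      m <- cnn_train(m, images$x[, idx$train, drop = FALSE],
                     images$labels[idx$train],
                     images$x[, idx$val, drop = FALSE],
                     images$labels[idx$val])
      max(m$history$val_accuracy)
    }
    tune <- bayes_optimize(objective, n_trials = tc$tune_trials,
                           seed = config$seed)
    hp <- tune$best_hp
  } else {
    hp <- cnn_hyperparams(tc$filter_size, tc$learning_rate, tc$momentum,
                          tc$l2)
  }
  model <- cnn_build(cfg, hp)
  model <- cnn_train(model, images$x[, idx$train, drop = FALSE],
                     images$labels[idx$train],
                     images$x[, idx$val, drop = FALSE],
                     images$labels[idx$val])
  model$metrics <- cnn_evaluate(model, images$x[, idx$test, drop = FALSE],
                                images$labels[idx$test])
  model$split <- idx
  saveRDS(model, p$model)
  report <- list(
    hyperparams = unclass(hp), config = unclass(cfg)[
      c("input_side", "channels", "conv_filters", "dropout", "batch_size",
        "max_epochs", "patience", "seed")],
    split_sizes = lapply(model$split, length),
    best_epoch = model$best_epoch, history = model$history,
    test_metrics = unclass(model$metrics),
    tuning = if (!is.null(tune)) tune$trials else NULL)
  jsonlite::write_json(report, p$report, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", dataframe = "columns")
  run_log(config, "train", sprintf(
    "set %d (%s): best epoch %d, val acc %.4f, test acc %.4f",
    tc$set, config$encode$encoder, model$best_epoch,
    max(model$history$val_accuracy), model$metrics$accuracy))
  invisible(c(model = p$model, report = p$report))
}

#' @rdname run_simulate
#' @export
run_screen <- function(config, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  tc <- config$train; sc <- config$screen
  p <- stage_paths(config, tc$set)
  if (!file.exists(p$model)) stop("missing model ", p$model,
                                  "; run run_train() first")
  if (file.exists(p$screen_tsv) && !force)
    stop("screen output ", p$screen_tsv, " exists; use force = TRUE")
  model <- readRDS(p$model)
  images <- read_stage_images(config, tc$set)
  test <- model$split$test
  screen <- screen_risk_snps(
    model,
    structure(list(x = images$x[, test, drop = FALSE],
                   labels = images$labels[test],
                   sample_ids = images$sample_ids[test],
                   layout = images$layout, encoder = images$encoder,
                   side = images$side, channels = images$channels),
              class = "genotype_image_set"),
    fraction = sc$fraction,
    annotation = sc$annotation, reference_genes = sc$reference_genes)
  write_screen_tsv(screen, p$screen_tsv)
  summary <- list(fraction = sc$fraction,
                  n_snps = length(screen$weights),
                  n_selected = nrow(screen$selected),
                  n_predicted_cases = screen$n_predicted_cases,
                  degenerate = screen$degenerate,
                  risk_gene_ratio = if (!is.null(screen$report))
                    screen$report$risk_gene_ratio else NULL,
                  n_genes = if (!is.null(screen$report))
                    length(screen$report$genes) else NULL)
  jsonlite::write_json(summary, p$screen_json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  run_log(config, "screen", "set ", tc$set, ": ", nrow(screen$selected),
          " SNPs selected -> ", p$screen_tsv)
  invisible(c(tsv = p$screen_tsv, json = p$screen_json))
}

#' @rdname run_simulate
#' @export
run_all <- function(config, force = FALSE) {
  t0 <- Sys.time()
  sim <- run_simulate(config, force = force)
  enc <- run_encode(config, force = force)
  tr <- run_train(config, force = force)
  scr <- run_screen(config, force = force)
  run_log(config, "run_all", sprintf("completed in %.1f s",
                                     as.numeric(Sys.time() - t0, units = "secs")))
  invisible(list(simulate = sim, encode = enc, train = tr, screen = scr))
}
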