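## End-to-end orchestration: fixtures -> QSAR -> pre-training ->
## fine-tuning -> reinforcement learning -> evaluation, with per-stage
## checkpoints so a run can resume after deleting any stage output.
## One global seed fans out to per-stage seeds through fixed offsets
## (stage i uses seed + 1000 * i), recorded in the run manifest.

.pipeline_stages <- c("fixtures", "qsar", "pretrain", "finetune", "rl",
                      "evaluate")

#' Build a pipeline configuration
#'
#' Nested list of per-stage parameters with desk-scale defaults; every
#' entry can be overridden via `...` (e.g. `rl = list(epsilon = 0.2)`).
#' The configuration serializes losslessly to JSON
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param seed Global seed.
#' @param ... Named per-stage override lists (`fixtures`, `qsar`,
#'   `pretrain`, `finetune`, `rl`, `evaluate`, `generator`).
#' @return A `run_config` list.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  base <- list(
    seed = as.integer(seed),
    fixtures = list(n_molecules = 2000L, motif = "c1ccoc1",
                    motif_prevalence = 0.3, label_noise = 0.05,
                    max_units = 5L),
    generator = list(embedding_dim = 32L, hidden_size = 64L, layers = 1L,
                     max_steps = 100L),
    qsar = list(algorithm = "RF", k = 5L, params = list()),
    pretrain = list(epochs = 40L, lr = 1e-3, batch_size = 500L,
                    valid_sample_size = 500L, valid_every = 10L),
    finetune = list(epochs = 10L, lr = 1e-3, batch_size = 500L,
                    valid_sample_size = 500L, valid_every = 5L),
    rl = list(epsilon = 0.1, beta = 0.0, epochs = 30L, batch_size = 500L,
              lr = 1e-3, desired_threshold = 0.5, phi = "pretrain"),
    evaluate = list(n_samples = 1000L, desired_threshold = 0.5))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(base)) stop("unknown config section: ", nm,
                                   call. = FALSE)
    base[[nm]] <- utils::modifyList(base[[nm]], over[[nm]])
  }
  structure(base, class = "run_config")
}

#' Serialize / parse a run configuration (JSON)
#' @param config A `run_config`.
#' @param path File path.
#' @return `read_run_config` returns a `run_config` identical to the one
#'   written.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$seed <- as.integer(x$seed)
  structure(x, class = "run_config")
}

.stage_seed <- function(config, stage) {
  config$seed + 1000L * match(stage, .pipeline_stages)
}

.stage_path <- function(outdir, stage) file.path(outdir, paste0(stage, ".rds"))

.run_stage <- function(outdir, stage, verbose, fn) {
  path <- .stage_path(outdir, stage)
  if (file.exists(path)) {
    if (verbose) message("[", stage, "] cached")
    return(readRDS(path))
  }
  if (verbose) message("[", stage, "] running")
  value <- tryCatch(fn(), error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  saveRDS(value, path)
  value
}

#' Run the full generation pipeline
#'
#' Executes, in order: fixture generation, QSAR training +
#' cross-validation, generator pre-training, fine-tuning on the active
#' subset, reinforcement learning with the exploration strategy, and a
#' final evaluation.  Each stage is checkpointed under `outdir`
#' (`<stage>.rds`); existing checkpoints are reused, so deleting one
#' re-executes only that stage and those after it that depend on it.
#' Reports (`qsar_cv.tsv`, `pretrain_log.tsv`, `finetune_log.tsv`,
#' `rl_log.tsv`, `evaluation.tsv`, `samples.smi`, `manifest.json`) are
#' (re)written at the end of every invocation.
#'
#' @param config A `run_config` from [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param verbose Print stage progress.
#' @return The output directory, invisibly; the evaluation report is in
#'   `evaluate.rds` / `evaluation.tsv`.
#' @export
run_pipeline <- function(config, outdir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(outdir, "config.json"))

  fx <- .run_stage(outdir, "fixtures", verbose, function() {
    fc <- do.call(fixture_config, c(config$fixtures,
                                    list(seed = .stage_seed(config,
                                                            "fixtures"))))
    corpus <- generate_corpus(fc)
    activity <- generate_activity_set(fc, corpus)
    write_smi(corpus, file.path(outdir, "corpus.smi"))
    write_activity_csv(activity, file.path(outdir, "activity.csv"))
    list(config = fc, corpus = corpus, activity = activity)
  })

  qs <- .run_stage(outdir, "qsar", verbose, function() {
    dataset <- curate_activity_dataset(fx$activity)
    seed <- .stage_seed(config, "qsar")
    cv <- crossvalidate_predictor(dataset, config$qsar$algorithm,
                                  k = config$qsar$k, seed = seed,
                                  params = config$qsar$params)
    model <- train_predictor(dataset, config$qsar$algorithm, seed = seed,
                             params = config$qsar$params,
                             path = file.path(outdir, "predictor.joblib"))
    list(dataset = dataset, cv = cv, model = model)
  })
  # sklearn models live in a file; refresh the handle on resumed runs
  if (qs$model$backend == "sklearn")
    qs$model$fit$path <- file.path(outdir, "predictor.joblib")

  gen <- config$generator
  pre <- .run_stage(outdir, "pretrain", verbose, function() {
    do.call(pretrain_generator, c(list(
      corpus = fx$corpus, epochs = config$pretrain$epochs,
      lr = config$pretrain$lr, batch_size = config$pretrain$batch_size,
      max_steps = gen$max_steps, embedding_dim = gen$embedding_dim,
      hidden_size = gen$hidden_size, layers = gen$layers,
      valid_sample_size = config$pretrain$valid_sample_size,
      valid_every = config$pretrain$valid_every,
      seed = .stage_seed(config, "pretrain"), verbose = verbose)))
  })

  ft <- .run_stage(outdir, "finetune", verbose, function() {
    # fine-tune on the raw spellings of the active molecules: canonical
    # forms can contain tokens (e.g. "-") absent from the corpus vocabulary
    raw <- fx$activity$smiles
    can <- canonicalize_smiles(raw)
    pos <- qs$dataset$smiles[qs$dataset$labels == 1L]
    actives <- raw[!is.na(can) & can %in% pos]
    finetune_generator(pre$model, actives, epochs = config$finetune$epochs,
                       lr = config$finetune$lr,
                       batch_size = config$finetune$batch_size,
                       max_steps = gen$max_steps,
                       valid_sample_size = config$finetune$valid_sample_size,
                       valid_every = config$finetune$valid_every,
                       seed = .stage_seed(config, "finetune"),
                       verbose = verbose)
  })

  rl <- .run_stage(outdir, "rl", verbose, function() {
    phi <- if (identical(config$rl$phi, "finetune")) ft$model else pre$model
    cfg <- rl_config(epsilon = config$rl$epsilon, beta = config$rl$beta,
                     epochs = config$rl$epochs,
                     batch_size = config$rl$batch_size,
                     max_steps = gen$max_steps, lr = config$rl$lr,
                     desired_threshold = config$rl$desired_threshold,
                     seed = .stage_seed(config, "rl"))
    train_rl(pre$model, freeze_generator(phi), qs$model, cfg,
             verbose = verbose)
  })

  ev <- .run_stage(outdir, "evaluate", verbose, function() {
    batch <- sample_generator(rl$model, config$evaluate$n_samples,
                              max_steps = gen$max_steps,
                              seed = .stage_seed(config, "evaluate"))
    report <- batch_report(batch, qs$model,
                           desired_threshold =
                             config$evaluate$desired_threshold)
    list(batch = batch, report = report)
  })

  write_cv_report(qs$cv, file.path(outdir, "qsar_cv.tsv"))
  for (nm in c("pretrain", "finetune", "rl")) {
    obj <- switch(nm, pretrain = pre, finetune = ft, rl = rl)
    utils::write.table(obj$log, file.path(outdir, paste0(nm, "_log.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_evaluation_report(ev$report, file.path(outdir, "evaluation.tsv"))
  write_smi(ev$batch$smiles, file.path(outdir, "samples.smi"))
  write_generator(rl$model, file.path(outdir, "generator.rds"))
  manifest <- list(
    seed = config$seed,
    stage_seeds = stats::setNames(
      lapply(.pipeline_stages, function(s) .stage_seed(config, s)),
      .pipeline_stages),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
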