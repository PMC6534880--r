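## QSAR reward model: dataset curation from pChEMBL activity tables and
## four classifier backends (RF / SVM / NB via scikit-learn through the
## worker, DNN natively) whose predicted activity probability Q is the
## reinforcement-learning reward.

#' Read / write an activity table
#'
#' CSV with header columns `smiles`, `pchembl`, `annotation` (extra
#' columns are preserved on write, ignored on curation).
#' @param path File path.
#' @param records Data frame of activity records.
#' @return `read_activity_csv` returns a data.frame.
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("smiles", "pchembl", "annotation")
  if (!all(need %in% names(df)))
    stop("activity CSV must have header columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  df$pchembl <- as.numeric(df$pchembl)
  df$annotation <- as.character(df$annotation)
  df
}

#' @rdname read_activity_csv
#' @export
write_activity_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Curate an activity table into a binary QSAR dataset
#'
#' Unparseable SMILES are skipped with a warning.  Records of the same
#' molecule (identical canonical SMILES) are merged by averaging their
#' pChEMBL values.  A molecule is a negative sample (label 0) when its
#' averaged pChEMBL is below `threshold` (strictly; the default 6.5 makes
#' exactly 6.5 positive) or when any of its records is annotated
#' "Not Active" (case-insensitive); otherwise it is positive (label 1).
#'
#' @param records Data frame with columns `smiles`, `pchembl`,
#'   `annotation` (each record needs at least one of the latter two).
#' @param threshold pChEMBL activity cut-off (default 6.5).
#' @param nbits Fingerprint length (default 4096).
#' @return A `qsar_dataset`: list with `smiles` (canonical, unique),
#'   `fingerprints` (list of bit-position vectors), `labels` (0/1
#'   integer) and `nbits`.
#' @export
curate_activity_dataset <- function(records, threshold = 6.5,
                                    nbits = 4096L) {
  stopifnot(is.data.frame(records),
            all(c("smiles", "pchembl", "annotation") %in% names(records)))
  ann <- records$annotation
  ann[is.na(ann)] <- ""
  if (any(is.na(records$pchembl) & !nzchar(ann)))
    stop("records need a pchembl value or an annotation", call. = FALSE)
  parsed <- parse_smiles(records$smiles)
  if (any(!parsed$valid)) {
    warning(sum(!parsed$valid), " unparseable SMILES record(s) skipped")
    records <- records[parsed$valid, , drop = FALSE]
    ann <- ann[parsed$valid]
    parsed <- parsed[parsed$valid, , drop = FALSE]
  }
  if (!nrow(records)) stop("no parseable records", call. = FALSE)
  key <- parsed$canonical
  groups <- split(seq_along(key), key)
  canon <- names(groups)
  pch <- vapply(groups, function(i) {
    v <- records$pchembl[i]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  not_active <- vapply(groups, function(i)
    any(tolower(trimws(ann[i])) == "not active"), logical(1))
  labels <- ifelse((!is.na(pch) & pch < threshold) | not_active, 0L, 1L)
  structure(list(smiles = canon,
                 fingerprints = compute_ecfp6(canon, nbits = nbits),
                 labels = as.integer(labels),
                 pchembl = unname(pch),
                 nbits = as.integer(nbits)),
            class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("QSAR dataset: %d molecules (%d positive, %d negative), %d-bit ECFP6\n",
              length(x$smiles), sum(x$labels == 1L), sum(x$labels == 0L),
              x$nbits))
  invisible(x)
}

#' Drug-likeness corpus filter
#'
#' Keeps molecules with `logp_range[1] < logP < logp_range[2]` and
#' `mw_range[1] < MW < mw_range[2]` (defaults: the drug-like window
#' -2 < logP < 6, 200 < MW < 600 used to assemble the pre-training
#' corpus).  Invalid SMILES are dropped.
#'
#' @param smiles Character vector.
#' @param logp_range,mw_range Open intervals.
#' @return The filtered character vector.
#' @export
filter_druglike <- function(smiles, logp_range = c(-2, 6),
                            mw_range = c(200, 600)) {
  keep <- is_valid_smiles(smiles)
  smiles <- smiles[keep]
  if (!length(smiles)) return(character(0))
  pc <- physchem_descriptors(smiles)
  smiles[pc$logp > logp_range[1] & pc$logp < logp_range[2] &
           pc$mw > mw_range[1] & pc$mw < mw_range[2]]
}

.default_qsar_params <- function(algorithm) {
  switch(algorithm,
         RF = list(n_trees = 1000L, criterion = "gini"),
         SVM = list(c_grid = 2^seq(-5, 15, by = 2),
                    gamma_grid = 2^seq(-15, 5, by = 2),
                    inner_folds = 3L),
         NB = list(),
         DNN = list(hidden = c(8000L, 4000L, 2000L), dropout = 0.2,
                    epochs = 100L, lr = 1e-3, batch_size = 128L),
         stop("unknown algorithm: ", algorithm, call. = FALSE))
}

.fp_matrix <- function(fingerprints, nbits) {
  X <- matrix(0, length(fingerprints), nbits)
  for (i in seq_along(fingerprints)) {
    b <- fingerprints[[i]]
    if (length(b)) X[i, b + 1L] <- 1
  }
  X
}

#' Train a QSAR activity classifier
#'
#' Reference hyperparameters per algorithm: RF — 1000 trees, gini; SVM —
#' RBF kernel, C and gamma selected on a log2 grid over [2^-5, 2^15] x
#' [2^-15, 2^5] by inner 3-fold AUC; NB — Bernoulli naive Bayes on the
#' fingerprint bits; DNN — hidden layers 8000/4000/2000, ReLU, 20%
#' dropout, sigmoid output, binary cross-entropy, Adam at 1e-3 for 100
#' epochs.  Any entry of `params` overrides the default.
#'
#' @param dataset A `qsar_dataset` with both classes present.
#' @param algorithm One of `"RF"`, `"SVM"`, `"NB"`, `"DNN"`.
#' @param seed Integer seed (fitting is deterministic given the seed).
#' @param params Named list of hyperparameter overrides.
#' @param path Checkpoint path for scikit-learn backends (default: a
#'   tempfile).
#' @return A `qsar_model` whose [predict_activity()] output Q is a
#'   probability in \[0, 1\].
#' @export
train_predictor <- function(dataset, algorithm = c("RF", "SVM", "NB", "DNN"),
                            seed = 0L, params = list(), path = NULL) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  algorithm <- match.arg(algorithm)
  if (length(unique(dataset$labels)) < 2L)
    stop("dataset must contain both classes", call. = FALSE)
  hp <- utils::modifyList(.default_qsar_params(algorithm), params)
  if (algorithm == "DNN") {
    X <- .fp_matrix(dataset$fingerprints, dataset$nbits)
    net <- .dnn_fit(X, dataset$labels, hidden = hp$hidden,
                    dropout = hp$dropout, epochs = hp$epochs, lr = hp$lr,
                    batch_size = hp$batch_size, seed = seed)
    fit <- list(net = net)
  } else {
    if (is.null(path)) path <- tempfile(fileext = ".joblib")
    fit <- .bridge_call("sk_fit", list(
      algorithm = algorithm, bits = lapply(dataset$fingerprints, as.list),
      y = dataset$labels, nbits = dataset$nbits, seed = seed,
      params = hp, path = path))
  }
  structure(list(algorithm = algorithm,
                 backend = if (algorithm == "DNN") "native" else "sklearn",
                 fit = fit, nbits = dataset$nbits, seed = seed, params = hp,
                 id = paste0(algorithm, "-", seed, "-",
                             format(as.numeric(Sys.time()) * 1000))),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("QSAR model: %s (%s backend), %d-bit ECFP6\n", x$algorithm,
              x$backend, x$nbits))
  invisible(x)
}

#' Predict activity probabilities Q
#'
#' @param model A `qsar_model`.
#' @param x Either a list of fingerprint bit-position vectors or a
#'   character vector of valid SMILES (fingerprinted on the fly).
#' @return Numeric vector of probabilities in \[0, 1\] that each molecule
#'   is active.
#' @export
predict_activity <- function(model, x) {
  stopifnot(inherits(model, "qsar_model"))
  # character input is memoised per model: RL re-scores largely
  # overlapping molecule sets every epoch
  if (is.character(x) && !is.null(model$id)) {
    key <- paste0(model$id, "|", x)
    known <- vapply(key, exists, logical(1), envir = .bridge$cache_q,
                    inherits = FALSE)
    todo <- unique(x[!known])
    if (length(todo)) {
      q <- .predict_activity_raw(model, compute_ecfp6(todo,
                                                      nbits = model$nbits))
      for (i in seq_along(todo))
        assign(paste0(model$id, "|", todo[i]), q[i], envir = .bridge$cache_q)
    }
    return(vapply(key, get, numeric(1), envir = .bridge$cache_q))
  }
  fps <- if (is.character(x)) compute_ecfp6(x, nbits = model$nbits) else x
  .predict_activity_raw(model, fps)
}

.predict_activity_raw <- function(model, fps) {
  if (!length(fps)) return(numeric(0))
  if (model$backend == "native") {
    p <- .dnn_predict(model$fit$net, .fp_matrix(fps, model$nbits))
  } else {
    p <- as.numeric(unlist(.bridge_call("sk_predict", list(
      path = model$fit$path, bits = lapply(fps, as.list),
      nbits = model$nbits))))
  }
  unname(pmin(pmax(p, 0), 1))
}

## ---- cross-validation ----------------------------------------------------

.auc_rank <- function(labels, scores) {
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.confusion_metrics <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / denom,
       sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
       accuracy = (tp + tn) / length(labels))
}

.stratified_folds <- function(labels, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("class ", cl, " has fewer members than folds", call. = FALSE)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Stratified k-fold cross-validation of a QSAR algorithm
#'
#' Metrics are pooled over the held-out predictions of all folds;
#' confusion-matrix metrics use a probability threshold of 0.5.
#'
#' @param dataset A `qsar_dataset`.
#' @param algorithm Passed to [train_predictor()].
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment and fits.
#' @param params Hyperparameter overrides for [train_predictor()].
#' @return A `cv_metrics` object: named list `auc`, `mcc`, `sensitivity`,
#'   `specificity`, `accuracy`, with the pooled held-out predictions in
#'   attribute `"predictions"`.
#' @export
crossvalidate_predictor <- function(dataset, algorithm = "RF", k = 5L,
                                    seed = 0L, params = list()) {
  stopifnot(inherits(dataset, "qsar_dataset"), k >= 2L,
            length(dataset$labels) >= k)
  fold <- .stratified_folds(dataset$labels, k, seed)
  scores <- numeric(length(dataset$labels))
  for (f in seq_len(k)) {
    tr <- fold != f
    sub <- structure(list(smiles = dataset$smiles[tr],
                          fingerprints = dataset$fingerprints[tr],
                          labels = dataset$labels[tr],
                          nbits = dataset$nbits),
                     class = "qsar_dataset")
    m <- train_predictor(sub, algorithm, seed = seed + f, params = params)
    scores[!tr] <- predict_activity(m, dataset$fingerprints[!tr])
  }
  cm <- .confusion_metrics(dataset$labels, scores)
  out <- structure(list(auc = .auc_rank(dataset$labels, scores),
                        mcc = cm$mcc, sensitivity = cm$sensitivity,
                        specificity = cm$specificity, accuracy = cm$accuracy),
                   class = "cv_metrics")
  attr(out, "predictions") <- data.frame(label = dataset$labels,
                                         score = scores, fold = fold)
  out
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf(
    "CV: AUC %.3f | MCC %.3f | Sens %.3f | Spec %.3f | Acc %.3f\n",
    x$auc, x$mcc, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Write a cross-validation report as TSV (one row per metric)
#' @param metrics A `cv_metrics` object.
#' @param path File path.
#' @export
write_cv_report <- function(metrics, path) {
  df <- data.frame(metric = c("auc", "mcc", "sensitivity", "specificity",
                              "accuracy"),
                   value = c(metrics$auc, metrics$mcc, metrics$sensitivity,
                             metrics$specificity, metrics$accuracy))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
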