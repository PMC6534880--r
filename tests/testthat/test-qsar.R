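records <- function(smiles, pchembl = NA_real_, annotation = "") {
  data.frame(smiles = smiles, pchembl = pchembl, annotation = annotation,
             stringsAsFactors = FALSE)
}

test_that("curation applies the averaging and 6.5 / Not-Active rules", {
  # mean of {6.0, 7.0} is exactly 6.5: "< 6.5" is strict, so positive
  ds <- curate_activity_dataset(records(c("CCO", "CCO"), c(6.0, 7.0)))
  expect_identical(ds$labels, 1L)
  expect_equal(ds$pchembl, 6.5)
  # annotation rule, no pchembl, case-insensitive
  ds <- curate_activity_dataset(records(c("CCN", "CCC"),
                                        c(NA, 7.2),
                                        c("not ACTIVE", "")))
  expect_identical(ds$labels[match(canonicalize_smiles("CCN"), ds$smiles)], 0L)
  expect_identical(ds$labels[match(canonicalize_smiles("CCC"), ds$smiles)], 1L)
  # canonical merge: "CCO" and "OCC" are one molecule, mean 6.0 -> negative
  ds <- curate_activity_dataset(records(c("CCO", "OCC"), c(7.0, 5.0)))
  expect_length(ds$smiles, 1L)
  expect_equal(ds$pchembl, 6.0)
  expect_identical(ds$labels, 0L)
})

test_that("curation skips unparseable records with a warning and is idempotent", {
  rec <- records(c("CCO", "C(", "CCN"), c(7.0, 7.0, NA),
                 c("", "", "Not Active"))
  expect_warning(ds <- curate_activity_dataset(rec), "skipped")
  expect_length(ds$smiles, 2L)
  rec2 <- records(ds$smiles, ds$pchembl,
                  ifelse(is.na(ds$pchembl), "Not Active", ""))
  ds2 <- curate_activity_dataset(rec2)
  expect_identical(ds2$labels[order(ds2$smiles)], ds$labels[order(ds$smiles)])
  expect_error(curate_activity_dataset(records("CCO")), "pchembl")
})

test_that("activity CSV round-trips through disk", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_activity_csv(toy_activity()[1:20, ], path)
  back <- read_activity_csv(path)
  expect_identical(back$smiles, toy_activity()$smiles[1:20])
  expect_equal(back$pchembl, toy_activity()$pchembl[1:20])
})

test_that("ECFP6 fingerprints are canonical-invariant and bounded", {
  fps <- compute_ecfp6(c("CCO", "OCC", "C"))
  expect_identical(fps[[1]], fps[[2]])
  expect_true(length(fps[[3]]) > 0)
  expect_true(all(unlist(fps) >= 0 & unlist(fps) < 4096))
  expect_identical(compute_ecfp6("CCO"), compute_ecfp6("CCO"))
  expect_error(compute_ecfp6("C("), "invalid SMILES")
  # invariance under atom-order permutation of a larger molecule
  perms <- c("CC(=O)Nc1ccc(O)cc1", "Oc1ccc(NC(C)=O)cc1")
  expect_identical(compute_ecfp6(perms[1]), compute_ecfp6(perms[2]))
})

test_that("predictors honor contracts: probability range, determinism, errors", {
  ds <- onebit_dataset()
  for (alg in c("NB", "DNN")) {
    params <- if (alg == "DNN") list(hidden = c(16L, 8L), epochs = 30L)
              else list()
    m <- train_predictor(ds, alg, seed = 5, params = params)
    q <- predict_activity(m, ds$fingerprints)
    expect_true(all(q >= 0 & q <= 1))
  }
  m1 <- train_predictor(ds, "RF", seed = 5, params = list(n_trees = 50L))
  m2 <- train_predictor(ds, "RF", seed = 5, params = list(n_trees = 50L))
  expect_equal(predict_activity(m1, ds$fingerprints),
               predict_activity(m2, ds$fingerprints))
  one_class <- ds
  one_class$labels <- rep(1L, length(ds$labels))
  expect_error(train_predictor(one_class, "RF"), "both classes")
})

test_that("cross-validation recovers the separable limit and matches a count oracle", {
  ds <- onebit_dataset(n = 80L)
  cv <- crossvalidate_predictor(ds, "RF", k = 5, seed = 2,
                                params = list(n_trees = 50L))
  expect_equal(cv$auc, 1.0)
  expect_equal(cv$mcc, 1.0)
  expect_equal(cv$accuracy, 1.0)
  # brute-force confusion recount from the pooled predictions
  pred <- attr(cv, "predictions")
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(pred))) {
    hard <- as.integer(pred$score[i] > 0.5)
    if (hard == 1 && pred$label[i] == 1) tp <- tp + 1
    if (hard == 0 && pred$label[i] == 0) tn <- tn + 1
    if (hard == 1 && pred$label[i] == 0) fp <- fp + 1
    if (hard == 0 && pred$label[i] == 1) fn <- fn + 1
  }
  expect_equal(cv$sensitivity, tp / (tp + fn))
  expect_equal(cv$specificity, tn / (tn + fp))
  expect_error(crossvalidate_predictor(onebit_dataset(n = 8L), "RF", k = 5),
               "fewer members than folds")
})

test_that("AUC flips under label inversion", {
  set.seed(4)
  y <- rep(c(0L, 1L), 50)
  s <- runif(100) + 0.3 * y
  expect_equal(smilesrl:::.auc_rank(y, s) + smilesrl:::.auc_rank(1L - y, s), 1)
})

test_that("drug-likeness filter applies the open logP/MW windows", {
  # ethanol (MW 46) fails the MW window; a mid-size aromatic passes
  keep <- filter_druglike(c("CCO", "CC(=O)Nc1ccc(OCCN(C)C)cc1", "C("),
                          logp_range = c(-2, 6), mw_range = c(200, 600))
  expect_identical(keep, "CC(=O)Nc1ccc(OCCN(C)C)cc1")
})
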