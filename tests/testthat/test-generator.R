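# Independent R reference implementation of one GRU step (same gate
# layout as the compiled code but written from the equations), used as
# the oracle for forward probabilities and sequence likelihoods.
ref_gru_step <- function(model, prev_idx1, h_list) {
  p <- model$params
  H <- model$hidden_size
  sig <- function(x) 1 / (1 + exp(-x))
  x <- p$E[prev_idx1, , drop = FALSE]
  for (l in seq_len(model$layers)) {
    hp <- h_list[[l]]
    ax <- x %*% p[[paste0("Wx", l)]] + matrix(p[[paste0("bx", l)]],
                                              nrow(x), 3 * H, byrow = TRUE)
    ah <- hp %*% p[[paste0("Wh", l)]] + matrix(p[[paste0("bh", l)]],
                                               nrow(x), 3 * H, byrow = TRUE)
    z <- sig(ax[, 1:H, drop = FALSE] + ah[, 1:H, drop = FALSE])
    r <- sig(ax[, H + 1:H, drop = FALSE] + ah[, H + 1:H, drop = FALSE])
    v <- ah[, 2 * H + 1:H, drop = FALSE]
    n <- tanh(ax[, 2 * H + 1:H, drop = FALSE] + r * v)
    h_list[[l]] <- (1 - z) * n + z * hp
    x <- h_list[[l]]
  }
  logits <- x %*% p$Wo + matrix(p$bo, nrow(x), ncol(p$Wo), byrow = TRUE)
  e <- exp(logits - apply(logits, 1, max))
  list(probs = e / rowSums(e), h = h_list)
}

test_that("per-step distributions are simplex vectors and match the R oracle", {
  m <- tiny_model()
  set.seed(21)
  for (rep in 1:5) {
    B <- 4L
    h0 <- matrix(rnorm(B * m$layers * m$hidden_size, sd = 0.5), B)
    prev <- sample.int(length(m$vocab$tokens), B)
    st <- smilesrl:::cpp_gru_step(m$params, m$layers, m$hidden_size,
                                  prev - 1L, h0)
    expect_true(all(st$probs >= 0))
    expect_equal(rowSums(st$probs), rep(1, B), tolerance = 1e-6)
    ref <- ref_gru_step(m, prev, lapply(seq_len(m$layers), function(l)
      h0[, (l - 1) * m$hidden_size + seq_len(m$hidden_size), drop = FALSE]))
    expect_equal(st$probs, ref$probs, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("sequence log-likelihood equals the step-by-step product oracle", {
  m <- tiny_model()
  v <- m$vocab
  s <- "Cc1ccoc1"
  idx <- encode_smiles(s, v)
  # brute force: walk the net one step at a time, multiply probabilities
  h <- lapply(seq_len(m$layers), function(l) matrix(0, 1, m$hidden_size))
  prev <- v$index[["GO"]]
  ll <- 0
  for (tok in c(idx, v$index[["EOS"]])) {
    st <- ref_gru_step(m, prev, h)
    ll <- ll + log(st$probs[1, tok])
    h <- st$h
    prev <- tok
  }
  expect_equal(sequence_log_likelihood(m, s), ll, tolerance = 1e-10)
  expect_lte(sequence_log_likelihood(m, s), 0)
  # batched teacher-forced loss equals the mean of independent per-sequence NLLs
  strs <- toy_corpus()[1:6]
  seqs <- lapply(strs, encode_smiles, vocab = v)
  bt <- smilesrl:::.build_batch(seqs, v)
  fb <- smilesrl:::.forward_backward(m, bt, rep(1, 6), norm = 6, grad = FALSE)
  indiv <- vapply(strs, function(s) -sequence_log_likelihood(m, s), numeric(1))
  expect_equal(fb$loss, mean(indiv), tolerance = 1e-10)
})

test_that("a forced-EOS model yields empty sequences; step cap and seeds hold", {
  m <- tiny_model()
  m$params$bo[] <- 0
  m$params$bo[1, smilesrl:::.eos_idx(m$vocab)] <- 50
  sb <- sample_generator(m, 20, seed = 1)
  expect_true(all(sb$smiles == ""))
  expect_true(all(sb$terminated))

  m2 <- tiny_model(seed = 33)
  sb1 <- sample_generator(m2, 50, max_steps = 17, seed = 9)
  sb2 <- sample_generator(m2, 50, max_steps = 17, seed = 9)
  expect_identical(sb1$smiles, sb2$smiles)
  expect_identical(sb1$tokens, sb2$tokens)
  expect_true(all(lengths(sb1$tokens) <= 17))
  expect_true(all(lengths(sb1$tokens)[!sb1$terminated] == 17))
})

test_that("first-token sampling frequencies match the model distribution", {
  m <- tiny_model(seed = 55)
  V <- length(m$vocab$tokens)
  st <- smilesrl:::cpp_gru_step(m$params, m$layers, m$hidden_size,
                                smilesrl:::.go_idx(m$vocab) - 1L,
                                matrix(0, 1, m$layers * m$hidden_size))
  p <- as.numeric(st$probs)
  sb <- sample_generator(m, 10000, max_steps = 1, seed = 77)
  first <- vapply(seq_along(sb$tokens), function(i) {
    if (length(sb$tokens[[i]])) sb$tokens[[i]][1]
    else smilesrl:::.eos_idx(m$vocab)
  }, integer(1))
  counts <- tabulate(first, nbins = V)
  keep <- p > 1e-4
  chi <- stats::chisq.test(counts[keep], p = p[keep] / sum(p[keep]))
  expect_gt(chi$p.value, 1e-3)
})

test_that("fine-tuning: zero epochs is the identity; motif corpus raises motif rate", {
  pre <- toy_pretrained(1L)
  same <- finetune_generator(pre$model, toy_corpus()[1:10], epochs = 0L)
  expect_identical(same$model$params, pre$model$params)

  motif_corpus <- toy_corpus()[match_smarts(toy_corpus(), "c1ccoc1")][1:50]
  ft <- finetune_generator(pre$model, motif_corpus, epochs = 15L,
                           batch_size = 25L, valid_sample_size = 0L,
                           seed = 3L)
  # input model untouched
  expect_identical(pre$model$params$E, toy_pretrained(1L)$model$params$E)
  r_pre <- motif_rate(pre$model, 500L, seed = 99L)
  r_ft <- motif_rate(ft$model, 500L, seed = 99L)
  expect_gt(r_ft, r_pre)
  # validity does not collapse
  sb <- sample_generator(ft$model, 400, seed = 5)
  expect_gt(mean(is_valid_smiles(sb$smiles)), 0.5)
})

test_that("training guards: frozen models, unseen tokens, bad corpora", {
  m <- tiny_model()
  expect_error(finetune_generator(freeze_generator(m), "CC", epochs = 1L),
               "frozen")
  v5 <- build_vocabulary(c("CCO", "CCN"))
  m5 <- init_generator(v5, 2, 3, 1, seed = 1)
  expect_error(finetune_generator(m5, "CBr", epochs = 1L), "Br")
})
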