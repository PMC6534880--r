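test_that("exploration limits reduce exactly to single-network sampling", {
  th <- tiny_model(seed = 1)
  ph <- freeze_generator(tiny_model(seed = 2))
  b0 <- sample_with_exploration(th, ph, epsilon = 0, n = 40, max_steps = 25,
                                seed = 7)
  expect_identical(b0$smiles, sample_generator(th, 40, 25, seed = 7)$smiles)
  expect_true(all(!unlist(b0$provenance)))
  b1 <- sample_with_exploration(th, ph, epsilon = 1, n = 40, max_steps = 25,
                                seed = 7)
  expect_identical(b1$smiles, sample_generator(ph, 40, 25, seed = 7)$smiles)
  expect_true(all(unlist(b1$provenance)))
  # provenance mask length equals number of realized draws
  bm <- sample_with_exploration(th, ph, epsilon = 0.5, n = 40, max_steps = 25,
                                seed = 8)
  expect_identical(lengths(bm$provenance),
                   lengths(bm$tokens) + as.integer(bm$terminated))
  v5 <- build_vocabulary(c("CCO", "CCN"))
  expect_error(sample_with_exploration(th, init_generator(v5, 2, 3, 1),
                                       0.1, 5),
               "share one vocabulary")
})

test_that("deduplication keeps one representative per canonical molecule", {
  mk <- function(smiles) {
    v <- toy_vocab()
    structure(list(tokens = lapply(smiles, encode_smiles, vocab = v),
                   terminated = rep(TRUE, length(smiles)), smiles = smiles,
                   provenance = rep(list(logical(0)), length(smiles)),
                   vocab_size = length(v)),
              class = "sample_batch")
  }
  expect_length(dedup_epoch(mk(rep("CCO", 9)))$smiles, 1L)
  distinct <- mk(c("CCO", "CCN", "CCC"))
  expect_identical(dedup_epoch(distinct)$smiles, distinct$smiles)
  expect_identical(dedup_epoch(mk(c("CCO", "OCC", "CCN")))$smiles,
                   c("CCO", "CCN"))
})

test_that("scoring assigns Q to valid molecules, 0 to invalid, advantage Q - beta", {
  v <- toy_vocab()
  sm <- c("Cc1ccoc1C", "C(", "CCO")
  batch <- structure(list(
    tokens = list(encode_smiles(sm[1], v), c(7L, 3L), encode_smiles(sm[3], v)),
    terminated = c(TRUE, FALSE, TRUE), smiles = sm,
    provenance = rep(list(logical(0)), 3), vocab_size = length(v)),
    class = "sample_batch")
  rb <- score_batch(batch, toy_predictor(), beta = 0.1)
  expect_s3_class(rb, "reward_batch")
  expect_identical(rb$valid, c(TRUE, FALSE, TRUE))
  expect_equal(rb$reward[2], 0)
  expect_equal(rb$advantage, rb$reward - 0.1)
  q <- predict_activity(toy_predictor(), sm[1])
  expect_equal(rb$reward[1], unname(q))
})

test_that("policy gradient: zero advantage is a no-op, positive advantage raises likelihood", {
  m <- tiny_model(seed = 4)
  sb <- sample_generator(m, 6, max_steps = 15, seed = 2)
  st <- policy_gradient_step(m, sb, rep(0, 6))
  expect_identical(st$model$params, m$params)

  one <- smilesrl:::.subset_batch(sb, which(lengths(sb$tokens) > 0)[1])
  ll0 <- sequence_log_likelihood(m, one$tokens[[1]],
                                 terminated = one$terminated[1])
  m2 <- m
  for (i in 1:3)
    m2 <- policy_gradient_step(m2, one, rep(1, 1))$model
  ll1 <- sequence_log_likelihood(m2, one$tokens[[1]],
                                 terminated = one$terminated[1])
  expect_gt(ll1, ll0)

  expect_error(policy_gradient_step(m, sb, rep(1, 2)), "aligned")
  expect_error(policy_gradient_step(freeze_generator(m), sb, rep(1, 6)),
               "frozen")
})

test_that("policy-gradient objective matches central finite differences", {
  # <= 100-parameter model: V = 5, emb 2, hidden 3, 1 layer
  v5 <- build_vocabulary(c("CCO", "CCN"))
  m <- init_generator(v5, embedding_dim = 2, hidden_size = 3, layers = 1,
                      seed = 6)
  expect_lte(sum(vapply(m$params, length, numeric(1))), 100)
  sb <- sample_generator(m, 4, max_steps = 8, seed = 3)
  adv <- c(0.9, -0.4, 0.2, 1.0)
  bt <- smilesrl:::.build_batch(sb$tokens, v5, terminated = sb$terminated)
  fb <- smilesrl:::.forward_backward(m, bt, adv, norm = 4)
  h <- 1e-5
  for (nm in names(m$params)) {
    for (i in seq_along(m$params[[nm]])) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - h
      num <- (smilesrl:::.forward_backward(mp, bt, adv, 4, grad = FALSE)$loss -
              smilesrl:::.forward_backward(mm, bt, adv, 4, grad = FALSE)$loss) /
        (2 * h)
      ana <- fb$grads[[nm]][i]
      if (abs(num) > 1e-7 || abs(ana) > 1e-7)
        expect_lt(abs(ana - num) / max(abs(num), abs(ana)), 1e-4)
    }
  }
})

test_that("rl_config validates and warns on the documented instability region", {
  cfg <- rl_config(epsilon = 0.1, beta = 0.05, epochs = 10, seed = 3)
  expect_s3_class(cfg, "rl_config")
  expect_warning(rl_config(epsilon = 0.3), "not to converge")
  expect_warning(rl_config(beta = 0.2), "not to converge")
  expect_error(rl_config(epsilon = -0.1))
})

test_that("train_rl keeps the exploration network bit-identical and logs bounded rewards", {
  pre <- toy_pretrained(1L)
  phi <- freeze_generator(pre$model)
  phi_before <- serialize(phi$params, NULL)
  cfg <- rl_config(epsilon = 0.1, beta = 0.05, epochs = 3, batch_size = 60,
                   max_steps = 60, seed = 5)
  res <- train_rl(pre$model, phi, toy_predictor(), cfg)
  expect_identical(serialize(phi$params, NULL), phi_before)
  expect_true(all(is.finite(res$log$mean_reward)))
  expect_true(all(res$log$mean_reward >= 0 & res$log$mean_reward <= 1))
  expect_true(all(res$log$valid_pct >= 0 & res$log$valid_pct <= 100))
  expect_identical(res$log$epoch, 1:3)
  expect_error(train_rl(freeze_generator(pre$model), phi, toy_predictor(),
                        cfg),
               "frozen")
})
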