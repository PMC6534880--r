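## Policy-gradient fine-tuning of the generator with the exploration
## strategy: at every sampling step a uniform variate decides whether the
## trainable exploitation network G_theta or a frozen exploration network
## G_phi picks the next token (probability epsilon for G_phi).  Both
## networks consume the same realized token history.  The objective
## ascended is
##     J(theta) = sum_t log G_theta(y_t | y_1:t-1) * (Q(y_1:T) - beta)
## where Q is the QSAR activity probability of the decoded molecule
## (0 for invalid SMILES) and beta a constant reward baseline.  The
## gradient flows through G_theta's log-probabilities at every step,
## including steps whose token was chosen by G_phi.

#' Reinforcement-learning configuration
#'
#' @param epsilon Exploration rate in \[0, 1\]: per-step probability that
#'   the frozen exploration network chooses the token.  Values above
#'   0.25 are accepted with a warning — training is documented not to
#'   converge there.
#' @param beta Reward baseline subtracted from Q; molecules scoring below
#'   it are punished.  Values above 0.1 warn for the same reason.
#' @param epochs Training epochs (default 200, the documented convergence
#'   budget).
#' @param batch_size Sequences sampled per epoch (default 500).
#' @param max_steps Sequence length cap (default 100).
#' @param lr Adam learning rate (default 1e-3).
#' @param desired_threshold Probability cut-off above which a valid
#'   molecule counts as "desired" (default 0.5).
#' @param seed Integer seed for the whole run.
#' @return A list of class `rl_config`.
#' @export
rl_config <- function(epsilon = 0.1, beta = 0.0, epochs = 200L,
                      batch_size = 500L, max_steps = 100L, lr = 1e-3,
                      desired_threshold = 0.5, seed = 1L) {
  stopifnot(epsilon >= 0, epsilon <= 1, beta >= 0, epochs >= 0,
            batch_size >= 1)
  if (epsilon > 0.25)
    warning("epsilon > 0.25: training is documented not to converge")
  if (beta > 0.1)
    warning("beta > 0.1: training is documented not to converge")
  structure(list(epsilon = epsilon, beta = beta, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps), lr = lr,
                 desired_threshold = desired_threshold,
                 seed = as.integer(seed)),
            class = "rl_config")
}

#' Sample sequences under the exploration strategy
#'
#' At each step u ~ Uniform\[0,1\] is drawn; if u < epsilon the token is
#' drawn from the exploration network's distribution, otherwise from the
#' exploitation network's.  Both networks are fed the realized token.
#' `epsilon = 0` (or 1) draws no mixing variates and reduces exactly to
#' [sample_generator()] on the single network under the same seed.
#'
#' @param theta Exploitation network (`gen_model`).
#' @param phi Exploration network (`gen_model`, same vocabulary).
#' @param epsilon Exploration rate in \[0, 1\].
#' @param n Number of sequences.
#' @param max_steps Step cap.
#' @param seed Optional seed.
#' @return A `sample_batch`; `provenance[[i]]` is a logical vector, TRUE
#'   where the exploration network chose the token.
#' @export
sample_with_exploration <- function(theta, phi, epsilon, n,
                                    max_steps = 100L, seed = NULL) {
  stopifnot(inherits(theta, "gen_model"), inherits(phi, "gen_model"),
            epsilon >= 0, epsilon <= 1, n >= 1)
  if (!identical(theta$vocab$tokens, phi$vocab$tokens))
    stop("exploitation and exploration networks must share one vocabulary",
         call. = FALSE)
  .sample_core(theta, phi, epsilon, n, max_steps, seed)
}

#' Remove duplicate molecules from a sampled batch
#'
#' Keeps one representative (the first occurrence) per canonical SMILES;
#' invalid entries are deduplicated by their raw string.
#'
#' @param batch A `sample_batch`.
#' @return The deduplicated `sample_batch`.
#' @export
dedup_epoch <- function(batch) {
  stopifnot(inherits(batch, "sample_batch"))
  if (!length(batch$smiles)) return(batch)
  parsed <- parse_smiles(batch$smiles)
  key <- ifelse(parsed$valid, paste0("v:", parsed$canonical),
                paste0("i:", batch$smiles))
  .subset_batch(batch, !duplicated(key))
}

#' Score a sampled batch with the QSAR predictor
#'
#' Valid molecules receive reward R = Q(fingerprint); invalid ones R = 0.
#' The advantage is R - beta, so an invalid molecule carries -beta and a
#' molecule scoring exactly the baseline carries 0.
#'
#' @param batch A `sample_batch`.
#' @param predictor A trained `qsar_model`.
#' @param beta Reward baseline (default 0).
#' @return A `reward_batch`: data.frame with columns `smiles`, `valid`,
#'   `canonical`, `reward`, `advantage`, aligned with the batch.
#' @export
score_batch <- function(batch, predictor, beta = 0.0) {
  stopifnot(inherits(batch, "sample_batch"), inherits(predictor, "qsar_model"))
  parsed <- parse_smiles(batch$smiles)
  reward <- numeric(length(batch$smiles))
  if (any(parsed$valid)) {
    ucan <- unique(parsed$canonical[parsed$valid])
    q <- predict_activity(predictor, ucan)  # memoised per canonical SMILES
    reward[parsed$valid] <- q[match(parsed$canonical[parsed$valid], ucan)]
  }
  out <- data.frame(smiles = batch$smiles, valid = parsed$valid,
                    canonical = parsed$canonical, reward = reward,
                    advantage = reward - beta, stringsAsFactors = FALSE)
  class(out) <- c("reward_batch", "data.frame")
  out
}

#' One policy-gradient (REINFORCE) update
#'
#' Minimizes `-(1/B) sum_b (Q_b - beta) sum_t log G_theta(y_bt | y_b,1:t-1)`
#' over the batch with one Adam step.  For sequences terminated by EOS
#' the EOS step is part of the objective; sequences cut at `max_steps`
#' contribute only their realized tokens.  If every advantage is zero the
#' gradient vanishes and the model is returned bit-identical.
#'
#' @param model Trainable `gen_model` (errors on frozen models).
#' @param batch A `sample_batch`.
#' @param rewards A `reward_batch` from [score_batch()] (or a numeric
#'   vector of advantages aligned with the batch).
#' @param optimizer Optional Adam state from a previous call (as found in
#'   the returned `optimizer` element); a fresh one is created otherwise.
#' @param lr Learning rate for a fresh optimizer.
#' @return List with `model` (updated), `optimizer` (reusable state) and
#'   `loss` (the minimized scalar).
#' @export
policy_gradient_step <- function(model, batch, rewards, optimizer = NULL,
                                 lr = 1e-3) {
  stopifnot(inherits(model, "gen_model"), inherits(batch, "sample_batch"))
  if (model$frozen) stop("cannot update a frozen generator", call. = FALSE)
  adv <- if (is.numeric(rewards)) rewards else rewards$advantage
  if (length(adv) != length(batch$smiles))
    stop("rewards not aligned with batch", call. = FALSE)
  bt <- .build_batch(batch$tokens, model$vocab,
                     terminated = batch$terminated)
  fb <- .forward_backward(model, bt, weights = adv, norm = length(adv))
  if (is.null(optimizer)) optimizer <- adam_init(model$params, lr = lr)
  if (any(adv != 0))
    model$params <- adam_update(optimizer, model$params, fb$grads)
  list(model = model, optimizer = optimizer, loss = fb$loss)
}

#' Reinforcement-learning training loop
#'
#' Per epoch: sample a batch with the exploration strategy, drop
#' duplicate molecules, score the survivors with the predictor and take
#' one policy-gradient step.  The exploration network is frozen and
#' returned untouched; only the exploitation network is updated and
#' returned as the final generator.
#'
#' @param theta Initial exploitation network (typically the pre-trained
#'   generator).
#' @param phi Exploration network (typically the pre-trained or
#'   fine-tuned generator); frozen internally if not already.
#' @param predictor A trained `qsar_model`.
#' @param config An `rl_config`.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (trained `gen_model`) and `log` (data.frame:
#'   epoch, mean_reward, valid_pct, desired_pct, unique_pct, loss) where
#'   rates describe the raw sampled batch and `mean_reward` the
#'   deduplicated training batch.
#' @export
train_rl <- function(theta, phi, predictor, config, verbose = FALSE) {
  stopifnot(inherits(theta, "gen_model"), inherits(phi, "gen_model"),
            inherits(predictor, "qsar_model"), inherits(config, "rl_config"))
  if (theta$frozen) stop("exploitation network is frozen", call. = FALSE)
  phi <- freeze_generator(phi)
  set.seed(config$seed)
  opt <- adam_init(theta$params, lr = config$lr)
  log <- data.frame()
  for (ep in seq_len(config$epochs)) {
    raw <- sample_with_exploration(theta, phi, config$epsilon,
                                   config$batch_size, config$max_steps)
    batch <- dedup_epoch(raw)
    scored <- score_batch(batch, predictor, config$beta)
    step <- policy_gradient_step(theta, batch, scored, optimizer = opt)
    theta <- step$model
    # epoch metrics on the raw batch (scores keyed by canonical SMILES)
    rawp <- parse_smiles(raw$smiles)
    q <- scored$reward[match(rawp$canonical, scored$canonical)]
    q[is.na(q) | !rawp$valid] <- 0
    log <- rbind(log, data.frame(
      epoch = ep,
      mean_reward = mean(scored$reward),
      valid_pct = 100 * mean(rawp$valid),
      desired_pct = 100 * mean(rawp$valid & q > config$desired_threshold),
      unique_pct = 100 * length(unique(rawp$canonical[rawp$valid])) /
        length(raw$smiles),
      loss = step$loss))
    if (verbose)
      message(sprintf(
        "epoch %d | reward %.3f | valid %.1f%% | desired %.1f%% | unique %.1f%%",
        ep, log$mean_reward[ep], log$valid_pct[ep], log$desired_pct[ep],
        log$unique_pct[ep]))
  }
  list(model = theta, log = log)
}
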