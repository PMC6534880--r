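## The recurrent SMILES policy G: token embedding, stacked GRU layers and
## a softmax output over the vocabulary.  Defaults follow the reference
## architecture (embedding 128, three GRU layers of 512 hidden units);
## the dimensions are parameters so desk-scale tests can shrink them.

#' Initialize a recurrent SMILES generator
#'
#' @param vocab A `smiles_vocab`.
#' @param embedding_dim Embedding width (default 128).
#' @param hidden_size GRU hidden width per layer (default 512).
#' @param layers Number of stacked GRU layers (default 3).
#' @param seed Optional integer seed for the parameter initialization.
#' @return An object of class `gen_model`.
#' @export
init_generator <- function(vocab, embedding_dim = 128L, hidden_size = 512L,
                           layers = 3L, seed = NULL) {
  stopifnot(inherits(vocab, "smiles_vocab"), embedding_dim >= 1,
            hidden_size >= 1, layers >= 1)
  if (!is.null(seed)) set.seed(seed)
  V <- length(vocab$tokens)
  H <- as.integer(hidden_size)
  k <- 1 / sqrt(H)
  rmat <- function(nr, nc, scale) matrix(stats::runif(nr * nc, -scale, scale),
                                         nr, nc)
  params <- list(E = rmat(V, embedding_dim, 0.1))
  for (l in seq_len(layers)) {
    din <- if (l == 1L) embedding_dim else H
    params[[paste0("Wx", l)]] <- rmat(din, 3L * H, k)
    params[[paste0("Wh", l)]] <- rmat(H, 3L * H, k)
    params[[paste0("bx", l)]] <- rmat(1L, 3L * H, k)
    params[[paste0("bh", l)]] <- rmat(1L, 3L * H, k)
  }
  params$Wo <- rmat(H, V, k)
  params$bo <- matrix(0, 1L, V)
  structure(list(params = params, vocab = vocab,
                 embedding_dim = as.integer(embedding_dim),
                 hidden_size = H, layers = as.integer(layers),
                 frozen = FALSE),
            class = "gen_model")
}

#' @export
print.gen_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "SMILES generator: vocab %d | embedding %d | %d GRU layer(s) x %d | %s | %d parameters\n",
    length(x$vocab$tokens), x$embedding_dim, x$layers, x$hidden_size,
    if (x$frozen) "frozen" else "trainable", np))
  invisible(x)
}

#' Freeze a generator (e.g. for use as the exploration network)
#' @param model A `gen_model`.
#' @return The model with its `frozen` flag set; training operations
#'   refuse to update frozen models.
#' @export
freeze_generator <- function(model) {
  stopifnot(inherits(model, "gen_model"))
  model$frozen <- TRUE
  model
}

## ---- Adam optimizer over a named list of matrices -----------------------

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$m <- lapply(params, function(p) array(0, dim(p)))
  opt$v <- lapply(params, function(p) array(0, dim(p)))
  opt
}

adam_update <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + opt$eps)
  }
  params
}

## ---- batch construction -------------------------------------------------

.go_idx <- function(vocab) unname(vocab$index[[GO_TOKEN]])
.eos_idx <- function(vocab) unname(vocab$index[[EOS_TOKEN]])

# seqs: list of 1-based index vectors without control tokens.
# terminated[i]: include the EOS target (TRUE for complete sequences).
# Returns 0-based input/target matrices plus the loss mask.
.build_batch <- function(seqs, vocab, terminated = NULL) {
  B <- length(seqs)
  if (is.null(terminated)) terminated <- rep(TRUE, B)
  lens <- lengths(seqs) + as.integer(terminated)
  T <- max(lens)
  eos0 <- .eos_idx(vocab) - 1L
  go0 <- .go_idx(vocab) - 1L
  input <- matrix(eos0, B, T)
  target <- matrix(eos0, B, T)
  mask <- matrix(0, B, T)
  for (b in seq_len(B)) {
    s0 <- as.integer(seqs[[b]]) - 1L
    tg <- if (terminated[b]) c(s0, eos0) else s0
    n <- length(tg)
    if (n == 0L) next
    target[b, seq_len(n)] <- tg
    input[b, seq_len(n)] <- c(go0, tg[-n])
    mask[b, seq_len(n)] <- 1
  }
  list(input = input, target = target, mask = mask)
}

.forward_backward <- function(model, batch, weights, norm, grad = TRUE) {
  cpp_gru_forward_backward(model$params, model$layers, model$hidden_size,
                           batch$input, batch$target, batch$mask,
                           as.numeric(weights), norm, grad)
}

## ---- maximum-likelihood training ----------------------------------------

.train_mle <- function(model, corpus, epochs, lr, batch_size, max_steps,
                       valid_sample_size, valid_every, seed, verbose) {
  if (model$frozen) stop("cannot train a frozen generator", call. = FALSE)
  if (!length(corpus)) stop("empty corpus", call. = FALSE)
  seqs <- lapply(corpus, function(s) encode_smiles(s, model$vocab))
  too_long <- lengths(seqs) >= max_steps
  if (any(too_long)) seqs <- seqs[!too_long]
  if (!is.null(seed)) set.seed(seed)
  opt <- adam_init(model$params, lr = lr)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    valid_pct = numeric(0))
  n <- length(seqs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    tok_loss <- 0; tok_n <- 0
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      bt <- .build_batch(seqs[idx], model$vocab)
      ntok <- sum(bt$mask)
      fb <- .forward_backward(model, bt, rep(1, length(idx)), ntok)
      model$params <- adam_update(opt, model$params, fb$grads)
      tok_loss <- tok_loss + fb$loss * ntok
      tok_n <- tok_n + ntok
    }
    vp <- NA_real_
    if (valid_sample_size > 0 && (ep %% valid_every == 0L || ep == epochs)) {
      sb <- sample_generator(model, valid_sample_size, max_steps = max_steps)
      vp <- 100 * mean(is_valid_smiles(sb$smiles))
    }
    log <- rbind(log, data.frame(epoch = ep, loss = tok_loss / tok_n,
                                 valid_pct = vp))
    if (verbose)
      message(sprintf("epoch %d | nll/token %.4f | valid %s", ep,
                      tok_loss / tok_n,
                      if (is.na(vp)) "-" else sprintf("%.1f%%", vp)))
  }
  list(model = model, log = log)
}

#' Pre-train a SMILES generator by maximum likelihood
#'
#' Teacher forcing with the start token GO prepended to the input and the
#' end token EOS appended to the target; the loss is the mean negative
#' log-likelihood per token, optimized with Adam.  Sequences of
#' `max_steps` tokens or more are dropped (they could never be sampled
#' back).  Each epoch the percentage of valid SMILES in a fresh sample is
#' logged alongside the loss.
#'
#' @param corpus Character vector of training SMILES (or a `gen_model` to
#'   continue training, in which case `vocab` is ignored).
#' @param vocab Optional `smiles_vocab`; built from the corpus if absent.
#' @param epochs Number of passes over the corpus (reference setting:
#'   1000).
#' @param lr Adam learning rate (default `1e-3`).
#' @param batch_size Sequences per gradient step (default 500).
#' @param max_steps Maximum sequence length (default 100).
#' @param embedding_dim,hidden_size,layers Architecture (defaults 128 /
#'   512 / 3).
#' @param valid_sample_size Sample size for the per-epoch validity check
#'   (default 1000; 0 disables).
#' @param valid_every Log validity every this many epochs (default 1).
#' @param seed Optional seed covering initialization, shuffling and the
#'   validity samples.
#' @param verbose Print per-epoch progress.
#' @return A list with elements `model` (`gen_model`) and `log`
#'   (data.frame: epoch, loss, valid_pct).
#' @export
pretrain_generator <- function(corpus, vocab = NULL, epochs = 1000L,
                               lr = 1e-3, batch_size = 500L, max_steps = 100L,
                               embedding_dim = 128L, hidden_size = 512L,
                               layers = 3L, valid_sample_size = 1000L,
                               valid_every = 1L, seed = NULL,
                               verbose = FALSE) {
  if (is.null(vocab)) vocab <- build_vocabulary(corpus)
  if (!is.null(seed)) set.seed(seed)
  model <- init_generator(vocab, embedding_dim, hidden_size, layers)
  .train_mle(model, corpus, epochs, lr, batch_size, max_steps,
             valid_sample_size, valid_every, seed = NULL, verbose = verbose)
}

#' Fine-tune a generator on a target-focused corpus
#'
#' Same procedure as [pretrain_generator()] but initialized from an
#' existing model; the input model is returned untouched.
#'
#' @param model A trained `gen_model`.
#' @param corpus Character vector of SMILES; every token must already be
#'   in the model's vocabulary.
#' @inheritParams pretrain_generator
#' @return A list with elements `model` and `log`.
#' @export
finetune_generator <- function(model, corpus, epochs = 1000L, lr = 1e-3,
                               batch_size = 500L, max_steps = 100L,
                               valid_sample_size = 1000L, valid_every = 1L,
                               seed = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "gen_model"))
  if (epochs == 0L) return(list(model = model,
                                log = data.frame(epoch = integer(0),
                                                 loss = numeric(0),
                                                 valid_pct = numeric(0))))
  if (!is.null(seed)) set.seed(seed)
  .train_mle(model, corpus, epochs, lr, batch_size, max_steps,
             valid_sample_size, valid_every, seed = NULL, verbose = verbose)
}

#' Sample SMILES sequences from a generator
#'
#' Autoregressive multinomial sampling (temperature 1) starting from GO;
#' a sequence ends when EOS is drawn or after `max_steps` steps,
#' whichever comes first.  Sequences that hit the cap are kept and
#' decoded as-is.
#'
#' @param model A `gen_model`.
#' @param n Number of sequences.
#' @param max_steps Step cap (default 100).
#' @param seed Optional seed; the same seed reproduces the batch exactly.
#' @return A `sample_batch`: list with `tokens` (list of 1-based index
#'   vectors, EOS not included), `terminated` (logical), `smiles`
#'   (decoded strings) and `provenance` (here `NULL`).
#' @export
sample_generator <- function(model, n, max_steps = 100L, seed = NULL) {
  stopifnot(inherits(model, "gen_model"), n >= 1)
  .sample_core(model, phi = NULL, epsilon = 0, n = n, max_steps = max_steps,
               seed = seed)
}

# Shared sampling loop.  epsilon = 0 never draws mixing variates nor
# steps the exploration network, so sample_generator() and
# sample_with_exploration(..., epsilon = 0) consume identical random
# streams; epsilon = 1 symmetrically delegates everything to phi.
.sample_core <- function(theta, phi, epsilon, n, max_steps, seed) {
  if (!is.null(seed)) set.seed(seed)
  vocab <- theta$vocab
  V <- length(vocab$tokens)
  eos <- .eos_idx(vocab)
  go <- .go_idx(vocab)
  mix <- epsilon > 0 && epsilon < 1
  use_theta_net <- epsilon < 1
  use_phi_net <- epsilon > 0
  UT <- upper.tri(matrix(0, V, V), diag = TRUE) * 1  # row cumsum helper
  h_th <- matrix(0, n, theta$layers * theta$hidden_size)
  if (use_phi_net) h_ph <- matrix(0, n, phi$layers * phi$hidden_size)
  prev <- rep.int(go - 1L, n)
  tokens <- matrix(NA_integer_, n, max_steps)
  prov <- matrix(NA, n, max_steps)
  alive <- rep(TRUE, n)
  steps <- 0L
  for (t in seq_len(max_steps)) {
    if (use_theta_net) {
      st <- cpp_gru_step(theta$params, theta$layers, theta$hidden_size,
                         prev, h_th)
      h_th <- st$h
      probs <- st$probs
    }
    if (use_phi_net) {
      sp <- cpp_gru_step(phi$params, phi$layers, phi$hidden_size, prev, h_ph)
      h_ph <- sp$h
      if (!use_theta_net) probs <- sp$probs
    }
    if (mix) {
      from_phi <- stats::runif(n) < epsilon
      if (any(from_phi)) probs[from_phi, ] <- sp$probs[from_phi, , drop = FALSE]
    } else {
      from_phi <- rep(epsilon == 1, n)
    }
    u <- stats::runif(n)
    tok <- as.integer(rowSums((probs %*% UT) < u)) + 1L
    tok[tok > V] <- V  # guard against numerical round-off at u ~ 1
    tokens[alive, t] <- tok[alive]
    prov[alive, t] <- from_phi[alive]
    steps <- t
    alive <- alive & tok != eos
    prev <- tok - 1L
    if (!any(alive)) break
  }
  toks <- lapply(seq_len(n), function(b) {
    row <- tokens[b, seq_len(steps)]
    row <- row[!is.na(row)]
    if (length(row) && row[length(row)] == eos) row[-length(row)] else row
  })
  terminated <- vapply(seq_len(n), function(b) {
    row <- tokens[b, seq_len(steps)]
    row <- row[!is.na(row)]
    length(row) > 0L && row[length(row)] == eos
  }, logical(1))
  # zero-length sequences (EOS drawn first) decode to ""
  smiles <- vapply(toks, function(s)
    if (length(s)) decode_tokens(s, vocab) else "", character(1))
  provenance <- lapply(seq_len(n), function(b) {
    row <- prov[b, seq_len(steps)]
    row[!is.na(row)][seq_len(length(toks[[b]]) + terminated[b])]
  })
  structure(list(tokens = toks, terminated = terminated, smiles = smiles,
                 provenance = provenance, vocab_size = V),
            class = "sample_batch")
}

#' @export
print.sample_batch <- function(x, ...) {
  cat("sample_batch:", length(x$smiles), "sequences;",
      sum(x$terminated), "terminated by EOS\n")
  invisible(x)
}

#' @export
length.sample_batch <- function(x) length(x$smiles)

.subset_batch <- function(batch, keep) {
  structure(list(tokens = batch$tokens[keep],
                 terminated = batch$terminated[keep],
                 smiles = batch$smiles[keep],
                 provenance = batch$provenance[keep],
                 vocab_size = batch$vocab_size),
            class = "sample_batch")
}

#' Log-likelihood of a sequence under a generator
#'
#' Sum over steps of the log-probability of each realized token, teacher
#' forced from GO; for a character input the terminating EOS step is
#' included, so this is the log-probability of generating exactly that
#' string and stopping.
#'
#' @param model A `gen_model`.
#' @param seq A SMILES string, or a 1-based token-index vector.
#' @param terminated For index input, whether to include the EOS step.
#' @return A non-positive number (nats).
#' @export
sequence_log_likelihood <- function(model, seq, terminated = TRUE) {
  stopifnot(inherits(model, "gen_model"))
  idx <- if (is.character(seq)) encode_smiles(seq, model$vocab)
         else as.integer(seq)
  bt <- .build_batch(list(idx), model$vocab, terminated = terminated)
  fb <- .forward_backward(model, bt, 1, 1, grad = FALSE)
  -fb$seq_nll[1]
}

#' Save / load a generator checkpoint
#'
#' One file holding the parameters, vocabulary and architecture.
#' @param model A `gen_model`.
#' @param path File path (`.rds`).
#' @return `read_generator` returns the `gen_model`.
#' @export
write_generator <- function(model, path) {
  stopifnot(inherits(model, "gen_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_generator
#' @export
read_generator <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "gen_model"))
  model
}
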