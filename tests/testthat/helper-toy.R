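# Shared desk-scale fixtures, built once per test session and cached.
# The "stated world" of the toy task:
#   * corpus: 2000 fragment-grammar molecules, seed 7, furan motif at
#     prevalence 0.3
#   * activity set: 600 molecules, label noise 0.05
#   * generator: embedding 32, hidden 64, 1 GRU layer, batch 100,
#     50 epochs (a scaled-down stand-in for 128/512/3, batch 500,
#     1000 epochs)
#   * RL-loop reward model: RF with 300 trees (the full 1000-tree
#     setting is exercised in the cross-validation criterion)

.toy <- new.env(parent = emptyenv())

toy_cached <- function(key, fn) {
  if (!exists(key, envir = .toy, inherits = FALSE))
    assign(key, fn(), envir = .toy)
  get(key, envir = .toy)
}

toy_corpus_config <- function()
  fixture_config(n_molecules = 2000L, seed = 7L, motif_prevalence = 0.3,
                 label_noise = 0.05)

toy_corpus <- function()
  toy_cached("corpus", function() generate_corpus(toy_corpus_config()))

toy_vocab <- function()
  toy_cached("vocab", function() build_vocabulary(toy_corpus()))

toy_activity_config <- function()
  fixture_config(n_molecules = 600L, seed = 7L, motif_prevalence = 0.3,
                 label_noise = 0.05)

toy_activity <- function()
  toy_cached("activity", function()
    generate_activity_set(toy_activity_config()))

toy_dataset <- function()
  toy_cached("dataset", function() curate_activity_dataset(toy_activity()))

# light RF used as the RL reward; criterion 3 trains the full 1000 trees
toy_predictor <- function()
  toy_cached("predictor", function()
    train_predictor(toy_dataset(), "RF", seed = 1L,
                    params = list(n_trees = 300L)))

toy_pretrained <- function(seed = 1L)
  toy_cached(paste0("pretrained", seed), function()
    pretrain_generator(toy_corpus(), epochs = 50L, batch_size = 100L,
                       embedding_dim = 32L, hidden_size = 64L, layers = 1L,
                       valid_sample_size = 0L, max_steps = 100L,
                       seed = seed))

# tiny untrained generator for mechanical tests
tiny_model <- function(seed = 11L, vocab = toy_vocab())
  init_generator(vocab, embedding_dim = 3L, hidden_size = 4L, layers = 2L,
                 seed = seed)

# hand-buildable QSAR dataset: label 1 iff bit `bit` is set
onebit_dataset <- function(n = 60L, bit = 7L, nbits = 64L, seed = 3L) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  fps <- lapply(seq_len(n), function(i) {
    extra <- sample(setdiff(0:(nbits - 1L), bit), 5L)
    sort(unique(c(extra, if (labels[i] == 1L) bit)))
  })
  structure(list(smiles = sprintf("mol%03d", seq_len(n)),
                 fingerprints = fps, labels = labels,
                 nbits = as.integer(nbits)),
            class = "qsar_dataset")
}

# fraction of sampled molecules containing the toy motif
motif_rate <- function(model, n = 500L, seed = 99L) {
  sb <- sample_generator(model, n, seed = seed)
  ok <- is_valid_smiles(sb$smiles)
  mean(ok & match_smarts(sb$smiles, "c1ccoc1"))
}
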