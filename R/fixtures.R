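## Synthetic stand-ins for the two external datasets: a fragment-grammar
## SMILES corpus (emulating a drug-like pre-training library) and an
## activity table whose labels are driven by a planted substructure plus
## label noise (emulating a target ligand set).  Molecules are assembled
## by valence-tracked concatenation of fragments, so every string is
## valid by construction and the token alphabet stays small.
##
## The activity motif defaults to a furan ring: actives in the emulated
## target set are enriched for furan, giving the toy task the same bias
## structure (a reward model keying on one substructure) that the
## full-scale problem exhibits.

#' Configuration for the synthetic fixtures
#'
#' @param n_molecules Corpus size.
#' @param seed Integer seed; everything downstream is deterministic in
#'   it.
#' @param motif SMARTS/SMILES substructure defining activity (default
#'   furan, `"c1ccoc1"`).
#' @param motif_prevalence Fraction of molecules built to contain the
#'   motif (default 0.3).
#' @param label_noise Probability that an activity label is flipped
#'   (default 0.1; must be < 0.5).
#' @param max_units Maximum number of grammar fragments appended after
#'   the start fragment (default 5; controls molecule size).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_molecules = 2000L, seed = 42L,
                           motif = "c1ccoc1", motif_prevalence = 0.3,
                           label_noise = 0.1, max_units = 5L) {
  stopifnot(n_molecules >= 1, motif_prevalence > 0, motif_prevalence < 1,
            label_noise >= 0, label_noise < 0.5, max_units >= 1)
  structure(list(n_molecules = as.integer(n_molecules),
                 seed = as.integer(seed), motif = motif,
                 motif_prevalence = motif_prevalence,
                 label_noise = label_noise,
                 max_units = as.integer(max_units)),
            class = "fixture_config")
}

# Grammar fragments.  Each appends to the current attachment atom and
# declares: the valence it consumes there (req) and the free valence of
# the new attachment atom (newf).  The furan fragment is the only source
# of aromatic oxygen, so motif prevalence is controlled exactly.
.frag_start <- list(
  list(s = "C",        newf = 4L),
  list(s = "CC",       newf = 3L),
  list(s = "c1ccccc1", newf = 1L),
  list(s = "C1CCCC1",  newf = 2L))

.frag_units <- list(
  list(s = "C",        req = 1L, newf = 3L),
  list(s = "CC",       req = 1L, newf = 3L),
  list(s = "N",        req = 1L, newf = 2L),
  list(s = "O",        req = 1L, newf = 1L),
  list(s = "c1ccccc1", req = 1L, newf = 1L),
  list(s = "C1CCCC1",  req = 1L, newf = 2L),
  list(s = "(F)",      req = 1L, newf = -1L),   # newf -1: attachment keeps f - req
  list(s = "(C)",      req = 1L, newf = -1L),
  list(s = "(=O)",     req = 2L, newf = -1L))

.frag_motif <- list(s = "c1ccoc1", req = 1L, newf = 1L)

.assemble_molecule <- function(with_motif, max_units) {
  st <- .frag_start[[sample.int(length(.frag_start), 1L)]]
  parts <- st$s
  f <- st$newf
  if (with_motif) {
    parts <- c(parts, .frag_motif$s)
    f <- .frag_motif$newf
  }
  for (i in seq_len(sample.int(max_units, 1L))) {
    ok <- vapply(.frag_units, function(u) u$req <= f, logical(1))
    if (!any(ok)) break
    u <- .frag_units[ok][[sample.int(sum(ok), 1L)]]
    parts <- c(parts, u$s)
    f <- if (u$newf < 0L) f - u$req else u$newf
    if (f <= 0L) break
  }
  paste(parts, collapse = "")
}

#' Generate a synthetic SMILES corpus
#'
#' Valence-safe fragment concatenation: every returned string parses,
#' the token alphabet has about a dozen symbols, and a molecule contains
#' the motif if and only if the grammar planted it (the motif fragment is
#' the only source of its atoms), so the motif-bearing fraction is an
#' exact Bernoulli(`motif_prevalence`) draw per molecule.
#'
#' @param config A `fixture_config`.
#' @return Character vector of `n_molecules` SMILES.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  with_motif <- stats::runif(config$n_molecules) < config$motif_prevalence
  vapply(seq_len(config$n_molecules), function(i)
    .assemble_molecule(with_motif[i], config$max_units), character(1))
}

#' Generate a synthetic activity table
#'
#' Takes the unique molecules of a corpus (generated from `config` if not
#' supplied), assigns the true label by motif match, flips each label
#' independently with probability `label_noise`, and synthesizes pChEMBL
#' values in \[7.0, 8.0\] for actives and \[5.0, 6.0\] for inactives so
#' that [curate_activity_dataset()] (cut-off 6.5) reproduces the labels
#' exactly.  A random 20% of the negatives are expressed through the
#' "Not Active" annotation (with no pChEMBL value) instead, exercising
#' the annotation rule.
#'
#' @param config A `fixture_config`.
#' @param corpus Optional character vector of SMILES.
#' @return Data frame with columns `smiles`, `pchembl`, `annotation` and
#'   attribute `"truth"` (data.frame: smiles, has_motif, label).
#' @export
generate_activity_set <- function(config, corpus = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  if (is.null(corpus)) corpus <- generate_corpus(config)
  smiles <- unique(corpus)
  set.seed(config$seed + 1L)
  has_motif <- match_smarts(smiles, config$motif)
  flip <- stats::runif(length(smiles)) < config$label_noise
  label <- ifelse(xor(has_motif, flip), 1L, 0L)
  pch <- ifelse(label == 1L, 7.5, 5.5) + stats::runif(length(smiles), -0.5, 0.5)
  annotation <- rep("", length(smiles))
  neg <- which(label == 0L)
  as_ann <- neg[stats::runif(length(neg)) < 0.2]
  annotation[as_ann] <- "Not Active"
  pch[as_ann] <- NA_real_
  out <- data.frame(smiles = smiles, pchembl = pch, annotation = annotation,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- data.frame(smiles = smiles, has_motif = has_motif,
                                   label = label)
  out
}
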