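## Molecule-set evaluation: validity/desired/uniqueness rates, Tanimoto
## internal diversity, ring-substructure percentages, a 19-descriptor
## physicochemical profile, 2D chemical-space projections, scaffold-space
## k-means comparison and candidate ranking.

#' Tanimoto similarity of two fingerprints
#'
#' `|a n b| / |a u b|` over on-bit positions.  The undefined both-empty
#' case is taken as 0 (distance 1).
#'
#' @param ma,mb Integer vectors of on-bit positions.
#' @return Similarity in \[0, 1\]; the Tanimoto distance is `1 - T_s`.
#' @export
tanimoto_similarity <- function(ma, mb) {
  ma <- unique(as.integer(ma)); mb <- unique(as.integer(mb))
  u <- length(union(ma, mb))
  if (u == 0L) return(0)
  length(intersect(ma, mb)) / u
}

.fps_of <- function(x, nbits = 4096L) {
  if (is.character(x)) compute_ecfp6(x, nbits = nbits) else x
}

#' Internal diversity of a molecule set
#'
#' `I(A) = |A|^-2 * sum over all ordered pairs (a, b) of T_d(a, b)`,
#' including self-pairs, so a set of n distinct molecules is bounded by
#' (n-1)/n and any set of identical molecules scores exactly 0.
#'
#' @param x Character vector of SMILES or a list of fingerprint
#'   bit-position vectors.
#' @param nbits Fingerprint length when `x` is SMILES.
#' @return Diversity in \[0, 1).
#' @export
internal_diversity <- function(x, nbits = 4096L) {
  fps <- .fps_of(x, nbits)
  n <- length(fps)
  if (n == 0L) stop("empty molecule set", call. = FALSE)
  sizes <- lengths(fps)
  M <- matrix(0, n, nbits)
  for (i in seq_len(n)) if (sizes[i]) M[i, fps[[i]] + 1L] <- 1
  inter <- tcrossprod(M)
  uni <- outer(sizes, sizes, "+") - inter
  ts <- ifelse(uni == 0, 0, inter / uni)
  mean(1 - ts)
}

#' Evaluation report for a generated batch
#'
#' Rates are percentages of the whole batch: `valid_pct` = parseable
#' molecules, `desired_pct` = valid with predictor probability above
#' `desired_threshold`, `unique_pct` = distinct entries (canonical SMILES
#' for valid molecules, the raw string for invalid ones),
#' `unique_desired_pct` = distinct canonical SMILES among desired
#' molecules.  Internal diversity and the substructure
#' percentages are computed on the unique desired subset by default
#' (`diversity_basis`).
#'
#' @param batch A `sample_batch` or character vector of SMILES.
#' @param predictor A trained `qsar_model`.
#' @param desired_threshold Activity-probability cut-off (default 0.5).
#' @param diversity_basis One of `"unique_desired"`, `"unique_valid"`.
#' @param substructure Also compute ring-substructure percentages.
#' @return An `evaluation_report` list: `n`, `valid_pct`, `desired_pct`,
#'   `unique_pct`, `unique_desired_pct`, `diversity`, `substructure_pct`.
#' @export
batch_report <- function(batch, predictor, desired_threshold = 0.5,
                         diversity_basis = c("unique_desired",
                                             "unique_valid"),
                         substructure = TRUE) {
  smiles <- if (inherits(batch, "sample_batch")) batch$smiles else batch
  stopifnot(is.character(smiles), inherits(predictor, "qsar_model"))
  if (!length(smiles)) stop("empty batch", call. = FALSE)
  diversity_basis <- match.arg(diversity_basis)
  n <- length(smiles)
  parsed <- parse_smiles(smiles)
  valid <- parsed$valid
  q <- numeric(n)
  if (any(valid)) {
    ucan <- unique(parsed$canonical[valid])
    qq <- predict_activity(predictor, ucan)
    q[valid] <- qq[match(parsed$canonical[valid], ucan)]
  }
  desired <- valid & q > desired_threshold
  # uniqueness keys: canonical SMILES for valid entries, the raw string
  # for invalid ones (mirrors the per-epoch deduplication rule)
  ukey <- ifelse(valid, paste0("v:", parsed$canonical), paste0("i:", smiles))
  uniq_all <- unique(ukey)
  uniq_valid <- unique(parsed$canonical[valid])
  uniq_desired <- unique(parsed$canonical[desired])
  basis <- if (diversity_basis == "unique_desired") uniq_desired
           else uniq_valid
  diversity <- if (length(basis)) internal_diversity(basis,
                                                     nbits = predictor$nbits)
               else NA_real_
  sub <- if (substructure && length(basis)) substructure_stats(basis)
         else c(fused_ring = NA_real_, furan_ring = NA_real_,
                benzene_ring = NA_real_)
  structure(list(n = n,
                 valid_pct = 100 * sum(valid) / n,
                 desired_pct = 100 * sum(desired) / n,
                 unique_pct = 100 * length(uniq_all) / n,
                 unique_desired_pct = 100 * length(uniq_desired) / n,
                 diversity = diversity,
                 diversity_basis = diversity_basis,
                 substructure_pct = sub),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "Batch of %d | valid %.1f%% | desired %.1f%% | unique %.1f%% | unique desired %.1f%%\n",
    x$n, x$valid_pct, x$desired_pct, x$unique_pct, x$unique_desired_pct))
  cat(sprintf("Internal diversity (%s): %s\n", x$diversity_basis,
              if (is.na(x$diversity)) "NA" else sprintf("%.3f", x$diversity)))
  if (!all(is.na(x$substructure_pct)))
    cat(sprintf("Substructures: fused %.1f%% | furan %.1f%% | benzene %.1f%%\n",
                x$substructure_pct[["fused_ring"]],
                x$substructure_pct[["furan_ring"]],
                x$substructure_pct[["benzene_ring"]]))
  invisible(x)
}

#' Write an evaluation report as TSV
#' @param report An `evaluation_report`.
#' @param path File path.
#' @export
write_evaluation_report <- function(report, path) {
  df <- data.frame(
    metric = c("n", "valid_pct", "desired_pct", "unique_pct",
               "unique_desired_pct", "diversity", "fused_ring_pct",
               "furan_ring_pct", "benzene_ring_pct"),
    value = c(report$n, report$valid_pct, report$desired_pct,
              report$unique_pct, report$unique_desired_pct,
              report$diversity, report$substructure_pct[["fused_ring"]],
              report$substructure_pct[["furan_ring"]],
              report$substructure_pct[["benzene_ring"]]))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Ring-substructure percentages
#'
#' Percentage of molecules containing a furan ring (aromatic `c1ccoc1`),
#' a benzene ring (`c1ccccc1`) and a fused ring system (two rings of the
#' smallest set sharing at least one bond — spiro systems, which share
#' only an atom, do not count).
#'
#' @param smiles Character vector of valid SMILES.
#' @return Named numeric vector `fused_ring`, `furan_ring`,
#'   `benzene_ring` (percentages), with the per-molecule logical flags in
#'   attribute `"flags"`.
#' @export
substructure_stats <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  val <- .bridge_call("substructure", list(smiles = as.list(smiles)))
  flags <- data.frame(
    smiles = smiles,
    fused_ring = vapply(val$fused, isTRUE, logical(1)),
    furan_ring = vapply(val$furan, isTRUE, logical(1)),
    benzene_ring = vapply(val$benzene, isTRUE, logical(1)))
  if (any(vapply(val$fused, is.null, logical(1))))
    warning("invalid SMILES counted as lacking all substructures")
  out <- c(fused_ring = 100 * mean(flags$fused_ring),
           furan_ring = 100 * mean(flags$furan_ring),
           benzene_ring = 100 * mean(flags$benzene_ring))
  attr(out, "flags") <- flags
  out
}

#' Names of the 19 physicochemical descriptors
#' @return Character vector in column order.
#' @export
physchem_names <- function() {
  c("logp", "mw", "hbd", "hba", "rotatable_bonds", "aliphatic_rings",
    "aromatic_rings", "heterocycles", "tpsa", "molar_refractivity",
    "fraction_csp3", "amide_bonds", "bridgehead_atoms", "heteroatoms",
    "heavy_atoms", "spiro_atoms", "rings", "saturated_rings",
    "valence_electrons")
}

#' 19D physicochemical descriptor vectors
#'
#' logP, molecular weight, H-bond donors/acceptors, rotatable bonds,
#' aliphatic/aromatic rings, heterocycles, TPSA, molar refractivity,
#' fraction of sp3 carbons, and counts of amide bonds, bridgehead atoms,
#' heteroatoms, heavy atoms, spiro atoms, rings, saturated rings and
#' valence electrons — the standard RDKit definitions.
#'
#' @param smiles Character vector of valid SMILES (errors on invalid).
#' @return Data frame, one row per molecule, columns [physchem_names()].
#' @export
physchem_descriptors <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  val <- .bridge_call("physchem", list(smiles = as.list(smiles)))
  m <- do.call(rbind, lapply(val, function(v) as.numeric(unlist(v))))
  df <- as.data.frame(m)
  names(df) <- physchem_names()
  df
}

#' Project descriptor vectors to 2D chemical space
#'
#' PCA (deterministic, components ordered by explained variance) or
#' seeded t-SNE.  PCA centers but does not rescale by default, so
#' already-2D data is reproduced up to rotation/reflection; set
#' `scale. = TRUE` for mixed-unit descriptors.
#'
#' @param x Numeric matrix or data frame (rows = molecules).
#' @param method `"pca"` or `"tsne"`.
#' @param seed Seed for t-SNE.
#' @param scale. Standardize columns before PCA.
#' @param perplexity t-SNE perplexity (reduced automatically for tiny
#'   sets).
#' @return n x 2 coordinate matrix; for PCA the proportion of variance
#'   explained is in attribute `"explained"`.
#' @export
project_space <- function(x, method = c("pca", "tsne"), seed = 0L,
                          scale. = FALSE, perplexity = 30) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (method == "pca") {
    keep <- apply(x, 2, stats::sd) > 0 | !scale.
    p <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE,
                       scale. = scale.)
    k <- min(2L, ncol(p$x))
    coords <- p$x[, seq_len(k), drop = FALSE]
    if (k < 2L) coords <- cbind(coords, 0)
    ev <- p$sdev^2 / sum(p$sdev^2)
    colnames(coords) <- c("PC1", "PC2")
    attr(coords, "explained") <- ev
    coords
  } else {
    val <- .bridge_call("tsne", list(
      x = lapply(seq_len(nrow(x)), function(i) as.numeric(x[i, ])),
      seed = seed, perplexity = perplexity))
    coords <- do.call(rbind, lapply(val, function(v) as.numeric(unlist(v))))
    colnames(coords) <- c("tSNE1", "tSNE2")
    coords
  }
}

#' Murcko scaffolds of molecules
#'
#' @param smiles Character vector.
#' @param mode `"murcko"` (ring systems + linkers) or `"generic"`
#'   (topological scaffold: atom types and bond orders abstracted).
#' @return Character vector of scaffold SMILES (`""` for acyclic
#'   molecules, `NA` for invalid input).
#' @export
murcko_scaffold <- function(smiles, mode = c("murcko", "generic")) {
  mode <- match.arg(mode)
  .bridge_scaffold(smiles, mode)
}

#' Compare scaffold-space occupancy of two molecule sets by k-means
#'
#' Fingerprints are computed on the full structure, the Murcko scaffold
#' or the topological (generic) Murcko scaffold; k-means is fit on the
#' pooled reference + query fingerprints and per-cluster occupancy
#' counted for each set.  Coverage is the fraction of reference-occupied
#' clusters that the query set also occupies.
#'
#' @param reference,query Character vectors of valid SMILES.
#' @param k Number of clusters (default 20).
#' @param mode `"full"`, `"murcko"` or `"generic"`.
#' @param seed Seed for the k-means initialization.
#' @param nbits Fingerprint length.
#' @return A `cluster_occupancy` list: `counts` (k x 2 matrix, columns
#'   reference/query), `coverage`, `assignment`, `mode`, `k`.
#' @export
cluster_compare <- function(reference, query, k = 20L,
                            mode = c("full", "murcko", "generic"),
                            seed = 0L, nbits = 4096L) {
  mode <- match.arg(mode)
  stopifnot(length(reference) >= 1L, length(query) >= 1L)
  if (length(reference) + length(query) < k)
    stop("fewer molecules than clusters", call. = FALSE)
  pool <- c(reference, query)
  struct <- if (mode == "full") pool else murcko_scaffold(pool, mode)
  if (anyNA(struct)) stop("invalid SMILES in input", call. = FALSE)
  # acyclic molecules have an empty scaffold; fingerprint them as empty
  fps <- vector("list", length(struct))
  nz <- nzchar(struct)
  if (any(nz)) fps[nz] <- compute_ecfp6(struct[nz], nbits = nbits)
  fps[!nz] <- list(integer(0))
  M <- .fp_matrix(fps, nbits)
  set.seed(seed)
  km <- stats::kmeans(M, centers = min(k, nrow(unique(M))), nstart = 5L)
  cl <- km$cluster
  is_ref <- seq_along(pool) <= length(reference)
  counts <- cbind(reference = tabulate(cl[is_ref], nbins = k),
                  query = tabulate(cl[!is_ref], nbins = k))
  occ_ref <- counts[, "reference"] > 0
  coverage <- if (!any(occ_ref)) NA_real_
              else mean(counts[occ_ref, "query"] > 0)
  structure(list(counts = counts, coverage = coverage, assignment = cl,
                 mode = mode, k = k),
            class = "cluster_occupancy")
}

#' @export
print.cluster_occupancy <- function(x, ...) {
  cat(sprintf("k-means scaffold comparison (%s, k = %d): coverage %.2f\n",
              x$mode, x$k, x$coverage))
  invisible(x)
}

#' Write per-cluster occupancy as TSV
#' @param occupancy A `cluster_occupancy`.
#' @param path File path.
#' @export
write_cluster_report <- function(occupancy, path) {
  df <- data.frame(cluster = seq_len(nrow(occupancy$counts)),
                   reference = occupancy$counts[, "reference"],
                   query = occupancy$counts[, "query"])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rank candidate molecules by predicted activity and novelty
#'
#' Each molecule is annotated with its predictor probability Q and its
#' minimum Tanimoto distance to the reference set; ranking is by Q
#' descending with ties broken by larger distance (novelty first).
#'
#' @param smiles Character vector of valid candidate SMILES.
#' @param predictor A trained `qsar_model`.
#' @param reference Character vector of reference SMILES (non-empty).
#' @param top_n Number of candidates to return (default: all).
#' @return Data frame `smiles`, `score`, `min_distance`, sorted.
#' @export
rank_candidates <- function(smiles, predictor, reference, top_n = Inf) {
  stopifnot(is.character(smiles), length(smiles) >= 1L,
            inherits(predictor, "qsar_model"), length(reference) >= 1L)
  fps <- compute_ecfp6(smiles, nbits = predictor$nbits)
  ref_fps <- compute_ecfp6(reference, nbits = predictor$nbits)
  q <- predict_activity(predictor, fps)
  mind <- vapply(fps, function(f)
    min(vapply(ref_fps, function(r) 1 - tanimoto_similarity(f, r),
               numeric(1))), numeric(1))
  out <- data.frame(smiles = smiles, score = q, min_distance = mind,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, -out$min_distance), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n = if (is.finite(top_n)) top_n else nrow(out))
}
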