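# O(n^2) reference for internal diversity, kept deliberately naive
diversity_oracle <- function(fps) {
  n <- length(fps)
  acc <- 0
  for (a in seq_len(n)) for (b in seq_len(n))
    acc <- acc + (1 - tanimoto_similarity(fps[[a]], fps[[b]]))
  acc / n^2
}

test_that("Tanimoto similarity follows the set formula", {
  expect_equal(tanimoto_similarity(c(1L, 5L, 9L), c(1L, 5L, 9L)), 1)
  expect_equal(tanimoto_similarity(c(1L, 2L), c(3L, 4L)), 0)
  expect_equal(tanimoto_similarity(c(1L, 2L, 3L), c(2L, 3L, 4L)), 0.5)
  expect_equal(tanimoto_similarity(integer(0), integer(0)), 0)
  expect_equal(tanimoto_similarity(c(2L, 3L), c(3L, 2L)),
               tanimoto_similarity(c(3L, 2L), c(2L, 3L)))
})

test_that("internal diversity matches the double-loop oracle and its bounds", {
  expect_equal(internal_diversity(rep("CCO", 7)), 0)
  # methane and amine fingerprints share no bits: I = (0+1+1+0)/4
  expect_equal(internal_diversity(c("C", "N")), 0.5)
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(2:12, 1)
    fps <- lapply(seq_len(n), function(i)
      sort(sample(0:199, sample(3:20, 1))))
    got <- internal_diversity(fps, nbits = 256L)
    expect_equal(got, diversity_oracle(fps), tolerance = 1e-12)
    expect_gte(got, 0)
    expect_lte(got, (n - 1) / n)
  }
  expect_error(internal_diversity(list()), "empty")
})

test_that("substructure flags match the hand-labeled fixture", {
  st <- substructure_stats(c("c1ccc2ccccc2c1", "c1ccoc1", "C1CCC2(CC1)CCCC2"))
  flags <- attr(st, "flags")
  expect_identical(flags$fused_ring, c(TRUE, FALSE, FALSE))  # spiro != fused
  expect_identical(flags$furan_ring, c(FALSE, TRUE, FALSE))
  expect_identical(flags$benzene_ring, c(TRUE, FALSE, FALSE))
  expect_equal(unname(st["furan_ring"]), 100 / 3, tolerance = 1e-12)
})

test_that("physicochemical descriptors return the 19 named values", {
  pc <- physchem_descriptors(c("C", "c1ccccc1", "CCO"))
  expect_identical(names(pc), physchem_names())
  expect_equal(pc$heavy_atoms, c(1, 6, 3))
  expect_equal(pc$rings, c(0, 1, 0))
  expect_equal(pc$heteroatoms, c(0, 0, 1))
  expect_equal(pc$aromatic_rings[2], 1)
  expect_equal(pc$saturated_rings[2], 0)
  expect_equal(pc$fraction_csp3[2], 0)
  expect_equal(pc$hbd[3], 1)
  expect_error(physchem_descriptors("C("), "invalid")
})

test_that("PCA projection preserves 2D data and orders variance", {
  set.seed(3)
  X <- cbind(rnorm(40, sd = 3), rnorm(40))
  co <- project_space(X, "pca")
  expect_equal(as.matrix(dist(co)), as.matrix(dist(X)), tolerance = 1e-9,
               ignore_attr = TRUE)
  X19 <- matrix(rnorm(50 * 19), 50)
  ev <- attr(project_space(X19, "pca"), "explained")
  expect_true(all(diff(ev) <= 1e-12))
  Xd <- rbind(X, X[1:3, ])
  cod <- project_space(Xd, "pca")
  expect_equal(cod[41:43, ], cod[1:3, ], ignore_attr = TRUE)
  expect_error(project_space(X[1:2, ], "pca"), "at least 3")
})

test_that("t-SNE projection is seeded and 2D", {
  X <- matrix(rnorm(30 * 5), 30)
  a <- project_space(X, "tsne", seed = 4)
  b <- project_space(X, "tsne", seed = 4)
  expect_identical(dim(a), c(30L, 2L))
  expect_equal(a, b)
})

test_that("scaffold k-means comparison: self-coverage, occupancy sums, scaffold oracle", {
  expect_identical(murcko_scaffold("Cc1ccccc1"), "c1ccccc1")
  expect_identical(murcko_scaffold("Cc1ccccc1", "generic"), "C1CCCCC1")
  expect_identical(murcko_scaffold("CCO"), "")
  mols <- unique(toy_corpus())[1:60]
  cc <- cluster_compare(mols, mols, k = 8, mode = "full", seed = 1)
  expect_equal(cc$coverage, 1.0)
  expect_identical(cc$counts[, "reference"], cc$counts[, "query"])
  expect_equal(sum(cc$counts[, "reference"]), 60)
  cm <- cluster_compare(mols[1:40], mols[41:60], k = 8, mode = "murcko",
                        seed = 2)
  expect_equal(sum(cm$counts[, "reference"]), 40)
  expect_equal(sum(cm$counts[, "query"]), 20)
  expect_error(cluster_compare(mols[1:3], mols[4:5], k = 20), "fewer")
})

test_that("candidate ranking orders by score then novelty", {
  pred <- toy_predictor()
  ref <- c("Cc1ccoc1", "CCc1ccoc1")
  cand <- c("Cc1ccoc1", "CCCCO", "c1ccoc1CC(F)C")
  rk <- rank_candidates(cand, pred, ref)
  expect_identical(sort(rk$smiles), sort(cand))
  expect_equal(rk$min_distance[rk$smiles == "Cc1ccoc1"], 0)
  expect_true(all(diff(rk$score) <= 1e-12))
  # explicit tie: equal scores, the more distant molecule first
  fake <- rk; fake$score <- c(0.5, 0.5, 0.5)
  ord <- fake[order(-fake$score, -fake$min_distance), ]
  expect_true(all(diff(ord$min_distance) <= 0))
  expect_identical(nrow(rank_candidates(cand, pred, ref, top_n = 99)), 3L)
  expect_identical(nrow(rank_candidates(cand, pred, ref, top_n = 2)), 2L)
})

test_that("batch_report handles degenerate batches per the stated denominators", {
  pred <- toy_predictor()
  rep10 <- batch_report(rep("Cc1ccoc1C", 10), pred, substructure = FALSE)
  expect_equal(rep10$valid_pct, 100)
  expect_equal(rep10$unique_pct, 10)
  expect_equal(rep10$diversity, 0)
  inv <- batch_report(c("C(", "(((", ")", "%1"), pred, substructure = FALSE)
  expect_equal(inv$valid_pct, 0)
  expect_equal(inv$desired_pct, 0)
  expect_equal(inv$unique_pct, 100)  # distinct invalid strings each count
  expect_true(is.na(inv$diversity))
  expect_error(batch_report(character(0), pred), "empty")
})
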