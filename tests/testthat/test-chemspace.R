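test_that("nearest-neighbor similarity matches the exhaustive oracle", {
  set.seed(41)
  Q <- randomBitMatrix(20, 64); R <- randomBitMatrix(20, 64)
  nn <- nnMeanTanimoto(Q, R)
  expect_equal(nn$mean_nn_similarity, refNNMean(Q > 0, R > 0), tolerance = 1e-12)
  sim <- tanimotoMatrix(Q, R)
  for (i in 1:20) {
    expect_equal(nn$pairs$similarity[i], max(sim[i, ]))
    expect_equal(nn$pairs$neighbor_key[i], colnames(sim)[which.max(sim[i, ])])
  }
})

test_that("a set against itself has mean nearest-neighbor similarity 1", {
  set.seed(42)
  A <- randomBitMatrix(12, 32)
  copy <- A; rownames(copy) <- sprintf("copy%02d", 1:12)
  expect_equal(nnMeanTanimoto(A, copy)$mean_nn_similarity, 1)
  # singleton vs singleton reduces to the single pairwise similarity
  one <- nnMeanTanimoto(A[1, , drop = FALSE], A[2, , drop = FALSE])
  expect_equal(one$mean_nn_similarity, tanimotoSimilarity(A[1, ], A[2, ]))
  expect_error(nnMeanTanimoto(A[0, , drop = FALSE], A), "non-empty")
})

test_that("property comparisons detect planted shifts and identity", {
  lib <- fixtureMoleculePool(40)
  phys <- computePhyschem(lib$smiles, lib$compound_key)
  same <- comparePropertyDistributions(phys, phys)
  expect_true(all(same$standardized_shift == 0))
  expect_equal(nrow(same), 7L)

  # planting a +100 g/mol substituent-mass shift forces a positive
  # molecular-weight shift and leaves the other properties untouched
  heavier <- phys
  heavier$molecular_weight <- phys$molecular_weight + 100
  cmp <- comparePropertyDistributions(phys, heavier)
  expect_gt(cmp$standardized_shift[cmp$property == "molecular_weight"], 0)
  expect_true(all(cmp$standardized_shift[cmp$property != "molecular_weight"] == 0))
  expect_error(comparePropertyDistributions(phys[0, ], phys), "non-empty")
})

test_that("2-D embedding is deterministic with the published defaults", {
  set.seed(5)
  m <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(sprintf("k%02d", 1:40), NULL))
  e1 <- embedChemicalSpace(m, seed = 11, overlap_keys = c("k01", "k02"))
  e2 <- embedChemicalSpace(m, seed = 11, overlap_keys = c("k01", "k02"))
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 40L)
  expect_equal(names(e1), c("compound_key", "x", "y", "domain", "overlap_flag"))
  expect_equal(sum(e1$overlap_flag), 2L)
  expect_error(embedChemicalSpace(m[1:10, ], seed = 1), "at least n_neighbors")
  expect_error(embedChemicalSpace(m), "seed")
})

test_that("delta sets drop exactly the shared structures from both sides", {
  pool <- fixtureMoleculePool(60)
  a <- makeDataset(pool[1:40, ], rep("active", 40), "public_like")
  b <- makeDataset(pool[31:60, ], rep("inactive", 30), "proprietary_like")
  delta <- domainDeltaSets(a, b)
  expect_equal(length(delta$shared), 10L)
  expect_equal(nMembers(delta$deltaA), 30L)
  expect_equal(nMembers(delta$deltaB), 20L)
  expect_length(intersect(memberInchis(delta$deltaA), memberInchis(delta$deltaB)), 0)
})
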