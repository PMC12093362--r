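test_that("fingerprints are deterministic and canonicalization-invariant", {
  fpA <- qsarShift:::fpMatrix(computeFingerprint(c("CCO", "OCC", "C"),
                                                 c("a", "b", "c")))
  fpB <- qsarShift:::fpMatrix(computeFingerprint(c("CCO", "OCC", "C"),
                                                 c("a", "b", "c")))
  expect_identical(fpA, fpB)
  expect_identical(fpA["a", ], fpA["b", ]) # CCO == OCC
  expect_gt(sum(fpA["c", ]), 0)            # methane: non-empty bit-set
  expect_error(computeFingerprint(character(0)), "no molecules")
  expect_error(computeFingerprint(c("CCO", "")), "empty molecule")
})

test_that("fingerprint matrices are stable across repeated hashing", {
  lib <- fixtureMoleculePool(200)
  m1 <- qsarShift:::fpMatrix(computeFingerprint(lib$smiles, lib$compound_key))
  m2 <- qsarShift:::fpMatrix(computeFingerprint(lib$smiles, lib$compound_key))
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(200L, 2048L))
  expect_true(all(rowSums(m1) > 0))
})

test_that("E-state atom values match the hand-computed Kier-Hall solution", {
  # ethanol: intrinsic states 2.0 (CH3), 1.5 (CH2), 6.0 (OH); perturbed
  # values derived by hand from I_i + sum (I_i - I_j) / (d_ij + 1)^2
  g <- qsarShift:::molGraphs("CCO", "etoh")[[1]]
  es <- qsarShift:::atomEstate(g)
  expect_equal(sort(unname(es$S)), sort(c(2 + 0.5 / 4 - 4 / 9,
                                  1.5 - 0.5 / 4 - 4.5 / 4,
                                  6 + 4.5 / 4 + 4 / 9)), tolerance = 1e-12)
  v <- qsarShift:::estateVector(g)
  expect_equal(unname(v["sCH3"]), 2 + 0.5 / 4 - 4 / 9)
  expect_equal(unname(v["sOH1"]), 6 + 4.5 / 4 + 4 / 9)
})

test_that("estate vectors are finite with constant width on diverse molecules", {
  lib <- fixtureMoleculePool(150)
  ds <- makeDataset(lib, rep(c("active", "inactive"), length.out = 150),
                    "public_like")
  dm <- computeDescriptorMatrix(ds, "estate_like")
  vals <- descriptorValues(dm)
  expect_equal(nrow(vals), 150L)
  expect_true(all(is.finite(vals)))
  expect_equal(ncol(vals), length(qsarShift:::estateVocabulary()))
})

test_that("permuting members permutes descriptor rows identically", {
  lib <- fixtureMoleculePool(30)
  ds <- makeDataset(lib, rep("active", 30), "public_like")
  dm1 <- descriptorValues(computeDescriptorMatrix(ds, "estate_like"))
  set.seed(2)
  perm <- sample(30)
  dsPerm <- ds
  dsPerm@compounds <- ds@compounds[perm, , drop = FALSE]
  dm2 <- descriptorValues(computeDescriptorMatrix(dsPerm, "estate_like"))
  expect_identical(dm2, dm1[perm, , drop = FALSE])
})

test_that("embedding providers are data-driven in width and signal misses", {
  f <- tempfile(fileext = ".csv")
  tab <- data.frame(key = sprintf("k%d", 1:5),
                    matrix(rnorm(5 * 8), 5, 8))
  write.csv(tab, f, row.names = FALSE)
  prov <- loadEmbeddingProvider(f)
  expect_equal(embeddingDim(prov), 8L)
  hit <- embeddingLookup(prov, c("k1", "k9", "k3"))
  expect_equal(rownames(hit$vectors), c("k1", "k3"))
  expect_equal(hit$missing, "k9")

  wide <- data.frame(key = sprintf("w%d", 1:5), matrix(rnorm(5 * 512), 5, 512))
  fw <- tempfile(fileext = ".csv")
  write.csv(wide, fw, row.names = FALSE)
  expect_equal(embeddingDim(loadEmbeddingProvider(fw)), 512L)

  ragged <- tempfile(fileext = ".csv")
  writeLines(c("key,v1,v2", "a,1,2", "b,3"), ragged)
  expect_error(loadEmbeddingProvider(ragged), "ragged|non-numeric")
})

test_that("missing embedding keys narrow the dataset with a logged drop", {
  lib <- fixtureMoleculePool(10)
  ds <- makeDataset(lib, rep(c("active", "inactive"), 5), "public_like")
  f <- tempfile(fileext = ".csv")
  tab <- data.frame(key = memberKeys(ds)[1:9], matrix(rnorm(9 * 16), 9, 16))
  write.csv(tab, f, row.names = FALSE)
  dm <- computeDescriptorMatrix(ds, "embedding", embedding = loadEmbeddingProvider(f))
  expect_equal(nrow(descriptorValues(dm)), 9L)
  expect_equal(dm@dropped$compound_key, memberKeys(ds)[10])
  narrowed <- alignToDescriptors(ds, dm)
  expect_equal(nMembers(narrowed), 9L)
  expect_match(curationLog(narrowed)$reason, "coverage", all = FALSE)

  empty <- makeDataset(lib[0, ], character(0), "public_like")
  dmE <- computeDescriptorMatrix(empty, "estate_like")
  expect_equal(nrow(descriptorValues(dmE)), 0L)
})

test_that("physicochemical records carry the seven fields with hand counts", {
  rec <- computePhyschem(c("CCO", "c1ccccc1", "C"),
                         c("ethanol", "benzene", "methane"))
  expect_equal(rec$heavy_atoms, c(3L, 6L, 1L))
  expect_equal(rec$hbond_donors[1], 1)   # ethanol OH
  expect_equal(rec$hbond_acceptors[2], 0) # benzene: none
  expect_equal(rec$hbond_donors[2], 0)
  expect_equal(rec$rotatable_bonds[3], 0)
  expect_equal(rec$tpsa[3], 0)
  expect_true(all(rec$molecular_weight > 0))
  expect_equal(ncol(rec), 8L) # key + seven properties
})
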