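test_that("assay formats derive from assay-type and cell-name annotations", {
  rows <- makeRows(rep("CCO", 4), sprintf("c%d", 1:4), rep(1, 4), "public_like",
                   assay_type = c("B", "B", "F", "A"),
                   cell_name = c("HEK293", "", NA, "CHO-K1"))
  out <- deriveAssayFormat(rows)
  expect_equal(out$rows$assay_format, c("cell_based", "cell_free", "cell_based"))
  expect_equal(out$excluded$compound_key, "c3")
  expect_match(out$excluded$reason, "not in \\{A, B, T\\}")
})

mixingFixture <- function() {
  pool <- fixtureMoleculePool(300)
  base <- makeDataset(pool[1:100, ], rep(c("active", "inactive"), 50),
                      "proprietary_like")
  pub <- makeDataset(pool[101:300, ], rep(c("active", "inactive"), 100),
                     "public_like")
  pub@compounds$assay_format <- rep(c("cell_based", "cell_free"), 100)
  list(base = base, pub = pub)
}

test_that("the three compilation approaches nest and conserve the base set", {
  fx <- mixingFixture()
  a <- compileMixed(fx$base, fx$pub, "a_target_only")
  b <- compileMixed(fx$base, fx$pub, "b_plus_assay_format", "cell_based")
  cc <- compileMixed(fx$base, fx$pub, "c_plus_similarity", "cell_based",
                     threshold = 0.230)
  expect_equal(nMembers(a), 300L) # disjoint union
  expect_equal(nMembers(b), 200L) # half the public rows are cell_based

  ia <- memberInchis(a); ib <- memberInchis(b); ic <- memberInchis(cc)
  expect_true(all(ic %in% ib))
  expect_true(all(ib %in% ia))

  for (mixed in list(a, b, cc)) {
    baseRows <- members(mixed)[members(mixed)$origin == "base", ]
    expect_setequal(baseRows$compound_key, memberKeys(fx$base))
    expect_equal(anyDuplicated(memberInchis(mixed)), 0L)
  }
  expect_error(compileMixed(makeDataset(fixtureMoleculePool(5)[0, ], character(0),
                                        "proprietary_like"), fx$pub,
                            "a_target_only"), "empty base")
  expect_error(compileMixed(fx$base, fx$pub, "b_plus_assay_format"), "assay_format")
})

test_that("approach c equals the exhaustive maximum-similarity oracle", {
  pool <- fixtureMoleculePool(100)
  base <- makeDataset(pool[1:50, ], rep("active", 50), "proprietary_like")
  pub <- makeDataset(pool[51:100, ], rep("inactive", 50), "public_like")
  pub@compounds$assay_format <- "cell_based"

  cc <- compileMixed(base, pub, "c_plus_similarity", "cell_based",
                     threshold = 0.230)
  fpB <- qsarShift:::fpMatrix(computeFingerprint(members(base)$smiles,
                                                 memberKeys(base)))
  fpP <- qsarShift:::fpMatrix(computeFingerprint(members(pub)$smiles,
                                                 memberKeys(pub)))
  keep <- character(0)
  for (i in seq_len(nrow(fpP))) {
    best <- 0
    for (j in seq_len(nrow(fpB)))
      best <- max(best, tanimotoSimilarity(fpP[i, ], fpB[j, ]))
    if (best >= 0.230) keep <- c(keep, rownames(fpP)[i])
  }
  added <- members(cc)$compound_key[members(cc)$origin == "added_public"]
  expect_setequal(added, keep)
})

test_that("base labels win InChI collisions and the copy is logged", {
  pool <- fixtureMoleculePool(60)
  base <- makeDataset(pool[1:30, ], rep("active", 30), "proprietary_like")
  pubLib <- pool[c(1:10, 31:60), ]
  pub <- makeDataset(pubLib, rep("inactive", 40), "public_like")
  pub@compounds$compound_key[1:10] <- sprintf("PUBDUP%02d", 1:10)
  mixed <- compileMixed(base, pub, "a_target_only")
  expect_equal(nMembers(mixed), 60L)
  dupRows <- members(mixed)[members(mixed)$inchi %in% pool$inchi[1:10], ]
  expect_true(all(dupRows$label == "active"))
  expect_true(all(dupRows$origin == "base"))
  log <- curationLog(mixed)
  expect_equal(sum(grepl("collision", log$reason)), 10L)
})

test_that("fold-level mixing records have the expected long-format shape", {
  pool <- fixtureMoleculePool(200)
  base <- makeDataset(pool[1:80, ], rep(c("active", "inactive"), 40),
                      "proprietary_like")
  pub <- makeDataset(pool[81:200, ], rep(c("active", "inactive"), 60),
                     "public_like")
  pub@compounds$assay_format <- rep(c("cell_based", "cell_free"), 60)
  cfg <- runConfig(seed = 2L, kOuter = 3L, kInner = 3L)
  rec <- evaluateMixing(base, pub, "cell_based", cfg, algorithm = "rf",
                        schemes = "random",
                        approaches = c("a_target_only", "b_plus_assay_format"))
  expect_equal(nrow(rec), 2L * 3L)
  expect_setequal(unique(rec$approach), c("a_target_only", "b_plus_assay_format"))
  expect_true(all(rec$mcc >= -1 & rec$mcc <= 1))
})
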