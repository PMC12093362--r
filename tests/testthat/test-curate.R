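test_that("class assignment follows the asymmetric replicate-conflict rules", {
  # conflicting replicates: removal in the public-like domain ...
  pub <- assignClass(c(5, 50), "=", "public_like")
  expect_equal(pub$action, "remove")
  expect_match(pub$reason, "conflict")
  # ... but active in the proprietary-like domain
  prp <- assignClass(c(5, 50), "=", "proprietary_like")
  expect_equal(prp$action, "keep")
  expect_equal(prp$label, "active")
  # threshold: 10 uM, ties active
  expect_equal(assignClass(9.9, "=", "public_like")$label, "active")
  expect_equal(assignClass(10.1, "=", "public_like")$label, "inactive")
  expect_equal(assignClass(10, "=", "public_like")$label, "active")
  # unanimity keeps the unanimous label
  expect_equal(assignClass(c(50, 60), "=", "proprietary_like")$label, "inactive")
})

test_that("relation qualifiers classify only when directionally informative", {
  expect_equal(assignClass(50, ">", "public_like")$label, "inactive")
  expect_equal(assignClass(5, "<", "public_like")$label, "active")
  # uninformative qualified rows are unusable
  expect_equal(assignClass(5, ">", "public_like")$reason, "no usable measurement")
  expect_equal(assignClass(50, "<", "public_like")$reason, "no usable measurement")
})

test_that("eligibility rejections fire exactly at the documented edges", {
  cfg <- runConfig()
  pool <- fixtureMoleculePool(1000)

  makeSet <- function(n, nActive) {
    lib <- pool[seq_len(n), ]
    makeRows(lib$smiles, lib$compound_key,
             c(rep(1, nActive), rep(100, n - nActive)), "public_like")
  }
  ds249 <- buildTargetDataset(makeSet(249, 100), "T1", "public_like", cfg)
  expect_false(isEligible(ds249))
  expect_match(ds249@rejectReason, "size 249 < 250")

  ds250 <- buildTargetDataset(makeSet(250, 100), "T1", "public_like", cfg)
  expect_true(isEligible(ds250))
  expect_equal(nMembers(ds250), 250L)

  ds149 <- buildTargetDataset(makeSet(1000, 149), "T1", "public_like", cfg)
  expect_false(isEligible(ds149))
  expect_match(ds149@rejectReason, "minority 14.9%")

  ds150 <- buildTargetDataset(makeSet(1000, 150), "T1", "public_like", cfg)
  expect_true(isEligible(ds150))
})

test_that("planted conflicts resolve asymmetrically and are fully logged", {
  pool <- fixtureMoleculePool(320)
  clean <- pool[1:300, ]
  confl <- pool[301:320, ]
  cleanRows <- makeRows(clean$smiles, clean$compound_key,
                        rep(c(1, 100), 150), "public_like")
  conflRows <- rbind(
    makeRows(confl$smiles, confl$compound_key, rep(2, 20), "public_like"),
    makeRows(confl$smiles, confl$compound_key, rep(200, 20), "public_like"))

  pub <- buildTargetDataset(rbind(cleanRows, conflRows), "T1", "public_like",
                            runConfig())
  expect_true(isEligible(pub))
  expect_false(any(confl$compound_key %in% memberKeys(pub))) # all removed
  removedLog <- curationLog(pub)
  expect_setequal(removedLog$compound_key[grepl("conflict", removedLog$reason)],
                  confl$compound_key)

  prpRows <- rbind(cleanRows, conflRows)
  prpRows$domain <- "proprietary_like"
  prp <- buildTargetDataset(prpRows, "T1", "proprietary_like", runConfig())
  got <- members(prp)[match(confl$compound_key, memberKeys(prp)), ]
  expect_true(all(got$label == "active")) # all conflicted present as active
})

test_that("curation output is independent of input row order", {
  pool <- fixtureMoleculePool(300)
  rows <- makeRows(pool$smiles, pool$compound_key,
                   rep(c(1, 100), 150), "public_like")
  a <- buildTargetDataset(rows, "T1", "public_like", runConfig())
  set.seed(8)
  b <- buildTargetDataset(rows[sample(nrow(rows)), ], "T1", "public_like",
                          runConfig())
  expect_identical(members(a), members(b))
})

test_that("duplicate structures collapse to one member per InChI", {
  pool <- fixtureMoleculePool(260)
  rows <- makeRows(pool$smiles, pool$compound_key,
                   rep(c(2, 50), 130), "public_like")
  dup <- rows[1:10, ]
  dup$compound_key <- paste0(dup$compound_key, "_dup")
  ds <- buildTargetDataset(rbind(rows, dup), "T1", "public_like", runConfig())
  expect_true(isEligible(ds))
  expect_equal(anyDuplicated(memberInchis(ds)), 0L)
  expect_equal(nMembers(ds), 260L)
})
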