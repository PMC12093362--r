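test_that("library enumeration is combinatorial, valid and deduplicated", {
  spec <- domainStudySpec(nScaffolds = 2L, substituentsPerScaffold = 3L, seed = 2L)
  lib <- generateLibrary(spec)
  expect_equal(nrow(lib), 6L) # 2 scaffolds x 3 substituent pairs
  expect_equal(anyDuplicated(lib$inchi), 0L)
  expect_setequal(unique(lib$scaffold_id), 1:2)
  # every product is standardizable as emitted
  restd <- standardizeCompound(lib$smiles)
  expect_true(all(restd$ok))
})

test_that("scaffold pools share everything at full overlap and nothing at zero", {
  full <- qsarShift:::scaffoldPools(24, 1)
  expect_setequal(full$public, full$proprietary)
  none <- qsarShift:::scaffoldPools(24, 0)
  expect_length(intersect(none$public, none$proprietary), 0)
  expect_setequal(c(none$public, none$proprietary), 1:24)
})

test_that("studies are byte-identical under a fixed spec and seed", {
  spec <- domainStudySpec(nPerDomain = 120L, seed = 31L)
  d1 <- file.path(tempdir(), "study_a"); d2 <- file.path(tempdir(), "study_b")
  generateStudy(spec, dir = d1)
  generateStudy(spec, dir = d2)
  for (f in c("public_like.csv", "proprietary_like.csv", "ground_truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("domain sampling hits the skews, overlap and conflict structure", {
  study <- fixtureStudy(3)
  gt <- study@groundTruth
  pub <- gt[gt$domain == "public_like", ]
  prp <- gt[gt$domain == "proprietary_like", ]
  expect_equal(nrow(pub), 500L)
  # class skews by ground truth, within +-3 percentage points
  expect_lt(abs(mean(pub$true_label == "active") - 0.8), 0.03)
  expect_lt(abs(mean(prp$true_label == "active") - 0.2), 0.03)
  # exact identity overlap: 10% of 500
  expect_length(intersect(pub$compound_key, prp$compound_key), 50L)

  # planted conflicts: replicated compounds straddling 10 uM on both sides
  tab <- study@tables$public_like
  um <- ifelse(tab$standard_units == "nM", tab$standard_value / 1000,
               tab$standard_value)
  byCmp <- split(um, tab$compound_key)
  straddle <- vapply(byCmp, function(v) any(v <= 10) && any(v > 10), TRUE)
  replicated <- vapply(byCmp, function(v) length(v) > 1, TRUE)
  expect_gt(sum(straddle), 0)
  confRate <- sum(straddle) / sum(replicated)
  # planted ~5% of replicated compounds, plus chance straddles from
  # measurement noise around the threshold
  expect_gte(confRate, 0.03)
  expect_lte(confRate, 0.35)
})

test_that("ground truth stays out of the emitted activity tables", {
  study <- fixtureStudy(3)
  for (tab in study@tables) {
    expect_false(any(c("true_um", "true_label", "scaffold_id", "has_pharm")
                     %in% names(tab)))
  }
})

test_that("infeasible draws fail with the deficit named", {
  spec <- domainStudySpec(nScaffolds = 2L, substituentsPerScaffold = 10L,
                          nPerDomain = 400L, seed = 1L)
  expect_error(generateStudy(spec), "cannot supply")
  expect_error(domainStudySpec(scaffoldOverlap = 0, identityOverlap = 0.1),
               "identityOverlap")
})
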