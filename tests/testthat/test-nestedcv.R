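# A small separable fixture: labels depend on a two-feature interaction so
# depth-limited stumps fail while deeper trees succeed.
xorFixture <- function(n = 120, seed = 14) {
  set.seed(seed)
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(sprintf("s%03d", 1:n), NULL))
  y <- factor(ifelse(xor(x[, 1] > 0, x[, 2] > 0), "active", "inactive"),
              levels = c("active", "inactive"))
  list(x = x, y = y)
}

test_that("hyperparameter grids match the published search space", {
  rf <- hyperparamGrid("rf")
  expect_equal(sort(unique(rf$n_estimators)), c(50L, 100L, 200L))
  expect_equal(sort(unique(rf$max_depth), na.last = TRUE), c(10L, 20L, NA))
  expect_equal(nrow(rf), 9L)
  xgb <- hyperparamGrid("xgb")
  expect_equal(sort(unique(xgb$max_depth)), c(3L, 5L, 7L))
  svm <- hyperparamGrid("svm")
  expect_setequal(unique(svm$C), c(0.1, 1, 10))
  expect_setequal(unique(svm$kernel), c("linear", "rbf"))
  expect_equal(nrow(svm), 6L)
  expect_equal(anyDuplicated(rf), 0L)
})

test_that("inner selection maximizes mean inner MCC with documented tie-breaks", {
  fx <- xorFixture()
  oneRow <- data.frame(n_estimators = 100L, max_depth = NA_integer_)
  sel1 <- innerSelect(fx$x, fx$y, "rf", grid = oneRow, seed = 1L)
  expect_equal(sel1$index, 1L) # single combination is forced

  grid <- data.frame(n_estimators = c(100L, 100L), max_depth = c(1L, NA_integer_))
  sel <- innerSelect(fx$x, fx$y, "rf", grid = grid, seed = 1L)
  expect_equal(sel$index, 2L) # stumps cannot represent the interaction
  expect_gt(sel$meanMCC[2], sel$meanMCC[1])

  expect_error(innerSelect(fx$x, factor(rep("active", 120),
                                        levels = c("active", "inactive")),
                           "rf", seed = 1L), "single class")
})

test_that("final hyperparameters are the mode of outer selections", {
  # 5 x combination 2 + 4 x combination 1 -> combination 2
  expect_equal(qsarShift:::modeSelection(c(2, 2, 2, 2, 2, 1, 1, 1, 1)), 2L)
  expect_equal(qsarShift:::modeSelection(rep(3L, 9)), 3L)
  # ties resolve by higher mean outer MCC, then grid order
  expect_equal(qsarShift:::modeSelection(c(1, 1, 2, 2), c(0.2, 0.2, 0.5, 0.5)), 2L)
  expect_equal(qsarShift:::modeSelection(c(1, 1, 2, 2), c(0.5, 0.5, 0.5, 0.5)), 1L)
  set.seed(17)
  for (i in 1:50) {
    sel <- sample(1:4, 9, replace = TRUE)
    mcc <- runif(9)
    expect_equal(qsarShift:::modeSelection(sel, mcc), refMode(sel, mcc))
  }
})

test_that("nested CV has the 5/9 geometry and no outer-test leakage", {
  ds <- fixtureDataset(1, "public_like")
  dm <- fixtureEstate(ds, "pub1")
  cfg <- runConfig(seed = 1L)
  res <- fixtureCached("nested_pub_1", runNestedCV(ds, dm, "rf", "random", cfg))

  expect_equal(nrow(res@outerMetrics), 9L)
  expect_equal(length(res@selections), 9L)
  expect_true(res@finalHyperparams$n_estimators %in% c(50L, 100L, 200L))

  # recompute the outer folds and the documented inner-seed derivation:
  # inner folds must partition exactly the outer-train portion
  outer <- makeFolds(ds, cfg@kOuter, "random", seed = cfg@seed)
  fv <- foldVector(outer)[memberKeys(ds)]
  for (f in seq_len(cfg@kOuter)) {
    trainKeys <- names(fv)[fv != f]
    testKeys <- names(fv)[fv == f]
    inner <- makeFolds(trainKeys, cfg@kInner, "random",
                       seed = qsarShift:::deriveSeed(cfg@seed, f),
                       labels = members(ds)$label[match(trainKeys, memberKeys(ds))])
    expect_setequal(names(foldVector(inner)), trainKeys)
    expect_length(intersect(names(foldVector(inner)), testKeys), 0)
    expect_equal(sort(unique(foldVector(inner))), 1:5)
  }
})

test_that("final retraining is reproducible and guarded", {
  ds <- fixtureDataset(1, "public_like")
  dm <- fixtureEstate(ds, "pub1")
  hp <- list(n_estimators = 100L, max_depth = NA_integer_)
  b1 <- retrainFinal(ds, dm, "rf", hp, seed = 5L)
  b2 <- retrainFinal(ds, dm, "rf", hp, seed = 5L)
  x <- descriptorValues(dm)
  expect_identical(predictClassifier(b1@fit, x), predictClassifier(b2@fit, x))
  expect_equal(b1@datasetHash, b2@datasetHash)

  # training-set fit should do at least as well as out-of-fold estimates
  res <- .fixtures$nested_pub_1
  own <- metricValues(metricSuite(confusionCounts(
    memberLabels(ds), predictClassifier(b1@fit, x[memberKeys(ds), ]))))
  expect_gte(own[["mcc"]], mean(res@outerMetrics$mcc))

  empty <- makeDataset(fixtureMoleculePool(5)[0, ], character(0), "public_like")
  expect_error(retrainFinal(empty, dm, "rf", hp), "empty")
})

test_that("the SVM size cap refuses oversized fits with a clear message", {
  fx <- xorFixture(60)
  expect_error(
    fitClassifier("svm", fx$x, fx$y, list(C = 1, kernel = "linear"), svmMaxN = 50L),
    "cap")
  fit <- fitClassifier("svm", fx$x, fx$y, list(C = 1, kernel = "rbf"), svmMaxN = 100L)
  expect_s3_class(fit, "qsarShiftModel")
  expect_length(predictClassifier(fit, fx$x), 60L)
})

test_that("xgboost and svm backends run the full selection loop", {
  fx <- xorFixture(90)
  for (alg in c("xgb", "svm")) {
    grid <- hyperparamGrid(alg)[c(1, 5), ]
    sel <- innerSelect(fx$x, fx$y, alg, grid = grid, kInner = 3L, seed = 2L)
    expect_true(sel$index %in% 1:2)
    fit <- fitClassifier(alg, fx$x, fx$y, qsarShift:::gridRow(grid, sel$index),
                         seed = 3L)
    expect_length(predictClassifier(fit, fx$x), 90L)
  }
})
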