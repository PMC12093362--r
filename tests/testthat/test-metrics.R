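test_that("confusion counts match a brute-force tally", {
  expect_equal(confusionCounts(c(1, 0, 1), c(1, 0, 1)),
               c(tp = 2L, tn = 1L, fp = 0L, fn = 0L))
  expect_equal(confusionCounts(c(1, 1), c(0, 0))[["fn"]], 2L)
  expect_error(confusionCounts(c(1, 0), c(1)), "mismatch")

  set.seed(11)
  y <- sample(c("active", "inactive"), 1000, replace = TRUE)
  p <- sample(c("active", "inactive"), 1000, replace = TRUE)
  cc <- confusionCounts(y, p)
  tally <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (i in seq_along(y)) {
    slot <- if (y[i] == "active" && p[i] == "active") "tp"
      else if (y[i] == "inactive" && p[i] == "inactive") "tn"
      else if (y[i] == "inactive") "fp" else "fn"
    tally[slot] <- tally[slot] + 1L
  }
  expect_equal(cc, tally)
  expect_equal(sum(cc), 1000L)
})

test_that("metric suite reproduces the printed formulas", {
  perfect <- metricValues(metricSuite(c(tp = 50, tn = 50, fp = 0, fn = 0)))
  expect_true(all(perfect == 1))

  even <- metricValues(metricSuite(c(tp = 25, tn = 25, fp = 25, fn = 25)))
  expect_equal(even[["accuracy"]], 0.5)
  expect_equal(even[["balanced_accuracy"]], 0.5)
  expect_equal(even[["mcc"]], 0)

  m <- metricValues(metricSuite(c(tp = 90, fn = 10, tn = 40, fp = 60)))
  expect_equal(m[["sensitivity"]], 0.9)
  expect_equal(m[["specificity"]], 0.4)
  expect_equal(m[["balanced_accuracy"]], 0.65)
  # direct evaluation of the printed MCC formula
  expect_equal(m[["mcc"]], (90 * 40 - 60 * 10) / sqrt(100 * 150 * 100 * 50))
})

test_that("degenerate ratios surface as NaN and the MCC convention is logged", {
  rep <- metricSuite(c(tp = 0, tn = 5, fp = 0, fn = 0))
  m <- metricValues(rep)
  expect_true(is.nan(m[["sensitivity"]])) # no actives among labels
  expect_true(is.nan(m[["ppv"]]))         # no predicted actives
  expect_equal(m[["mcc"]], 0)
  expect_match(rep@notes, "zero factor", all = FALSE)
})

test_that("the fast selection-loop MCC equals the full suite's MCC", {
  set.seed(19)
  for (i in 1:50) {
    cc <- confusionCounts(sample(0:1, 30, TRUE), sample(0:1, 30, TRUE))
    expect_identical(qsarShift:::mccValue(cc),
                     unname(metricValues(metricSuite(cc))[["mcc"]]))
  }
})

test_that("label-swap symmetry and prediction inversion behave like a correlation", {
  set.seed(7)
  for (i in 1:20) {
    cc <- confusionCounts(sample(0:1, 60, TRUE), sample(0:1, 60, TRUE))
    m <- metricValues(metricSuite(cc))[["mcc"]]
    swapped <- c(tp = cc[["tn"]], tn = cc[["tp"]], fp = cc[["fn"]], fn = cc[["fp"]])
    inverted <- c(tp = cc[["fn"]], tn = cc[["fp"]], fp = cc[["tn"]], fn = cc[["tp"]])
    expect_equal(metricValues(metricSuite(swapped))[["mcc"]], m)
    expect_equal(metricValues(metricSuite(inverted))[["mcc"]], -m)
  }
})

test_that("f-measure equals the harmonic form of precision and sensitivity", {
  set.seed(3)
  for (i in 1:50) {
    cc <- confusionCounts(sample(0:1, 40, TRUE), sample(0:1, 40, TRUE))
    m <- metricValues(metricSuite(cc))
    if (!is.nan(m[["ppv"]]) && !is.nan(m[["sensitivity"]]) &&
        m[["ppv"]] + m[["sensitivity"]] > 0) {
      expect_equal(m[["f_measure"]],
                   2 * m[["ppv"]] * m[["sensitivity"]] / (m[["ppv"]] + m[["sensitivity"]]))
    }
  }
})
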