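## Cross-domain application of frozen models: InChI leakage filtering,
## evaluation on the other domain's curated set, over-prediction diagnosis.

#' Remove train-set compounds from a test set (leakage filter)
#'
#' Compounds present in the training set are filtered out of the test set
#' by stereo-free InChI; a pure set operation, idempotent and independent of
#' input order. Every removal is logged individually.
#'
#' @param test_set,train_set [ClassifiedDataset-class] objects for the same
#'   target.
#' @return list with `dataset` (filtered test set) and `removed` (character
#'   vector of removed compound keys).
#' @export
filterLeakage <- function(test_set, train_set) {
  trainInchis <- memberInchis(train_set)
  hit <- memberInchis(test_set) %in% trainInchis
  removedKeys <- memberKeys(test_set)[hit]
  out <- test_set
  out@compounds <- test_set@compounds[!hit, , drop = FALSE]
  if (length(removedKeys)) {
    out@curationLog <- rbind(out@curationLog,
      data.frame(compound_key = removedKeys, action = "removed",
                 reason = "train-set leakage (shared InChI)",
                 stringsAsFactors = FALSE))
  }
  list(dataset = out, removed = removedKeys)
}

biasCall <- function(fp, fn, n, margin = 0.05) {
  if (abs(fp - fn) > margin * n) {
    if (fp > fn) "overpredicts_actives" else "overpredicts_inactives"
  } else "balanced"
}

#' Evaluate a frozen model on the other domain's data set
#'
#' The model is applied as-is (no refit or recalibration). The test set must
#' already be leakage-filtered: any test compound whose InChI appears in the
#' bundle's training set is an error.
#'
#' @param bundle a [ModelBundle-class].
#' @param test_set leakage-filtered [ClassifiedDataset-class].
#' @param descriptors [DescriptorMatrix-class] for the test set, same
#'   provider as the bundle.
#' @param train_domain,target optional provenance overrides.
#' @return a [CrossEvalReport-class].
#' @export
evaluateCross <- function(bundle, test_set, descriptors,
                          train_domain = NA_character_, target = NA_character_) {
  if (bundle@provider != descriptorProvider(descriptors))
    stopf("descriptor provider mismatch: model %s vs matrix %s",
          bundle@provider, descriptorProvider(descriptors))
  leaked <- memberInchis(test_set) %in% bundle@trainInchis
  if (any(leaked))
    stopf("leakage: %d test compound(s) are in the model's training set; run filterLeakage first",
          sum(leaked))
  x <- descriptorValues(descriptors)
  keys <- memberKeys(test_set)
  if (!setequal(rownames(x), keys)) stop("descriptor matrix is not aligned")
  x <- x[keys, , drop = FALSE]
  if (length(bundle@featureNames) && !is.null(colnames(x)) &&
      !identical(colnames(x), bundle@featureNames))
    stop("feature columns differ from the model's training features")
  pred <- predictClassifier(bundle@fit, x)
  rep <- metricSuite(confusionCounts(memberLabels(test_set), pred),
                     context = list(train_domain = train_domain,
                                    test_domain = test_set@domain,
                                    target = target, model = bundle@algorithm))
  counts <- confusionValues(rep)
  nBefore <- nMembers(test_set) + sum(grepl("leakage", curationLog(test_set)$reason))
  nRemoved <- sum(grepl("leakage", curationLog(test_set)$reason))
  new("CrossEvalReport",
      trainDomain = train_domain %||% NA_character_,
      testDomain = test_set@domain,
      target = if (is.na(target)) test_set@target else target,
      nTestBefore = as.integer(nBefore),
      nRemovedLeakage = as.integer(nRemoved),
      nTestAfter = nMembers(test_set),
      metrics = rep,
      biasDirection = biasCall(counts[["fp"]], counts[["fn"]], nMembers(test_set)))
}

#' Diagnose over-prediction bias from a cross-evaluation report
#'
#' A directional call requires |fp - fn| > 0.05 * n; smaller asymmetries are
#' reported as balanced so prediction noise is not labeled as bias.
#'
#' @param report a [CrossEvalReport-class] or [MetricsReport-class].
#' @return list with `direction`, `fp`, `fn` and the margin used.
#' @export
biasDiagnostic <- function(report) {
  rep <- if (is(report, "CrossEvalReport")) report@metrics else report
  counts <- confusionValues(rep)
  n <- sum(counts)
  list(direction = biasCall(counts[["fp"]], counts[["fn"]], n),
       fp = unname(counts[["fp"]]), fn = unname(counts[["fn"]]),
       margin = 0.05 * n)
}
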