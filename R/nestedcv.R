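## Nested cross-validation: an outer loop for evaluation, an inner loop for
## hyperparameter tuning, and final retraining with the mode of the outer
## selections (the most frequently selected combination is less prone to
## overfitting than the single highest-MCC combination).

#' Select hyperparameters by inner cross-validation
#'
#' Runs class-stratified k-fold cross-validation on the training portion for
#' every grid combination and returns the one maximizing mean validation
#' MCC; exact ties go to the earlier grid row.
#'
#' @param x feature matrix of the training portion.
#' @param y labels (factor active/inactive).
#' @param algorithm `rf`, `xgb` or `svm`.
#' @param grid hyperparameter grid (default [hyperparamGrid()]).
#' @param kInner inner fold count (default 5).
#' @param seed seed for the inner folds and fits.
#' @param svmMaxN see [fitClassifier()].
#' @return list with `hyperparams`, `index` (grid row) and `meanMCC` per
#'   combination.
#' @export
innerSelect <- function(x, y, algorithm, grid = hyperparamGrid(algorithm),
                        kInner = 5L, seed = 1L, svmMaxN = 5000L) {
  y <- factor(y, levels = LABELS)
  if (length(unique(y)) < 2L) stop("training portion has a single class")
  keys <- rownames(x) %||% sprintf("r%d", seq_len(nrow(x)))
  folds <- makeFolds(keys, kInner, "random", seed = seed, labels = y)
  fv <- unname(foldVector(folds))
  scores <- matrix(0, nrow(grid), kInner)
  for (f in seq_len(kInner)) {
    tr <- fv != f
    xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
    xte <- x[!tr, , drop = FALSE]; yte <- y[!tr]
    for (g in seq_len(nrow(grid))) {
      fit <- fitClassifier(algorithm, xtr, ytr, gridRow(grid, g),
                           seed = deriveSeed(seed, g * 100 + f), svmMaxN = svmMaxN)
      pred <- predictClassifier(fit, xte)
      scores[g, f] <- mccValue(confusionCounts(yte, pred))
    }
  }
  scores <- rowMeans(scores)
  best <- which.max(scores) # ties: first in grid order
  list(hyperparams = gridRow(grid, best), index = best, meanMCC = scores)
}

# Mode of the per-outer-fold selections; ties resolved by higher mean
# outer-test MCC among the tied combinations, then by grid order.
modeSelection <- function(indices, outerMCC = NULL) {
  tab <- table(indices)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) == 1L) return(top)
  if (!is.null(outerMCC)) {
    means <- vapply(top, function(i) mean(outerMCC[indices == i]), numeric(1))
    top <- top[means == max(means)]
  }
  min(top)
}

#' Run nested cross-validation on one data set
#'
#' For each of `kOuter` outer folds, hyperparameters are selected by
#' [innerSelect()] on the outer-training portion only (inner folds never see
#' the outer test compounds), a model is fitted on the outer-training portion
#' and evaluated on the outer test fold. The final hyperparameters are the
#' mode of the outer selections.
#'
#' @param dataset a [ClassifiedDataset-class] (eligible).
#' @param descriptors a [DescriptorMatrix-class] aligned to `dataset`.
#' @param algorithm `rf`, `xgb` or `svm`.
#' @param scheme `random` or `cluster` outer splitting.
#' @param config a [RunConfig-class].
#' @param fingerprints fingerprints of the members, required for the cluster
#'   scheme (a [ChemmineR::FPset-class]); clustered with [butinaCluster()] at
#'   `config@similarityThreshold`.
#' @param grid optional hyperparameter grid override.
#' @return a [NestedCVResult-class].
#' @export
runNestedCV <- function(dataset, descriptors, algorithm = "rf",
                        scheme = c("random", "cluster"), config = runConfig(),
                        fingerprints = NULL, grid = hyperparamGrid(algorithm)) {
  scheme <- match.arg(scheme)
  if (!isEligible(dataset)) stop("dataset failed curation eligibility")
  x <- descriptorValues(descriptors)
  keys <- memberKeys(dataset)
  if (!setequal(rownames(x), keys))
    stop("descriptor matrix is not aligned to the dataset (use alignToDescriptors)")
  x <- x[keys, , drop = FALSE]
  y <- memberLabels(dataset)
  clusters <- NULL
  if (scheme == "cluster") {
    if (is.null(fingerprints)) stop("cluster scheme requires fingerprints")
    clusters <- butinaCluster(fingerprints, config@similarityThreshold)
  }
  outer <- makeFolds(dataset, config@kOuter, scheme, clusters = clusters,
                     seed = config@seed)
  fv <- unname(foldVector(outer)[keys])

  rows <- list(); selections <- list()
  for (f in seq_len(config@kOuter)) {
    tr <- fv != f; te <- !tr
    if (!any(te)) stopf("outer fold %d is empty", f)
    innerSeed <- deriveSeed(config@seed, f)
    sel <- innerSelect(x[tr, , drop = FALSE], y[tr], algorithm, grid,
                       kInner = config@kInner, seed = innerSeed,
                       svmMaxN = config@svmMaxN)
    fit <- fitClassifier(algorithm, x[tr, , drop = FALSE], y[tr],
                         sel$hyperparams, seed = deriveSeed(config@seed, 10000 + f),
                         svmMaxN = config@svmMaxN)
    pred <- predictClassifier(fit, x[te, , drop = FALSE])
    rep <- metricSuite(confusionCounts(y[te], pred),
                       context = list(fold = f, scheme = scheme,
                                      algorithm = algorithm,
                                      target = dataset@target,
                                      domain = dataset@domain))
    rows[[f]] <- data.frame(fold = f, grid_index = sel$index,
                            t(metricValues(rep)))
    selections[[f]] <- sel$hyperparams
  }
  outerMetrics <- do.call(rbind, rows)
  finalIdx <- modeSelection(outerMetrics$grid_index, outerMetrics$mcc)
  new("NestedCVResult",
      outerMetrics = outerMetrics, selections = selections,
      finalHyperparams = gridRow(grid, finalIdx),
      algorithm = algorithm, scheme = scheme,
      provider = descriptorProvider(descriptors), seed = config@seed)
}

#' Retrain the final model on the full data set
#'
#' @param dataset a [ClassifiedDataset-class].
#' @param descriptors aligned [DescriptorMatrix-class].
#' @param algorithm `rf`, `xgb` or `svm`.
#' @param hyperparams final hyperparameters (e.g.
#'   `result@finalHyperparams` from [runNestedCV()]).
#' @param seed fitting seed.
#' @param svmMaxN see [fitClassifier()].
#' @return a [ModelBundle-class] recording the training-set hash.
#' @export
retrainFinal <- function(dataset, descriptors, algorithm, hyperparams,
                         seed = 1L, svmMaxN = 5000L) {
  if (nMembers(dataset) == 0L) stop("empty dataset")
  x <- descriptorValues(descriptors)
  keys <- memberKeys(dataset)
  if (!setequal(rownames(x), keys)) stop("descriptor matrix is not aligned")
  x <- x[keys, , drop = FALSE]
  fit <- fitClassifier(algorithm, x, memberLabels(dataset), hyperparams,
                       seed = seed, svmMaxN = svmMaxN)
  inchis <- memberInchis(dataset)
  new("ModelBundle", fit = fit, algorithm = algorithm,
      provider = descriptorProvider(descriptors),
      hyperparams = hyperparams,
      featureNames = colnames(x) %||% character(0),
      trainInchis = inchis,
      datasetHash = hashStrings(sort(inchis)),
      seed = as.integer(seed))
}
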