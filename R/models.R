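## Pluggable classifier backends behind a common fit/predict contract.
## The three algorithms are configuration, not code forks: random forest via
## ranger, gradient boosting via xgboost, support vector machine via e1071.

#' Hyperparameter grids for the three classifier families
#'
#' Random forest: n_estimators in {50, 100, 200} x max_depth in
#' {unlimited, 10, 20}. XGBoost: n_estimators in {50, 100, 200} x max_depth
#' in {3, 5, 7}. SVM: C in {0.1, 1, 10} x kernel in {linear, rbf}. The row
#' order of the returned grid is the documented tie-break order.
#'
#' @param algorithm `rf`, `xgb` or `svm`.
#' @return data.frame of unique hyperparameter combinations.
#' @export
hyperparamGrid <- function(algorithm = c("rf", "xgb", "svm")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    rf = expand.grid(n_estimators = c(50L, 100L, 200L),
                     max_depth = c(NA_integer_, 10L, 20L)),
    xgb = expand.grid(n_estimators = c(50L, 100L, 200L),
                      max_depth = c(3L, 5L, 7L)),
    svm = expand.grid(C = c(0.1, 1, 10),
                      kernel = c("linear", "rbf"), stringsAsFactors = FALSE))
}

gridRow <- function(grid, i) as.list(grid[i, , drop = FALSE])

#' Fit one classifier
#'
#' @param algorithm `rf`, `xgb` or `svm`.
#' @param x numeric feature matrix (rows = compounds).
#' @param y factor with levels active/inactive.
#' @param hyperparams one row of [hyperparamGrid()] as a list.
#' @param seed fitting seed.
#' @param svmMaxN refuse SVM fits above this training-set size (the cubic
#'   scaling of kernel SVMs makes very large sets impractical).
#' @return opaque fitted model (to be used with [predictClassifier()]).
#' @export
fitClassifier <- function(algorithm, x, y, hyperparams, seed = 1L, svmMaxN = 5000L) {
  y <- factor(y, levels = LABELS)
  if (length(unique(y[!is.na(y)])) < 2L) stop("training portion has a single class")
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  if (algorithm == "rf") {
    depth <- hyperparams$max_depth
    fit <- ranger::ranger(
      x = x, y = y,
      num.trees = hyperparams$n_estimators,
      max.depth = if (is.na(depth)) 0 else depth,
      seed = as.integer(seed), num.threads = 1L,
      verbose = FALSE)
    return(structure(list(fit = fit, algorithm = "rf"), class = "qsarShiftModel"))
  }
  if (algorithm == "xgb") {
    fit <- withSeed(seed, xgboost::xgb.train(
      params = list(max_depth = hyperparams$max_depth,
                    objective = "binary:logistic", nthread = 1L, eta = 0.3,
                    tree_method = "hist"),
      data = xgboost::xgb.DMatrix(x, label = as.numeric(y == "active"),
                                  nthread = 1L),
      nrounds = hyperparams$n_estimators, verbose = 0))
    return(structure(list(fit = fit, algorithm = "xgb"), class = "qsarShiftModel"))
  }
  if (algorithm == "svm") {
    if (nrow(x) > svmMaxN)
      stopf(paste("SVM fit refused: training set has %d compounds, above the",
                  "configured cap of %d; raise svmMaxN deliberately if needed"),
            nrow(x), svmMaxN)
    kernel <- if (identical(hyperparams$kernel, "rbf")) "radial" else "linear"
    fit <- withSeed(seed, e1071::svm(
      x = x, y = y, cost = hyperparams$C, kernel = kernel, scale = FALSE))
    return(structure(list(fit = fit, algorithm = "svm"), class = "qsarShiftModel"))
  }
  stopf("unknown algorithm '%s'", algorithm)
}

#' Predict activity labels
#'
#' @param model a fitted model from [fitClassifier()].
#' @param x numeric feature matrix.
#' @return factor of predicted labels with levels active/inactive.
#' @export
predictClassifier <- function(model, x) {
  stopifnot(inherits(model, "qsarShiftModel"))
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  if (model$algorithm == "rf") {
    p <- predict(model$fit, data = x, num.threads = 1L)$predictions
    return(factor(as.character(p), levels = LABELS))
  }
  if (model$algorithm == "xgb") {
    p <- predict(model$fit, newdata = x)
    return(factor(ifelse(p >= 0.5, "active", "inactive"), levels = LABELS))
  }
  p <- predict(model$fit, newdata = x)
  factor(as.character(p), levels = LABELS)
}
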