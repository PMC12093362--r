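## Confusion counts and the eight binary-classification statistics.

# Bare MCC from confusion counts (same formula and zero-factor convention as
# metricSuite) for hot loops that only rank by MCC.
mccValue <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); tn <- as.numeric(counts[["tn"]])
  fp <- as.numeric(counts[["fp"]]); fn <- as.numeric(counts[["fn"]])
  den <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
}

#' Confusion counts from labels and predictions
#'
#' A true active prediction is a true positive.
#'
#' @param labels,predictions vectors coercible to character with values
#'   `active`/`inactive` (or logical/0-1 with TRUE/1 = active).
#' @return named integer vector (tp, tn, fp, fn).
#' @export
confusionCounts <- function(labels, predictions) {
  toAct <- function(x) {
    if (is.logical(x)) return(ifelse(x, "active", "inactive"))
    if (is.numeric(x)) return(ifelse(x > 0, "active", "inactive"))
    as.character(x)
  }
  y <- toAct(labels); p <- toAct(predictions)
  if (length(y) != length(p)) stopf("length mismatch: %d labels vs %d predictions",
                                    length(y), length(p))
  if (!length(y)) stop("need at least one observation")
  c(tp = sum(y == "active" & p == "active"),
    tn = sum(y == "inactive" & p == "inactive"),
    fp = sum(y == "inactive" & p == "active"),
    fn = sum(y == "active" & p == "inactive"))
}

#' The eight evaluation statistics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), balanced accuracy
#' (sensitivity+specificity)/2, accuracy (TP+TN)/n, positive predictive
#' value TP/(TP+FP), negative predictive value TN/(TN+FN), F-measure
#' 2*(PPV*sensitivity)/(PPV+sensitivity) and the Matthews correlation
#' coefficient (TP*TN - FP*FN)/sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)).
#' A ratio with zero denominator is NaN (never silently 0); an MCC whose
#' root contains a zero factor is 0 by convention, noted in the report.
#'
#' @param counts named vector (tp, tn, fp, fn) as from [confusionCounts()].
#' @param context optional provenance list stored in the report.
#' @return a [MetricsReport-class].
#' @examples
#' metricSuite(c(tp = 90, tn = 40, fp = 60, fn = 10))
#' @export
metricSuite <- function(counts, context = list()) {
  stopifnot(all(c("tp", "tn", "fp", "fn") %in% names(counts)))
  tp <- as.numeric(counts[["tp"]]); tn <- as.numeric(counts[["tn"]])
  fp <- as.numeric(counts[["fp"]]); fn <- as.numeric(counts[["fn"]])
  if (any(c(tp, tn, fp, fn) < 0) || tp + tn + fp + fn < 1)
    stop("invalid confusion counts")
  ratio <- function(num, den) if (den == 0) NaN else num / den
  notes <- character(0)
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  bacc <- (sens + spec) / 2
  acc <- ratio(tp + tn, tp + fp + tn + fn)
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  fme <- if (is.nan(ppv) || is.nan(sens) || ppv + sens == 0) NaN else
    2 * (ppv * sens) / (ppv + sens)
  mccDen <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- if (mccDen == 0) {
    notes <- c(notes, "mcc denominator had a zero factor; value 0 by convention")
    0
  } else (tp * tn - fp * fn) / sqrt(mccDen)
  new("MetricsReport",
      counts = setNames(as.integer(c(tp, tn, fp, fn)), c("tp", "tn", "fp", "fn")),
      metrics = c(sensitivity = sens, specificity = spec,
                  balanced_accuracy = bacc, accuracy = acc, ppv = ppv, npv = npv,
                  f_measure = fme, mcc = mcc),
      notes = notes, context = context)
}
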