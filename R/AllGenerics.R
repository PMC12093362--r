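#' Accessors for pipeline objects
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param x a pipeline object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("nMembers", function(x) standardGeneric("nMembers"))
#' @rdname accessors
#' @export
setGeneric("memberKeys", function(x) standardGeneric("memberKeys"))
#' @rdname accessors
#' @export
setGeneric("memberLabels", function(x) standardGeneric("memberLabels"))
#' @rdname accessors
#' @export
setGeneric("memberInchis", function(x) standardGeneric("memberInchis"))
#' @rdname accessors
#' @export
setGeneric("curationLog", function(x) standardGeneric("curationLog"))
#' @rdname accessors
#' @export
setGeneric("isEligible", function(x) standardGeneric("isEligible"))
#' @rdname accessors
#' @export
setGeneric("descriptorProvider", function(x) standardGeneric("descriptorProvider"))
#' @rdname accessors
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))
#' @rdname accessors
#' @export
setGeneric("foldVector", function(x) standardGeneric("foldVector"))
#' @rdname accessors
#' @export
setGeneric("clusterVector", function(x) standardGeneric("clusterVector"))
#' @rdname accessors
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))
#' @rdname accessors
#' @export
setGeneric("confusionValues", function(x) standardGeneric("confusionValues"))

setMethod("members", "ClassifiedDataset", function(x) x@compounds)
setMethod("nMembers", "ClassifiedDataset", function(x) nrow(x@compounds))
setMethod("memberKeys", "ClassifiedDataset", function(x) x@compounds$compound_key)
setMethod("memberLabels", "ClassifiedDataset", function(x) factor(x@compounds$label, levels = LABELS))
setMethod("memberInchis", "ClassifiedDataset", function(x) x@compounds$inchi)
setMethod("curationLog", "ClassifiedDataset", function(x) x@curationLog)
setMethod("isEligible", "ClassifiedDataset", function(x) x@eligible)

setMethod("descriptorProvider", "DescriptorMatrix", function(x) x@provider)
setMethod("descriptorValues", "DescriptorMatrix", function(x) x@values)
setMethod("foldVector", "FoldAssignment", function(x) x@fold)
setMethod("clusterVector", "FoldAssignment", function(x) x@clusterId)
setMethod("clusterVector", "ClusterAssignment", function(x) x@clusterId)
setMethod("metricValues", "MetricsReport", function(x) x@metrics)
setMethod("confusionValues", "MetricsReport", function(x) x@counts)

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig\n")
  cat(sprintf("  activity threshold: %g uM; eligibility: >= %d compounds, >= %d%% minority\n",
              object@activityThresholdUM, object@minDatasetSize,
              round(100 * object@minMinorityFraction)))
  cat(sprintf("  nested CV: %d inner / %d outer folds; Tanimoto threshold %.3f\n",
              object@kInner, object@kOuter, object@similarityThreshold))
  cat(sprintf("  fingerprints: %d bits; seed: %d\n", object@fingerprintBits, object@seed))
})

setMethod("show", "ClassifiedDataset", function(object) {
  cat(sprintf("ClassifiedDataset: target %s, domain %s\n", object@target, object@domain))
  if (object@eligible) {
    tab <- table(factor(object@compounds$label, levels = LABELS))
    cat(sprintf("  %d compounds (%d active / %d inactive), %d curation-log entries\n",
                nrow(object@compounds), tab[["active"]], tab[["inactive"]],
                nrow(object@curationLog)))
  } else {
    cat(sprintf("  REJECTED: %s\n", object@rejectReason))
  }
})

setMethod("show", "DescriptorMatrix", function(object) {
  cat(sprintf("DescriptorMatrix [%s]: %d compounds x %d features; %d dropped\n",
              object@provider, nrow(object@values), ncol(object@values),
              nrow(object@dropped)))
})

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d compounds in %d folds (scheme %s, seed %d)\n",
              length(object@fold), object@k, object@scheme, object@seed))
  print(table(fold = object@fold))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d compounds in %d clusters (Tanimoto >= %.3f)\n",
              length(object@clusterId), length(object@centroids), object@threshold))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n  counts:", paste(names(object@counts), object@counts,
                                        sep = "=", collapse = " "), "\n")
  print(round(object@metrics, 4))
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "NestedCVResult", function(object) {
  cat(sprintf("NestedCVResult: %s / %s splits, %d outer folds (seed %d)\n",
              object@algorithm, object@scheme, nrow(object@outerMetrics), object@seed))
  cat(sprintf("  mean outer MCC: %.3f\n", mean(object@outerMetrics$mcc)))
  cat("  final hyperparameters:",
      paste(names(object@finalHyperparams), unlist(object@finalHyperparams),
            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "CrossEvalReport", function(object) {
  cat(sprintf("CrossEvalReport: %s model -> %s test set (target %s)\n",
              object@trainDomain, object@testDomain, object@target))
  cat(sprintf("  test set %d -> %d after removing %d leaked compounds\n",
              object@nTestBefore, object@nTestAfter, object@nRemovedLeakage))
  cat(sprintf("  MCC %.3f; bias: %s\n", object@metrics@metrics[["mcc"]], object@biasDirection))
})

setMethod("show", "ModelBundle", function(object) {
  cat(sprintf("ModelBundle: %s on %s descriptors (%d training compounds, seed %d)\n",
              object@algorithm, object@provider, length(object@trainInchis), object@seed))
})

setMethod("show", "SyntheticStudy", function(object) {
  ns <- vapply(object@tables, nrow, 0L)
  cat(sprintf("SyntheticStudy: %s measurement rows (%s), %d ground-truth compounds\n",
              paste(ns, collapse = " + "), paste(names(ns), collapse = " + "),
              nrow(object@groundTruth)))
})

setMethod("show", "EmbeddingProvider", function(object) {
  cat(sprintf("EmbeddingProvider: %d keys, dimension %d\n",
              nrow(object@vectors), ncol(object@vectors)))
})
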