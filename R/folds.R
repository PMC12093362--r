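## Fold construction for nested cross-validation: class-stratified random
## folds, or cluster-integrity folds in which no Butina cluster spans folds.

#' Construct cross-validation folds
#'
#' Random scheme: compounds are shuffled within each class under the seed and
#' dealt cyclically, giving class-stratified folds whose sizes differ by at
#' most one. Cluster scheme: clusters are sorted by decreasing size (ties by
#' cluster id) and each is assigned to the currently smallest fold, so no
#' cluster ever spans two folds.
#'
#' @param dataset a [ClassifiedDataset-class], or a character vector of
#'   compound keys together with `labels`.
#' @param k number of folds.
#' @param scheme `random` or `cluster`.
#' @param clusters a [ClusterAssignment-class]; required for the cluster
#'   scheme.
#' @param seed integer seed.
#' @param labels optional label vector when `dataset` is a key vector.
#' @return a [FoldAssignment-class] with folds in 1..k.
#' @export
makeFolds <- function(dataset, k, scheme = c("random", "cluster"),
                      clusters = NULL, seed = 1L, labels = NULL) {
  scheme <- match.arg(scheme)
  if (is(dataset, "ClassifiedDataset")) {
    keys <- memberKeys(dataset)
    labels <- as.character(memberLabels(dataset))
  } else {
    keys <- as.character(dataset)
    labels <- if (is.null(labels)) rep("all", length(keys)) else as.character(labels)
  }
  n <- length(keys)
  k <- as.integer(k)
  if (scheme == "random") {
    if (k > n) stopf("k = %d folds but only %d compounds", k, n)
    fold <- integer(n)
    withSeed(seed, {
      ord <- unlist(lapply(split(seq_len(n), labels), sample), use.names = FALSE)
      fold[ord] <- rep_len(seq_len(k), n)
    })
    return(new("FoldAssignment", fold = setNames(fold, keys), k = k,
               scheme = "random", seed = as.integer(seed), clusterId = integer(0)))
  }
  if (is.null(clusters)) stop("cluster scheme requires a ClusterAssignment")
  cid <- clusterVector(clusters)[keys]
  if (anyNA(cid)) stop("cluster assignment does not cover all compounds")
  sizes <- table(cid)
  sizes <- sizes[order(-as.numeric(sizes), as.numeric(names(sizes)))]
  if (k > length(sizes))
    stopf("k = %d folds but only %d clusters", k, length(sizes))
  foldSize <- setNames(numeric(k), seq_len(k))
  foldOf <- setNames(integer(length(sizes)), names(sizes))
  for (cl in names(sizes)) {
    target <- which.min(foldSize) # ties: lowest fold index
    foldOf[cl] <- target
    foldSize[target] <- foldSize[target] + sizes[[cl]]
  }
  fold <- unname(foldOf[as.character(cid)])
  new("FoldAssignment", fold = setNames(as.integer(fold), keys), k = k,
      scheme = "cluster", seed = as.integer(seed),
      clusterId = setNames(as.integer(cid), keys))
}
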