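## Tanimoto similarity and Butina sphere-exclusion clustering.

fpMatrix <- function(fp) {
  if (is(fp, "FPset")) {
    m <- fp@fpma
    storage.mode(m) <- "numeric"
    m
  } else if (is.matrix(fp)) {
    storage.mode(fp) <- "numeric"
    fp
  } else if (is.numeric(fp) || is.logical(fp)) {
    matrix(as.numeric(fp), nrow = 1)
  } else stop("expected an FPset, a 0/1 matrix or a bit vector")
}

#' Tanimoto similarity of two fingerprints
#'
#' The ratio of shared on-bits to the total number of on-bits in either
#' fingerprint. Two empty fingerprints have similarity 0, with a warning.
#'
#' @param a,b fingerprints: 0/1 vectors, single-row matrices or 1-compound
#'   [ChemmineR::FPset-class] objects over the same bit universe.
#' @return similarity in `[0, 1]`.
#' @examples
#' tanimotoSimilarity(c(1, 1, 1, 0), c(0, 1, 1, 1)) # 2 shared / 4 union
#' @export
tanimotoSimilarity <- function(a, b) {
  va <- as.numeric(fpMatrix(a)[1, ]); vb <- as.numeric(fpMatrix(b)[1, ])
  if (length(va) != length(vb)) stop("fingerprints live in different bit universes")
  inter <- sum(va * vb)
  union <- sum(va) + sum(vb) - inter
  if (union == 0) {
    warning("both fingerprints are empty; similarity defined as 0")
    return(0)
  }
  inter / union
}

#' All-pairs Tanimoto similarity matrix
#'
#' @param fpA fingerprints (rows are compounds).
#' @param fpB optional second set; defaults to `fpA`.
#' @return numeric matrix of similarities, rows from `fpA`, columns from
#'   `fpB`.
#' @export
tanimotoMatrix <- function(fpA, fpB = NULL) {
  A <- fpMatrix(fpA)
  B <- if (is.null(fpB)) A else fpMatrix(fpB)
  if (ncol(A) != ncol(B)) stop("fingerprints live in different bit universes")
  inter <- A %*% t(B)
  ra <- rowSums(A); rb <- rowSums(B)
  union <- outer(ra, rb, "+") - inter
  sim <- ifelse(union == 0, 0, inter / union)
  dimnames(sim) <- list(rownames(A), rownames(B))
  sim
}

#' Butina sphere-exclusion clustering
#'
#' Greedy sphere exclusion on a fingerprint set: neighbor lists are built at
#' Tanimoto similarity at or above `threshold`; the unassigned compound with
#' the most unassigned neighbors (ties: lowest input index) becomes the next
#' cluster centroid and claims its unassigned neighbors; compounds without
#' neighbors end as singleton clusters. Every non-centroid member therefore
#' has similarity at least `threshold` to its centroid. Cluster ids are dense
#' from 1 in order of creation.
#'
#' @param fp fingerprints ([ChemmineR::FPset-class] or 0/1 matrix with
#'   rownames).
#' @param threshold Tanimoto similarity threshold (default 0.230).
#' @return a [ClusterAssignment-class].
#' @export
butinaCluster <- function(fp, threshold = 0.230) {
  m <- fpMatrix(fp)
  n <- nrow(m)
  if (n < 1L) stop("need at least one fingerprint")
  keys <- rownames(m) %||% sprintf("cmp%d", seq_len(n))
  sim <- tanimotoMatrix(m)
  nbr <- sim >= threshold
  diag(nbr) <- FALSE
  assigned <- rep(FALSE, n)
  clusterId <- integer(n)
  centroids <- character(0)
  cl <- 0L
  counts <- rowSums(nbr)
  while (!all(assigned)) {
    counts <- rowSums(nbr[, !assigned, drop = FALSE]) # unassigned neighbors
    counts[assigned] <- -1L
    centroid <- which.max(counts) # ties: lowest index
    cl <- cl + 1L
    membersIdx <- c(centroid, which(nbr[centroid, ] & !assigned))
    membersIdx <- unique(membersIdx)
    clusterId[membersIdx] <- cl
    assigned[membersIdx] <- TRUE
    centroids[cl] <- keys[centroid]
  }
  new("ClusterAssignment", clusterId = setNames(clusterId, keys),
      centroids = centroids, threshold = threshold)
}
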