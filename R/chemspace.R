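## Chemical-space diagnostics between two domains: nearest-neighbor mean
## Tanimoto similarity, 2-D manifold embedding and physicochemical
## distribution comparison. These quantify chemical-space divergence; they
## are diagnostics, not performance predictors.

#' Nearest-neighbor mean Tanimoto similarity between two sets
#'
#' For each query compound, the maximum Tanimoto similarity over the
#' reference set; the report carries the per-query nearest neighbors and the
#' arithmetic mean of the maxima. The measure is directional: the default
#' convention is query = proprietary-like, reference = public-like.
#'
#' @param query_fp,reference_fp fingerprint sets
#'   ([ChemmineR::FPset-class] or 0/1 matrices with compound-key rownames).
#' @param direction label recorded in the report.
#' @return list with `pairs` (data.frame query_key, neighbor_key,
#'   similarity), `mean_nn_similarity` and `direction`.
#' @export
nnMeanTanimoto <- function(query_fp, reference_fp,
                           direction = "proprietary_like->public_like") {
  Q <- fpMatrix(query_fp); R <- fpMatrix(reference_fp)
  if (nrow(Q) == 0L || nrow(R) == 0L) stop("both sets must be non-empty")
  sim <- tanimotoMatrix(Q, R)
  best <- max.col(sim, ties.method = "first")
  bestSim <- sim[cbind(seq_len(nrow(sim)), best)]
  pairs <- data.frame(
    query_key = rownames(Q) %||% sprintf("q%d", seq_len(nrow(Q))),
    neighbor_key = (rownames(R) %||% sprintf("r%d", seq_len(nrow(R))))[best],
    similarity = bestSim, stringsAsFactors = FALSE)
  list(pairs = pairs, mean_nn_similarity = mean(bestSim), direction = direction)
}

#' 2-D manifold embedding of a descriptor matrix
#'
#' Uniform manifold approximation and projection (UMAP) with
#' n_neighbors = 15, min_dist = 0.1 and n_components = 2 by default,
#' computed deterministically under the mandatory seed. Compounds shared
#' between the domains can be flagged for plotting as a third category.
#'
#' @param descriptors a [DescriptorMatrix-class] (E-state vectors by
#'   default convention) or a numeric matrix with rownames.
#' @param params list overriding n_neighbors, min_dist, n_components.
#' @param seed integer seed (required; the embedding is stochastic).
#' @param overlap_keys compound keys present in both domains, flagged in the
#'   output.
#' @param domains optional named vector of domain tags per compound.
#' @return data.frame (compound_key, x, y, domain, overlap_flag).
#' @export
embedChemicalSpace <- function(descriptors, params = list(), seed,
                               overlap_keys = character(0), domains = NULL) {
  if (missing(seed)) stop("an explicit seed is required for the embedding")
  m <- if (is(descriptors, "DescriptorMatrix")) descriptorValues(descriptors) else descriptors
  p <- modifyList(list(n_neighbors = 15, min_dist = 0.1, n_components = 2), params)
  if (p$n_components != 2L) stop("only 2-D embeddings are supported")
  if (nrow(m) < p$n_neighbors + 1)
    stopf("embedding needs at least n_neighbors + 1 = %d rows, got %d",
          p$n_neighbors + 1, nrow(m))
  if (Sys.which("python") == "") stop("python executable not found on PATH")
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)))
  write.csv(data.frame(key = rownames(m), m, check.names = FALSE), fin,
            row.names = FALSE)
  script <- system.file("python", "run_umap.py", package = "qsarShift")
  status <- system2("python", c(script, fin, fout,
                                as.character(p$n_neighbors),
                                as.character(p$min_dist),
                                as.character(as.integer(seed))),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L) || !file.exists(fout)) stop("UMAP embedding failed")
  coords <- read.csv(fout, stringsAsFactors = FALSE)
  keys <- coords$key
  data.frame(compound_key = keys, x = coords$x, y = coords$y,
             domain = if (is.null(domains)) NA_character_ else unname(domains[keys]),
             overlap_flag = keys %in% overlap_keys,
             stringsAsFactors = FALSE)
}

#' Compare physicochemical property distributions of two sets
#'
#' Per property: median and quartiles per set, plus a robust standardized
#' location shift (difference of medians over the pooled median absolute
#' deviation; 0 when the pooled MAD is 0 and the medians agree).
#'
#' @param physA,physB data.frames from [computePhyschem()].
#' @return data.frame with one row per property.
#' @export
comparePropertyDistributions <- function(physA, physB) {
  props <- setdiff(names(physA), "compound_key")
  if (!nrow(physA) || !nrow(physB)) stop("both property sets must be non-empty")
  stopifnot(identical(props, setdiff(names(physB), "compound_key")))
  rows <- lapply(props, function(p) {
    a <- physA[[p]]; b <- physB[[p]]
    scale <- mad(c(a, b))
    diff <- median(b) - median(a)
    shift <- if (scale == 0) { if (diff == 0) 0 else sign(diff) * Inf } else diff / scale
    data.frame(property = p,
               median_a = median(a), q1_a = quantile(a, 0.25), q3_a = quantile(a, 0.75),
               median_b = median(b), q1_b = quantile(b, 0.25), q3_b = quantile(b, 0.75),
               standardized_shift = shift, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Remove the compounds shared between two domains from each counterpart
#'
#' Builds the "delta" views used before plotting: each set minus the InChIs
#' it shares with the other.
#'
#' @param setA,setB [ClassifiedDataset-class] objects.
#' @return list with `deltaA`, `deltaB` and `shared` (the shared InChIs).
#' @export
domainDeltaSets <- function(setA, setB) {
  shared <- intersect(memberInchis(setA), memberInchis(setB))
  a <- setA; b <- setB
  a@compounds <- a@compounds[!memberInchis(setA) %in% shared, , drop = FALSE]
  b@compounds <- b@compounds[!memberInchis(setB) %in% shared, , drop = FALSE]
  list(deltaA = a, deltaB = b, shared = shared)
}
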