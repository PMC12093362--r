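# Independent reference implementations used as oracles. These deliberately
# take different computational routes from the package code.

# Metrics via reconstructed binary vectors: MCC as the Pearson correlation of
# the label/prediction indicators, rates from the vectors themselves.
refMetrics <- function(tp, tn, fp, fn) {
  y <- c(rep(1, tp), rep(1, fn), rep(0, tn), rep(0, fp))
  p <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  safe <- function(x) if (is.nan(x) || is.na(x)) NaN else x
  sens <- safe(sum(y == 1 & p == 1) / sum(y == 1))
  spec <- safe(sum(y == 0 & p == 0) / sum(y == 0))
  ppv <- safe(sum(y == 1 & p == 1) / sum(p == 1))
  npv <- safe(sum(y == 0 & p == 0) / sum(p == 0))
  mcc <- suppressWarnings(cor(y, p))
  if (is.na(mcc)) mcc <- 0 # zero-variance margin: package convention
  c(sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    ppv = ppv, npv = npv,
    f_measure = if (is.nan(ppv) || is.nan(sens) || ppv + sens == 0) NaN else
      safe(2 * (ppv * sens) / (ppv + sens)),
    mcc = mcc)
}

# Exhaustive Butina reference: plain loops over a precomputed similarity
# matrix, following the documented greedy order (most unassigned neighbors,
# ties to the lowest index).
refButina <- function(simMatrix, threshold) {
  n <- nrow(simMatrix)
  nbr <- simMatrix >= threshold
  diag(nbr) <- FALSE
  cluster <- integer(n)
  cl <- 0L
  repeat {
    un <- which(cluster == 0L)
    if (!length(un)) break
    best <- un[1]; bestCount <- -1L
    for (i in un) {
      cnt <- sum(nbr[i, un])
      if (cnt > bestCount) { best <- i; bestCount <- cnt }
    }
    cl <- cl + 1L
    members <- c(best, un[nbr[best, un]])
    cluster[unique(members)] <- cl
  }
  cluster
}

# Brute-force nearest-neighbor similarity with explicit loops.
refNNMean <- function(Q, R) {
  best <- numeric(nrow(Q))
  for (i in seq_len(nrow(Q))) {
    sims <- numeric(nrow(R))
    for (j in seq_len(nrow(R))) {
      inter <- sum(Q[i, ] & R[j, ])
      uni <- sum(Q[i, ] | R[j, ])
      sims[j] <- if (uni == 0) 0 else inter / uni
    }
    best[i] <- max(sims)
  }
  mean(best)
}

# Counting-based mode with the package's documented tie-breaks.
refMode <- function(indices, mcc) {
  counts <- sapply(sort(unique(indices)), function(i) sum(indices == i))
  names(counts) <- sort(unique(indices))
  top <- as.integer(names(counts)[counts == max(counts)])
  if (length(top) > 1L) {
    means <- sapply(top, function(i) mean(mcc[indices == i]))
    top <- top[means == max(means)]
  }
  min(top)
}

randomBitMatrix <- function(n, bits, density = 0.2) {
  m <- matrix(runif(n * bits) < density, n, bits)
  storage.mode(m) <- "numeric"
  # guarantee non-empty rows so Tanimoto is everywhere defined
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample(bits, sum(empty), replace = TRUE))] <- 1
  rownames(m) <- sprintf("b%03d", seq_len(n))
  m
}
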