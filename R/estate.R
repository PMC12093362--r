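## Electrotopological-state (E-state) descriptor vector.
##
## Kier-Hall atom-level E-state indices computed from the heavy-atom graph:
## the intrinsic state I = ((2/N)^2 * dv + 1) / d (N principal quantum number,
## dv valence-electron count minus implicit hydrogens, d heavy-atom degree)
## perturbed by all other atoms with (I_i - I_j) / (r_ij + 1)^2, r_ij the
## topological distance. Atom values are aggregated into a fixed-width
## molecular vector by summing over an atom-type vocabulary (element, bond
## pattern, hydrogen count, ring membership). The published 79-feature
## Molconn-Z aggregation is proprietary; this vocabulary is the package's own
## and downstream code treats the width as data-driven.

.ZV <- c(C = 4, N = 5, O = 6, S = 6, P = 5, F = 7, Cl = 7, Br = 7, I = 7, B = 3)
.PQN <- c(C = 2, N = 2, O = 2, F = 2, B = 2, S = 3, P = 3, Cl = 3, Br = 4, I = 5)
.DEFVAL <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1, B = 3)

# Fixed atom-type vocabulary: bond prefix (s single-only, d has double,
# t has triple) x element x implicit-H count x ring flag, restricted to
# combinations that occur in organic molecules.
estateVocabulary <- function() {
  combos <- expand.grid(
    prefix = c("s", "d", "t"), elem = names(.ZV), h = 0:3, ring = c("", "r"),
    stringsAsFactors = FALSE)
  maxh <- c(C = 3, N = 2, O = 1, S = 1, P = 2, F = 0, Cl = 0, Br = 0, I = 0, B = 2)
  keep <- combos$h <= maxh[combos$elem] &
    !(combos$prefix %in% c("d", "t") & combos$elem %in% c("F", "Cl", "Br", "I")) &
    !(combos$prefix == "t" & combos$elem %in% c("O", "S")) &
    !(combos$ring == "r" & combos$elem %in% c("F", "Cl", "Br", "I")) &
    !(combos$prefix == "t" & combos$ring == "r")
  combos <- combos[keep, ]
  sort(sprintf("%s%sH%d%s", combos$prefix, combos$elem, combos$h, combos$ring))
}

# Per-atom E-state values for one molecular graph (as built by molGraphs).
atomEstate <- function(graph) {
  elems <- graph$elements
  n <- length(elems)
  bonds <- graph$bonds
  deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
  bosum <- numeric(n)
  if (nrow(bonds)) for (r in seq_len(nrow(bonds))) {
    o <- bonds[r, 3]
    bosum[bonds[r, 1]] <- bosum[bonds[r, 1]] + o
    bosum[bonds[r, 2]] <- bosum[bonds[r, 2]] + o
  }
  zv <- .ZV[elems]; pqn <- .PQN[elems]; defv <- .DEFVAL[elems]
  if (anyNA(zv)) stopf("unsupported element(s): %s",
                       paste(unique(elems[is.na(zv)]), collapse = ", "))
  # implicit hydrogens from default valence; charges shift the valence
  # (+1 on N gives 4 bonds, -1 on O gives 1); hypervalent S/P fall out at 0
  h <- pmax(0, defv + graph$charges - bosum)
  dv <- pmax(zv - h, 1)
  d <- pmax(deg, 1)
  intrinsic <- ((2 / pqn)^2 * dv + 1) / d
  if (n == 1L || nrow(bonds) == 0L) return(list(S = intrinsic, h = h, deg = deg))
  g <- igraph::graph_from_edgelist(apply(bonds[, 1:2, drop = FALSE], 2, as.integer),
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  dist <- igraph::distances(g)
  pert <- numeric(n)
  for (i in seq_len(n)) {
    dij <- dist[i, -i]
    fin <- is.finite(dij)
    pert[i] <- sum((intrinsic[i] - intrinsic[-i][fin]) / (dij[fin] + 1)^2)
  }
  list(S = intrinsic + pert, h = h, deg = deg)
}

# Ring-membership flags: atoms incident to an edge that is not a bridge.
ringAtoms <- function(graph) {
  n <- length(graph$elements)
  if (!nrow(graph$bonds)) return(rep(FALSE, n))
  g <- igraph::graph_from_edgelist(apply(graph$bonds[, 1:2, drop = FALSE], 2, as.integer),
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  br <- igraph::bridges(g)
  cyc <- igraph::E(g)[setdiff(seq_len(igraph::ecount(g)), as.integer(br))]
  flags <- rep(FALSE, n)
  if (length(cyc)) {
    ends <- igraph::ends(g, cyc)
    flags[unique(as.integer(ends))] <- TRUE
  }
  flags
}

# E-state molecular vector over the fixed vocabulary for one graph.
estateVector <- function(graph, vocab = estateVocabulary()) {
  es <- atomEstate(graph)
  elems <- graph$elements
  n <- length(elems)
  bonds <- graph$bonds
  hasD <- rep(FALSE, n); hasT <- rep(FALSE, n)
  if (nrow(bonds)) for (r in seq_len(nrow(bonds))) {
    if (bonds[r, 3] == 2) hasD[bonds[r, 1:2]] <- TRUE
    if (bonds[r, 3] == 3) hasT[bonds[r, 1:2]] <- TRUE
  }
  prefix <- ifelse(hasT, "t", ifelse(hasD, "d", "s"))
  ring <- ifelse(ringAtoms(graph), "r", "")
  types <- sprintf("%s%sH%d%s", prefix, elems, pmin(es$h, 3), ring)
  v <- setNames(numeric(length(vocab)), vocab)
  known <- types %in% vocab
  agg <- tapply(es$S[known], types[known], sum)
  v[names(agg)] <- agg
  v
}
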