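## Descriptor providers: E-state-like vectors, loadable embedding tables,
## fingerprint bit matrices and physicochemical property records.

# Session cache for E-state vectors keyed by canonical SMILES; the vectors
# are pure functions of the structure, so recomputation across stages and
# seeds is wasted work.
.estateCache <- new.env(parent = emptyenv())

estateMatrix <- function(smiles, keys) {
  vocab <- estateVocabulary()
  out <- matrix(0, length(smiles), length(vocab), dimnames = list(keys, vocab))
  missing <- !vapply(smiles, function(s) !is.null(.estateCache[[s]]), logical(1))
  if (any(missing)) {
    graphs <- molGraphs(smiles[missing], keys[missing])
    smi_m <- smiles[missing]
    for (i in seq_along(graphs)) {
      .estateCache[[smi_m[i]]] <- estateVector(graphs[[i]], vocab)
    }
  }
  for (i in seq_along(smiles)) out[i, ] <- .estateCache[[smiles[i]]]
  out
}

#' Load an embedding-vector provider from a table file
#'
#' Reads a CSV/TSV table whose first column is the compound key and whose
#' remaining columns form a constant-width numeric vector (e.g. molecular
#' embeddings produced by an external neural encoder). The vector dimension
#' is taken from the data.
#'
#' @param path table file; delimiter inferred from the extension.
#' @return an [EmbeddingProvider-class].
#' @export
loadEmbeddingProvider <- function(path) {
  if (!file.exists(path)) stopf("embedding table not found: %s", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("embedding table needs a key column plus numeric columns")
  keys <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  if (anyNA(m)) stop("embedding table is ragged or non-numeric")
  rownames(m) <- keys
  new("EmbeddingProvider", vectors = m)
}

#' Look up embedding vectors for compound keys
#'
#' @param provider an [EmbeddingProvider-class].
#' @param keys compound keys to look up.
#' @return list with `vectors` (matrix for the known keys, in request order)
#'   and `missing` (keys absent from the table — a miss signal, never zeros).
#' @export
embeddingLookup <- function(provider, keys) {
  hit <- match(keys, rownames(provider@vectors))
  list(vectors = provider@vectors[hit[!is.na(hit)], , drop = FALSE],
       missing = keys[is.na(hit)])
}

#' Embedding dimension
#' @param provider an [EmbeddingProvider-class].
#' @return integer vector width.
#' @export
embeddingDim <- function(provider) ncol(provider@vectors)

#' Compute a descriptor matrix for a classified data set
#'
#' Rows are aligned to the member order of `dataset`. Compounds the provider
#' cannot cover (keys absent from an embedding table) are dropped and
#' recorded in the `dropped` slot with a reason; zero-imputation is never
#' performed.
#'
#' @param dataset a [ClassifiedDataset-class].
#' @param provider `estate_like`, `embedding` or `fingerprint_bits`.
#' @param embedding an [EmbeddingProvider-class]; required when
#'   `provider = "embedding"`.
#' @param nbits fingerprint width for `fingerprint_bits`.
#' @return a [DescriptorMatrix-class].
#' @export
computeDescriptorMatrix <- function(dataset, provider = c("estate_like", "embedding",
                                                          "fingerprint_bits"),
                                    embedding = NULL, nbits = 2048L) {
  provider <- match.arg(provider)
  cmp <- members(dataset)
  dropped <- data.frame(compound_key = character(), reason = character())
  if (nrow(cmp) == 0L) {
    return(new("DescriptorMatrix", provider = provider,
               values = matrix(numeric(0), 0, 0), dropped = dropped))
  }
  values <- switch(provider,
    estate_like = estateMatrix(cmp$smiles, cmp$compound_key),
    fingerprint_bits = {
      fp <- computeFingerprint(cmp$smiles, cmp$compound_key, nbits = nbits)
      m <- fpMatrix(fp)
      colnames(m) <- sprintf("bit%04d", seq_len(ncol(m)))
      m
    },
    embedding = {
      if (is.null(embedding)) stop("provider 'embedding' requires an EmbeddingProvider")
      res <- embeddingLookup(embedding, cmp$compound_key)
      if (length(res$missing)) {
        dropped <- data.frame(compound_key = res$missing,
                              reason = "absent from embedding table")
      }
      colnames(res$vectors) <- sprintf("emb%04d", seq_len(ncol(res$vectors)))
      res$vectors
    })
  new("DescriptorMatrix", provider = provider, values = values, dropped = dropped)
}

#' Restrict a data set to the compounds covered by a descriptor matrix
#'
#' Narrows the member list consistently after provider-side drops.
#'
#' @param dataset a [ClassifiedDataset-class].
#' @param descriptors a [DescriptorMatrix-class].
#' @return the narrowed `ClassifiedDataset` (drop actions appended to the
#'   curation log).
#' @export
alignToDescriptors <- function(dataset, descriptors) {
  keep <- memberKeys(dataset) %in% rownames(descriptorValues(descriptors))
  if (all(keep)) return(dataset)
  dropped <- memberKeys(dataset)[!keep]
  dataset@curationLog <- rbind(dataset@curationLog,
    data.frame(compound_key = dropped, action = "dropped",
               reason = "no descriptor coverage"))
  dataset@compounds <- dataset@compounds[keep, , drop = FALSE]
  dataset
}

#' Physicochemical property records
#'
#' Molecular weight, hydrogen-bond donor and acceptor counts, heavy-atom
#' count, rotatable-bond count, topological polar surface area and a computed
#' logP (named `logp_proxy`: it stands in for a pH-corrected logD predictor
#' that is not publicly available).
#'
#' @param smiles character vector of valid SMILES.
#' @param keys compound keys.
#' @return data.frame with the seven property columns, one row per compound.
#' @examples
#' \donttest{
#' computePhyschem(c("CCO", "c1ccccc1"), keys = c("ethanol", "benzene"))
#' }
#' @export
computePhyschem <- function(smiles, keys = NULL) {
  keys <- keys %||% sprintf("cmp%d", seq_along(smiles))
  if (!length(smiles)) stop("no molecules supplied")
  graphs <- molGraphs(smiles, keys)
  heavy <- vapply(graphs, function(g) length(g$elements), 0L)
  rot <- vapply(graphs, countRotatableBonds, 0L)
  out <- data.frame(
    compound_key = keys,
    molecular_weight = NA_real_, hbond_donors = NA_real_,
    hbond_acceptors = NA_real_, heavy_atoms = heavy,
    rotatable_bonds = rot, tpsa = NA_real_, logp_proxy = NA_real_,
    row.names = NULL)
  multi <- heavy > 1L
  if (any(multi)) {
    ids <- sprintf("p%d", seq_len(sum(multi)))
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles[multi], ids)))
    if (length(sdf) != sum(multi)) stop("unparsable SMILES in physchem input")
    props <- suppressWarnings(ChemmineR::propOB(sdf))
    out$molecular_weight[multi] <- props$MW
    out$hbond_donors[multi] <- props$HBD
    out$hbond_acceptors[multi] <- props$HBA1
    out$tpsa[multi] <- props$TPSA
    out$logp_proxy[multi] <- props$logP
  }
  if (any(!multi)) {
    # single heavy atoms (e.g. methane): the SDF route degenerates, so the
    # fields follow directly from the atom and its implicit hydrogens
    mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
              F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904)
    hmass <- 1.008
    for (i in which(!multi)) {
      g <- graphs[[i]]
      el <- g$elements[1]
      nH <- max(0, .DEFVAL[el] + g$charges[1])
      out$molecular_weight[i] <- unname(mass[el] + nH * hmass)
      out$hbond_donors[i] <- if (el %in% c("N", "O") && nH > 0) 1 else 0
      out$hbond_acceptors[i] <- as.numeric(el %in% c("N", "O"))
      out$tpsa[i] <- unname(c(N = 26.02, O = 20.23)[el] %||% 0)
      if (is.na(out$tpsa[i])) out$tpsa[i] <- 0
      out$logp_proxy[i] <- 0
    }
  }
  out
}

# Rotatable bonds: acyclic single bonds whose both atoms bind >= 2 heavy
# neighbors (classic rotor definition; terminal and ring bonds excluded).
countRotatableBonds <- function(graph) {
  bonds <- graph$bonds
  if (!nrow(bonds)) return(0L)
  n <- length(graph$elements)
  deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
  g <- igraph::graph_from_edgelist(apply(bonds[, 1:2, drop = FALSE], 2, as.integer),
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  isBridge <- rep(FALSE, nrow(bonds))
  isBridge[as.integer(igraph::bridges(g))] <- TRUE
  sum(bonds[, 3] == 1 & isBridge & deg[bonds[, 1]] >= 2 & deg[bonds[, 2]] >= 2)
}
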