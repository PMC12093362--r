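## Mixed training-set compilation: a proprietary-like base set from one
## experimental setup enriched with public-like compounds under three nested
## strategies — (a) target only, (b) additionally matching assay format,
## (c) additionally Tanimoto similarity >= 0.230 to the base set.

#' Derive assay-format labels for public-like measurement rows
#'
#' Public sources rarely annotate the assay format explicitly; it is derived
#' from the assay-type and cell-name annotations: rows with assay type
#' Binding (B), ADME (A) or Toxicity (T) are cell-based when a cell name is
#' annotated and cell-free otherwise; rows with other assay types are
#' excluded (logged).
#'
#' @param rows measurement rows ([readActivityTable()]`$rows`).
#' @return list with `rows` (the retained rows with `assay_format` filled)
#'   and `excluded` (data.frame compound_key, reason).
#' @export
deriveAssayFormat <- function(rows) {
  at <- toupper(trimws(rows$assay_type %||% rep(NA_character_, nrow(rows))))
  eligible <- !is.na(at) & at %in% c("A", "B", "T")
  hasCell <- !is.na(rows$cell_name) & nzchar(trimws(rows$cell_name))
  rows$assay_format[eligible] <- ifelse(hasCell[eligible], "cell_based", "cell_free")
  excluded <- data.frame(
    compound_key = rows$compound_key[!eligible],
    reason = sprintf("assay type '%s' not in {A, B, T}", at[!eligible]),
    stringsAsFactors = FALSE)
  list(rows = rows[eligible, , drop = FALSE], excluded = excluded)
}

#' Compile a mixed training set
#'
#' Starting from the full base (proprietary-like) set, adds public-like
#' compounds under the requested approach: `a_target_only` adds all,
#' `b_plus_assay_format` adds only those whose assay format matches
#' `assay_format`, `c_plus_similarity` additionally requires a maximum
#' Tanimoto similarity to any base compound of at least `threshold`. The
#' member sets are nested (c within b within a). InChI collisions resolve
#' toward the base set (the public copy is dropped and logged); members
#' carry an origin tag.
#'
#' @param base_set,public_set curated [ClassifiedDataset-class] objects for
#'   the same target.
#' @param approach one of `a_target_only`, `b_plus_assay_format`,
#'   `c_plus_similarity`.
#' @param assay_format `cell_based` or `cell_free`; the base setup's format
#'   (required for approaches b and c).
#' @param threshold Tanimoto threshold for approach c (default 0.230).
#' @param nbits fingerprint width used for the approach-c similarity screen.
#' @return a [ClassifiedDataset-class] whose compounds carry an `origin`
#'   column (`base` or `added_public`); the compilation log records every
#'   exclusion.
#' @export
compileMixed <- function(base_set, public_set,
                         approach = c("a_target_only", "b_plus_assay_format",
                                      "c_plus_similarity"),
                         assay_format = NULL, threshold = 0.230, nbits = 2048L) {
  approach <- match.arg(approach)
  if (nMembers(base_set) == 0L) stop("empty base set")
  base <- members(base_set); pub <- members(public_set)
  base$origin <- "base"
  log <- data.frame(compound_key = character(), action = character(),
                    reason = character(), stringsAsFactors = FALSE)
  note <- function(keys, action, reason) {
    if (length(keys))
      log <<- rbind(log, data.frame(compound_key = keys, action = action,
                                    reason = reason, stringsAsFactors = FALSE))
  }

  if (approach %in% c("b_plus_assay_format", "c_plus_similarity")) {
    if (is.null(assay_format) || !assay_format %in% c("cell_based", "cell_free"))
      stop("approaches b and c require the base setup's assay_format")
    match_ <- !is.na(pub$assay_format) & pub$assay_format == assay_format
    note(pub$compound_key[!match_], "excluded",
         sprintf("assay format does not match '%s'", assay_format))
    pub <- pub[match_, , drop = FALSE]
  }
  if (approach == "c_plus_similarity" && nrow(pub)) {
    fpPub <- computeFingerprint(pub$smiles, pub$compound_key, nbits = nbits)
    fpBase <- computeFingerprint(base$smiles, base$compound_key, nbits = nbits)
    maxSim <- apply(tanimotoMatrix(fpPub, fpBase), 1, max)
    keep <- maxSim >= threshold
    note(pub$compound_key[!keep], "excluded",
         sprintf("max Tanimoto to base %.3f < %.3f", maxSim[!keep], threshold))
    note(pub$compound_key[keep], "kept",
         sprintf("max Tanimoto to base %.3f >= %.3f", maxSim[keep], threshold))
    pub <- pub[keep, , drop = FALSE]
  }
  dup <- pub$inchi %in% base$inchi
  note(pub$compound_key[dup], "dropped", "InChI collision with base set (base label wins)")
  pub <- pub[!dup, , drop = FALSE]
  pub$origin <- rep("added_public", nrow(pub))

  cmp <- rbind(base, pub)
  rownames(cmp) <- NULL
  new("ClassifiedDataset",
      target = base_set@target, domain = base_set@domain,
      compounds = cmp, curationLog = log, eligible = TRUE, rejectReason = "")
}

#' Evaluate the three mixing approaches by nested cross-validation
#'
#' Compiles the mixed training set under each approach, runs random and
#' cluster-based nested cross-validation on each, and returns fold-level MCC
#' records in long format, ready for violin-style summaries.
#'
#' @param base_set,public_set curated [ClassifiedDataset-class] objects.
#' @param assay_format base setup's format for approaches b and c.
#' @param config a [RunConfig-class].
#' @param algorithm classifier family (default `xgb`, the cheaper of the two
#'   boosted/kernel families with comparable accuracy).
#' @param provider descriptor provider for the models.
#' @param schemes CV schemes to run.
#' @param approaches approaches to run.
#' @return data.frame (approach, scheme, fold, mcc, n_train).
#' @export
evaluateMixing <- function(base_set, public_set, assay_format,
                           config = runConfig(), algorithm = "xgb",
                           provider = "estate_like",
                           schemes = c("random", "cluster"),
                           approaches = c("a_target_only", "b_plus_assay_format",
                                          "c_plus_similarity")) {
  out <- list()
  for (app in approaches) {
    mixed <- compileMixed(base_set, public_set, app, assay_format,
                          threshold = config@similarityThreshold,
                          nbits = config@fingerprintBits)
    desc <- computeDescriptorMatrix(mixed, provider, nbits = config@fingerprintBits)
    fps <- if ("cluster" %in% schemes)
      computeFingerprint(members(mixed)$smiles, memberKeys(mixed),
                         nbits = config@fingerprintBits) else NULL
    for (sch in schemes) {
      res <- runNestedCV(mixed, desc, algorithm, sch, config, fingerprints = fps)
      out[[paste(app, sch)]] <- data.frame(
        approach = app, scheme = sch,
        fold = res@outerMetrics$fold, mcc = res@outerMetrics$mcc,
        n_train = nMembers(mixed))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
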