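## Binary class assignment and per-target data set curation.
##
## Labels: a measurement is active iff its potency (IC50 or Ki, pooled as
## interchangeable replicates) is at or below the activity threshold
## (default 10 uM; ties are active). Replicate conflicts are resolved
## asymmetrically by domain: in the public-like domain a compound whose
## replicates disagree is removed from the target's data set; in the
## proprietary-like domain any active replicate makes the compound active
## (cautious toward false positives, which matter less than missed effects
## in off-target work).

#' Assign a binary activity class from replicate measurements
#'
#' Relation qualifiers are resolved first: `>` rows are classifiable only as
#' inactive (value above threshold), `<` rows only as active (value at or
#' below threshold); otherwise qualified rows are excluded. Ties at the
#' threshold are active.
#'
#' @param values_um potency values in micromolar.
#' @param relations relation qualifiers (`=`, `<`, `>`), recycled if length 1.
#' @param domain `public_like` or `proprietary_like`.
#' @param threshold_um activity threshold in micromolar (default 10).
#' @return list with `action` (`keep`/`remove`), `label` (`active`/
#'   `inactive` or NA) and `reason`.
#' @examples
#' assignClass(c(5, 50), "=", "public_like")      # conflict -> removal
#' assignClass(c(5, 50), "=", "proprietary_like") # any active -> active
#' @export
assignClass <- function(values_um, relations = "=", domain, threshold_um = 10) {
  stopifnot(domain %in% DOMAIN_TAGS)
  relations <- rep_len(relations, length(values_um))
  usable <- logical(length(values_um))
  labels <- character(length(values_um))
  for (i in seq_along(values_um)) {
    v <- values_um[i]
    if (is.na(v) || v <= 0) next
    if (relations[i] == "=") {
      usable[i] <- TRUE
      labels[i] <- if (v <= threshold_um) "active" else "inactive"
    } else if (relations[i] == ">" && v > threshold_um) {
      usable[i] <- TRUE; labels[i] <- "inactive"
    } else if (relations[i] == "<" && v <= threshold_um) {
      usable[i] <- TRUE; labels[i] <- "active"
    }
  }
  labels <- labels[usable]
  if (!length(labels))
    return(list(action = "remove", label = NA_character_, reason = "no usable measurement"))
  hasActive <- any(labels == "active")
  hasInactive <- any(labels == "inactive")
  if (hasActive && hasInactive) {
    if (domain == "public_like")
      return(list(action = "remove", label = NA_character_, reason = "replicate conflict"))
    return(list(action = "keep", label = "active", reason = "conflict resolved to active"))
  }
  list(action = "keep", label = if (hasActive) "active" else "inactive", reason = "")
}

#' Build a curated per-target binary data set
#'
#' Standardizes structures, groups measurements by stereo-free InChI,
#' assigns classes under the domain's conflict rule and applies the
#' eligibility criteria (at least `minDatasetSize` compounds and at least
#' `minMinorityFraction` of the minority class, checked on the final set).
#' A data set failing eligibility is returned as a rejection record; every
#' removal is written to the curation log with a reason.
#'
#' @param rows measurement rows as returned by [readActivityTable()]`$rows`.
#' @param target_id target to curate.
#' @param domain `public_like` or `proprietary_like`.
#' @param config a [RunConfig-class].
#' @return a [ClassifiedDataset-class] (check [isEligible()]).
#' @export
buildTargetDataset <- function(rows, target_id, domain, config = runConfig()) {
  rows <- rows[rows$target_id == target_id & rows$domain == domain, , drop = FALSE]
  log <- data.frame(compound_key = character(), action = character(),
                    reason = character(), stringsAsFactors = FALSE)
  addLog <- function(keys, action, reason) {
    if (length(keys))
      log <<- rbind(log, data.frame(compound_key = keys, action = action,
                                    reason = reason, stringsAsFactors = FALSE))
  }
  reject <- function(reason) {
    new("ClassifiedDataset", target = target_id, domain = domain,
        compounds = data.frame(compound_key = character(), smiles = character(),
                               inchi = character(), inchikey = character(),
                               label = character(), assay_format = character(),
                               stringsAsFactors = FALSE),
        curationLog = log, eligible = FALSE, rejectReason = reason)
  }
  if (nrow(rows) == 0L) return(reject("no measurement rows"))

  ## standardize unique input structures once
  uniq <- !duplicated(rows$smiles)
  std <- standardizeCompound(rows$smiles[uniq], rows$compound_key[uniq])
  bad <- std[!std$ok, ]
  for (j in seq_len(nrow(bad))) {
    addLog(unique(rows$compound_key[rows$smiles == bad$input_smiles[j]]),
           "rejected", paste0("standardization: ", bad$reason[j]))
  }
  hit <- match(rows$smiles, std$input_smiles)
  rows$std_smiles <- std$smiles[hit]
  rows$inchi <- std$inchi[hit]
  rows$inchikey <- std$inchikey[hit]
  rows <- rows[!is.na(rows$inchi), , drop = FALSE]
  if (nrow(rows) == 0L) return(reject("no standardizable structures"))

  ## group measurements by InChI and assign classes
  groups <- split(seq_len(nrow(rows)), rows$inchi)
  recs <- lapply(names(groups), function(ic) {
    idx <- groups[[ic]]
    cls <- assignClass(rows$value_um[idx], rows$relation[idx], domain,
                       config@activityThresholdUM)
    key <- min(rows$compound_key[idx])
    fmt <- unique(rows$assay_format[idx])
    fmt <- if (length(fmt) == 1L && !is.na(fmt) && nzchar(fmt)) fmt else NA_character_
    list(key = key, inchi = ic, smiles = rows$std_smiles[idx[1]],
         inchikey = rows$inchikey[idx[1]], cls = cls, assay_format = fmt)
  })
  kept <- Filter(function(r) r$cls$action == "keep", recs)
  removed <- Filter(function(r) r$cls$action == "remove", recs)
  for (r in removed) addLog(r$key, "removed", r$cls$reason)
  for (r in kept) if (nzchar(r$cls$reason)) addLog(r$key, "kept", r$cls$reason)

  cmp <- data.frame(
    compound_key = vapply(kept, `[[`, character(1), "key"),
    smiles = vapply(kept, `[[`, character(1), "smiles"),
    inchi = vapply(kept, `[[`, character(1), "inchi"),
    inchikey = vapply(kept, `[[`, character(1), "inchikey"),
    label = vapply(kept, function(r) r$cls$label, character(1)),
    assay_format = vapply(kept, `[[`, character(1), "assay_format"),
    stringsAsFactors = FALSE)
  cmp <- cmp[order(cmp$inchikey, cmp$compound_key), , drop = FALSE]
  rownames(cmp) <- NULL

  ## eligibility on the final curated set
  n <- nrow(cmp)
  if (n < config@minDatasetSize)
    return(reject(sprintf("size %d < %d", n, config@minDatasetSize)))
  minority <- min(table(factor(cmp$label, levels = LABELS))) / n
  if (minority < config@minMinorityFraction)
    return(reject(sprintf("minority %.1f%% < %.0f%%", 100 * minority,
                          100 * config@minMinorityFraction)))
  new("ClassifiedDataset", target = target_id, domain = domain, compounds = cmp,
      curationLog = log, eligible = TRUE, rejectReason = "")
}
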