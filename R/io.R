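## Readers and writers for the tabular formats the pipeline touches.

#' Default activity-table column dialect
#'
#' Column names follow ChEMBL bulk-export conventions; pass a modified copy
#' of this list to [readActivityTable()] to map other dialects. Optional
#' columns may be absent from the file.
#'
#' @return named list mapping logical fields to column names.
#' @export
defaultDialect <- function() {
  list(compound_key = "compound_key",
       structure = "canonical_smiles",
       measurement_type = "standard_type",
       value = "standard_value",
       units = "standard_units",
       relation = "standard_relation",
       target_id = "target_id",
       domain = "domain",
       assay_type = "assay_type",       # optional
       cell_name = "cell_name",         # optional
       assay_format = "assay_format")   # optional
}

.OPTIONAL_FIELDS <- c("assay_type", "cell_name", "assay_format")

normalizeUnits <- function(value, units) {
  u <- trimws(tolower(units))
  u[u %in% c("μm", "µm", "um")] <- "um"
  factor <- ifelse(u == "nm", 1e-3, ifelse(u == "um", 1, NA_real_))
  value * factor
}

#' Read an activity table
#'
#' Parses a CSV/TSV bioactivity export into standardized measurement rows:
#' units normalized to micromolar, relations normalized to one of
#' `=`, `<`, `>` (missing treated as `=`), measurement types restricted to
#' IC50/Ki. Rows that cannot be used are collected into a rejects report
#' with a reason, never silently dropped.
#'
#' @param path CSV (or TSV for `.tsv` files) activity table.
#' @param dialect column mapping, see [defaultDialect()].
#' @return list with `rows` (data.frame: compound_key, smiles, measurement
#'   type, value_um, relation, target_id, domain, assay_type, cell_name,
#'   assay_format) and `rejects` (data.frame row, compound_key, reason).
#' @export
readActivityTable <- function(path, dialect = defaultDialect()) {
  if (!file.exists(path)) stopf("activity table not found: %s", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  if (nrow(tab) == 0L) stopf("activity table is empty: %s", path)
  required <- setdiff(names(defaultDialect()), .OPTIONAL_FIELDS)
  missing <- vapply(required, function(f) !(dialect[[f]] %in% names(tab)), logical(1))
  if (any(missing))
    stopf("mapped column(s) missing from %s: %s", path,
          paste(unlist(dialect[required][missing]), collapse = ", "))
  getcol <- function(field) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(tab)) tab[[col]] else rep(NA_character_, nrow(tab))
  }
  rows <- data.frame(
    compound_key = getcol("compound_key"),
    smiles = getcol("structure"),
    measurement_type = toupper(trimws(getcol("measurement_type"))),
    value_raw = getcol("value"),
    units = getcol("units"),
    relation = trimws(getcol("relation")),
    target_id = getcol("target_id"),
    domain = getcol("domain"),
    assay_type = getcol("assay_type"),
    cell_name = getcol("cell_name"),
    assay_format = getcol("assay_format"),
    stringsAsFactors = FALSE)
  rows$measurement_type[rows$measurement_type == "KI"] <- "Ki"
  rows$relation[is.na(rows$relation) | rows$relation == ""] <- "="

  reason <- rep("", nrow(rows))
  value <- suppressWarnings(as.numeric(rows$value_raw))
  reason[is.na(value)] <- "non-numeric value"
  reason[!is.na(value) & value <= 0] <- "non-positive value"
  value_um <- normalizeUnits(value, rows$units)
  reason[reason == "" & is.na(value_um)] <- "unrecognized units"
  reason[reason == "" & !rows$measurement_type %in% c("IC50", "Ki")] <-
    "unsupported measurement type"
  reason[reason == "" & !rows$domain %in% DOMAIN_TAGS] <- "unknown domain tag"
  reason[reason == "" & (is.na(rows$smiles) | !nzchar(trimws(rows$smiles)))] <-
    "missing structure"
  reason[reason == "" & !rows$relation %in% c("=", "<", ">")] <- "unknown relation"

  ok <- reason == ""
  rows$value_um <- value_um
  rejects <- data.frame(row = which(!ok),
                        compound_key = rows$compound_key[!ok],
                        reason = reason[!ok], stringsAsFactors = FALSE)
  keep <- rows[ok, c("compound_key", "smiles", "measurement_type", "value_um",
                     "relation", "target_id", "domain", "assay_type", "cell_name",
                     "assay_format")]
  rownames(keep) <- NULL
  list(rows = keep, rejects = rejects)
}

# Serializable list views of report objects -------------------------------

reportAsList <- function(object) {
  if (is(object, "MetricsReport")) {
    return(list(schema = "MetricsReport",
                counts = as.list(object@counts),
                metrics = as.list(object@metrics),
                notes = object@notes,
                context = object@context))
  }
  if (is(object, "FoldAssignment")) {
    return(list(schema = "FoldAssignment",
                compound_key = names(object@fold),
                fold = unname(object@fold),
                cluster = if (length(object@clusterId))
                  unname(object@clusterId[names(object@fold)]) else NULL,
                k = object@k, scheme = object@scheme, seed = object@seed))
  }
  if (is(object, "CrossEvalReport")) {
    return(list(schema = "CrossEvalReport",
                train_domain = object@trainDomain, test_domain = object@testDomain,
                target = object@target,
                n_test_before = object@nTestBefore,
                n_removed_leakage = object@nRemovedLeakage,
                n_test_after = object@nTestAfter,
                bias_direction = object@biasDirection,
                metrics = reportAsList(object@metrics)))
  }
  if (is(object, "NestedCVResult")) {
    return(list(schema = "NestedCVResult",
                outer = object@outerMetrics,
                final_hyperparams = object@finalHyperparams,
                algorithm = object@algorithm, scheme = object@scheme,
                provider = object@provider, seed = object@seed))
  }
  if (is.data.frame(object) || is.list(object)) return(object)
  stopf("cannot serialize object of class %s", class(object)[1])
}

#' Write a pipeline report
#'
#' Serializes a pipeline product (metrics report, fold assignment,
#' cross-evaluation report, nested-CV result or plain data.frame/list) to
#' JSON or CSV. A later [readReport()] reproduces integer and text fields
#' exactly and reals to printed precision.
#'
#' @param object the object to write.
#' @param path output file.
#' @param format `json` or `csv`.
#' @export
writeReport <- function(object, path, format = c("json", "csv")) {
  format <- match.arg(format)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  x <- reportAsList(object)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  } else {
    df <- if (is.data.frame(x)) x else {
      if (identical(x$schema, "FoldAssignment")) {
        data.frame(compound_key = x$compound_key, fold = x$fold,
                   cluster = x$cluster %||% NA_integer_,
                   scheme = x$scheme, seed = x$seed)
      } else if (identical(x$schema, "MetricsReport")) {
        cbind(data.frame(x$counts), data.frame(x$metrics))
      } else {
        stopf("no CSV schema for %s", x$schema %||% class(object)[1])
      }
    }
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a report written by [writeReport()]
#'
#' @param path report file; format inferred from the extension.
#' @return the deserialized list (JSON) or data.frame (CSV).
#' @export
readReport <- function(path) {
  if (!file.exists(path)) stopf("report not found: %s", path)
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Write a classified data set and its curation log
#'
#' @param dataset a [ClassifiedDataset-class].
#' @param path output CSV for the members; the curation log goes to
#'   `<path base>_curation_log.csv`.
#' @export
writeDataset <- function(dataset, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(members(dataset), path, row.names = FALSE)
  logPath <- sub("\\.csv$", "", path)
  write.csv(curationLog(dataset), paste0(logPath, "_curation_log.csv"),
            row.names = FALSE)
  invisible(path)
}
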