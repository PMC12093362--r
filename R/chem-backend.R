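## Chemistry backend: structure standardization, identifiers, molecular graphs
## and circular fingerprints, all through OpenBabel (ChemmineOB bindings and
## the obabel executable for batch fingerprinting).

OB_NEUTRALIZE <- data.frame(names = "neutralize", args = "")

# Batch-convert SMILES with per-molecule fallback: OpenBabel stops a stream at
# the first unparsable molecule, so on a line-count mismatch each molecule is
# converted individually and failures come back as NA.
obConvert <- function(smiles, to, options = NULL) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  one <- function(smi) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat(
        "SMI", to, paste0(smi, "\n"),
        options = options %||% data.frame(names = character(), args = character()))),
      error = function(e) "")
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- sub("\t.*$", "", lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 1L) lines else NA_character_
  }
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", to, paste0(paste(smiles, collapse = "\n"), "\n"),
      options = options %||% data.frame(names = character(), args = character()))),
    error = function(e) "")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- sub("\t.*$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == n) return(lines)
  vapply(smiles, one, character(1), USE.NAMES = FALSE)
}

# Count atoms in a SMILES fragment and test whether it contains carbon.
# Handles bracket atoms explicitly and the organic-subset symbols outside
# brackets; sufficient for fragment ranking, not a full parser.
smilesFragmentInfo <- function(frag) {
  brackets <- regmatches(frag, gregexpr("\\[[^]]*\\]", frag))[[1]]
  rest <- gsub("\\[[^]]*\\]", "", frag)
  bare <- regmatches(rest, gregexpr("Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s", rest))[[1]]
  belem <- sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", brackets)
  nAtoms <- length(bare) + length(brackets)
  hasC <- any(bare %in% c("C", "c")) || any(belem %in% c("C", "c", "CH"))
  list(nAtoms = nAtoms, organic = hasC && nAtoms > 0L)
}

#' Standardize compound structures
#'
#' Applies the curation-grade standardization protocol: keep the largest
#' organic fragment (salt stripping), remove stereochemistry, neutralize
#' charges where attainable, canonicalize, and derive InChI and InChIKey from
#' the standardized structure. Inputs that cannot be parsed or contain no
#' organic fragment are returned as rejections with a reason code, never
#' dropped silently.
#'
#' @param smiles character vector of input SMILES.
#' @param keys optional compound keys (defaults to `cmp1..cmpN`).
#' @return data.frame with columns compound_key, input_smiles, smiles
#'   (standardized canonical), inchi, inchikey, ok (logical) and reason
#'   (`parse`, `nonorganic` or empty).
#' @examples
#' \donttest{
#' standardizeCompound(c("C[C@@H](N)C(=O)O", "CCN.Cl", "[Na+].[Cl-]"))
#' }
#' @export
standardizeCompound <- function(smiles, keys = NULL) {
  n <- length(smiles)
  keys <- keys %||% sprintf("cmp%d", seq_len(n))
  res <- data.frame(
    compound_key = keys, input_smiles = smiles,
    smiles = NA_character_, inchi = NA_character_, inchikey = NA_character_,
    ok = FALSE, reason = "", stringsAsFactors = FALSE)
  if (n == 0L) return(res)

  parseable <- !is.na(obConvert(ifelse(is.na(smiles) | !nzchar(trimws(smiles)),
                                       "X", trimws(smiles)), "CAN"))
  frag <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    smi <- trimws(smiles[i])
    if (is.na(smi) || !nzchar(smi) || !parseable[i]) { res$reason[i] <- "parse"; next }
    parts <- strsplit(smi, ".", fixed = TRUE)[[1]]
    info <- lapply(parts, smilesFragmentInfo)
    org <- vapply(info, `[[`, logical(1), "organic")
    if (!any(org)) { res$reason[i] <- "nonorganic"; next }
    sizes <- vapply(info, `[[`, numeric(1), "nAtoms")
    sizes[!org] <- -1
    frag[i] <- parts[which.max(sizes)]
  }

  todo <- which(!is.na(frag))
  if (length(todo)) {
    # stereo marks are dropped textually before canonicalization; "@" only
    # occurs as a chirality tag and "/","\\" only as directional bonds
    plain <- gsub("@", "", frag[todo], fixed = TRUE)
    plain <- gsub("/", "", plain, fixed = TRUE)
    plain <- gsub("\\", "", plain, fixed = TRUE)
    can <- obConvert(plain, "CAN", options = OB_NEUTRALIZE)
    inchi <- rep(NA_character_, length(todo))
    ikey <- rep(NA_character_, length(todo))
    good <- !is.na(can) & nzchar(can)
    if (any(good)) {
      inchi[good] <- obConvert(can[good], "INCHI")
      ikey[good] <- obConvert(can[good], "INCHIKEY")
    }
    ok <- good & !is.na(inchi) & grepl("^InChI=", inchi) & !is.na(ikey)
    res$smiles[todo] <- ifelse(ok, can, NA_character_)
    res$inchi[todo] <- ifelse(ok, inchi, NA_character_)
    res$inchikey[todo] <- ifelse(ok, ikey, NA_character_)
    res$ok[todo] <- ok
    res$reason[todo][!ok] <- "parse"
  }
  res
}

# SDF charge-column codes to formal charges.
.chgMap <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2, `7` = -3)

#' Molecular graphs from SMILES
#'
#' Parses standardized SMILES into heavy-atom graphs (element, formal charge,
#' bond list with orders) used by the electrotopological-state descriptors and
#' the graph-derived physicochemical counts.
#'
#' @param smiles character vector of valid SMILES.
#' @param keys compound keys used to name the result.
#' @return named list of graphs; each has `elements`, `charges` and a
#'   three-column `bonds` matrix (atom1, atom2, order).
#' @keywords internal
molGraphs <- function(smiles, keys = NULL) {
  keys <- keys %||% sprintf("cmp%d", seq_along(smiles))
  if (!length(smiles)) return(setNames(list(), character()))
  ids <- sprintf("g%d", seq_along(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, ids)))
  if (length(sdf) != length(smiles)) stopf("unparsable SMILES among %d inputs", length(smiles))
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    if (smilesFragmentInfo(smiles[i])$nAtoms == 1L) {
      # single heavy atom: the V2000 block ChemmineR returns is degenerate
      sym <- if (grepl("^\\[", smiles[i])) {
        sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", smiles[i])
      } else sub("^([A-Za-z][a-z]?).*$", "\\1", smiles[i])
      chg <- if (grepl("\\+", smiles[i])) 1 else if (grepl("-", smiles[i])) -1 else 0
      out[[i]] <- list(elements = toupper(substr(sym, 1, 1)) |>
                         paste0(substring(sym, 2)),
                       charges = chg, bonds = matrix(numeric(0), ncol = 3))
      next
    }
    ab <- ChemmineR::atomblock(sdf[[i]])
    bb <- ChemmineR::bondblock(sdf[[i]])
    elements <- sub("_.*$", "", rownames(ab))
    charges <- unname(.chgMap[as.character(ab[, "C6"])])
    charges[is.na(charges)] <- 0
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
      matrix(numeric(0), ncol = 3)
    } else unname(as.matrix(bb[, 1:3, drop = FALSE]))
    out[[i]] <- list(elements = elements, charges = charges, bonds = bonds)
  }
  setNames(out, keys)
}

# Parse the hex dump of `obabel -ofpt -xh` into a logical matrix.
parseObFptHex <- function(lines, nbits) {
  ids <- character(0); bits <- list(); cur <- NULL; hex <- character(0)
  flush <- function() {
    if (!is.null(cur)) {
      h <- strsplit(paste(hex, collapse = ""), "")[[1]]
      v <- as.integer(strtoi(h, 16L))
      m <- t(vapply(v, function(x) as.integer(bitwAnd(bitwShiftR(x, 0:3), 1L)),
                    integer(4)))
      bits[[cur]] <<- as.logical(as.vector(t(m)))
    }
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      cur <- strsplit(trimws(sub("^>", "", ln)), "[[:space:]]+")[[1]][1]
      hex <- character(0)
    } else if (grepl("^[0-9a-fA-F ]+$", ln)) {
      hex <- c(hex, gsub(" ", "", ln))
    }
  }
  flush()
  keep <- vapply(bits, length, 0L) == nbits
  bits <- bits[keep]
  if (!length(bits)) return(matrix(FALSE, 0, nbits))
  do.call(rbind, bits)
}

#' Compute hashed circular fingerprints
#'
#' Morgan-type extended-connectivity fingerprints of radius 2 (ECFP4), folded
#' to a fixed bit width, computed with OpenBabel. Deterministic for a given
#' canonical SMILES; identical structures yield identical bit-sets.
#'
#' @param smiles character vector of valid SMILES.
#' @param keys compound keys (row identifiers of the result).
#' @param nbits folded width, default 2048.
#' @return a [ChemmineR::FPset-class] with one row per compound.
#' @examples
#' \donttest{
#' fp <- computeFingerprint(c("CCO", "OCC"), keys = c("a", "b"))
#' }
#' @export
computeFingerprint <- function(smiles, keys = NULL, nbits = 2048L) {
  keys <- keys %||% sprintf("cmp%d", seq_along(smiles))
  if (!length(smiles)) stop("no molecules supplied")
  if (any(is.na(smiles) | !nzchar(trimws(smiles)))) stop("empty molecule in fingerprint input")
  if (Sys.which("obabel") == "") stop("obabel executable not found on PATH")
  fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".fpt")
  on.exit(unlink(c(fin, fout)))
  ids <- sprintf("fp%d", seq_along(smiles))
  writeLines(paste(smiles, ids), fin)
  system2("obabel", c("-ismi", fin, "-ofpt", "-xfECFP4", "-xN", as.character(nbits),
                      "-xh", "-O", fout), stdout = FALSE, stderr = FALSE)
  m <- parseObFptHex(readLines(fout), as.integer(nbits))
  if (is.null(rownames(m))) stop("fingerprint output could not be parsed")
  m2 <- matrix(FALSE, length(smiles), as.integer(nbits), dimnames = list(keys, NULL))
  hit <- match(ids, rownames(m))
  bad <- is.na(hit)
  if (any(bad)) stopf("fingerprints could not be computed for %d molecule(s): %s",
                      sum(bad), paste(head(keys[bad], 5), collapse = ", "))
  m2[] <- m[hit, , drop = FALSE]
  storage.mode(m2) <- "numeric"
  new("FPset", fpma = m2, type = "ECFP4", foldCount = 0)
}
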