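# Shared fixtures, generated programmatically and cached for the session
# (studies and curated sets are reused across test files).

.fixtures <- new.env(parent = emptyenv())

fixtureCached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Default-condition synthetic study for a seed. The combinatorial library
# depends only on the seed (none of the fixture overrides touch the scaffold
# or substituent counts), so it is cached per seed across study variants.
fixtureStudy <- function(seed, ...) {
  extra <- list(...)
  stopifnot(!any(c("nScaffolds", "substituentsPerScaffold") %in% names(extra)))
  key <- paste0("study_", seed, "_", paste(names(extra), unlist(extra), collapse = "_"))
  fixtureCached(key, {
    spec <- do.call(domainStudySpec, c(list(seed = as.integer(seed)), extra))
    lib <- fixtureCached(paste0("lib_", seed),
                         generateLibrary(domainStudySpec(seed = as.integer(seed))))
    sampleDomains(assignLatentActivity(lib, spec), spec)
  })
}

# Curated dataset for one domain of a study.
fixtureDataset <- function(seed, domain, ..., config = runConfig(seed = 1L)) {
  extra <- list(...)
  key <- paste0("ds_", seed, "_", domain, "_",
                paste(names(extra), unlist(extra), collapse = "_"))
  fixtureCached(key, {
    study <- fixtureStudy(seed, ...)
    f <- tempfile(fileext = ".csv")
    on.exit(unlink(f))
    write.csv(study@tables[[domain]], f, row.names = FALSE)
    buildTargetDataset(readActivityTable(f)$rows, "SYNT1", domain, config)
  })
}

fixtureEstate <- function(dataset, key) {
  fixtureCached(paste0("estate_", key), computeDescriptorMatrix(dataset, "estate_like"))
}

fixtureFingerprints <- function(dataset, key) {
  fixtureCached(paste0("fp_", key),
                computeFingerprint(members(dataset)$smiles, memberKeys(dataset)))
}

# A small pool of valid, structurally diverse molecules for curation tests.
fixtureMoleculePool <- function(n) {
  lib <- fixtureCached("pool_library",
                       generateLibrary(domainStudySpec(seed = 42L)))
  stopifnot(nrow(lib) >= n)
  lib[seq_len(n), ]
}

# Measurement rows in the parsed (post-reader) schema.
makeRows <- function(smiles, keys, values_um, domain, relation = "=",
                     target = "T1", assay_type = NA_character_,
                     cell_name = NA_character_, assay_format = NA_character_) {
  data.frame(compound_key = keys, smiles = smiles,
             measurement_type = "IC50", value_um = values_um,
             relation = relation, target_id = target, domain = domain,
             assay_type = assay_type, cell_name = cell_name,
             assay_format = assay_format, stringsAsFactors = FALSE)
}

# Construct a curated ClassifiedDataset directly (bypassing measurement
# simulation) for set-operation tests.
makeDataset <- function(lib, labels, domain, target = "T1") {
  cmp <- data.frame(compound_key = lib$compound_key, smiles = lib$smiles,
                    inchi = lib$inchi, inchikey = lib$inchikey,
                    label = labels, assay_format = rep(NA_character_, nrow(lib)),
                    stringsAsFactors = FALSE)
  new("ClassifiedDataset", target = target, domain = domain, compounds = cmp,
      curationLog = data.frame(compound_key = character(), action = character(),
                               reason = character(), stringsAsFactors = FALSE),
      eligible = TRUE, rejectReason = "")
}
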