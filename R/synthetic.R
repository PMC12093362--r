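## Synthetic two-domain bioactivity study generator.
##
## Emulates the statistical structure of a public/proprietary source pair:
## a public-like domain skewed toward actives, a proprietary-like domain
## skewed toward inactives, controllable scaffold-level chemical-space
## overlap, a bounded fraction of identical compounds present in both
## domains, replicate measurements with planted label conflicts, and
## cell-based/cell-free assay annotations. Chemistry realism is bounded by
## design: molecules are combinatorial scaffold + substituent assemblies of
## small drug-like fragments chosen so circular fingerprints separate
## scaffold families; the generator's purpose is statistical structure, not
## medicinal-chemistry fidelity. Ground truth is kept in a separate table
## that no pipeline stage reads.

# Two-slot scaffold templates; substituents are inserted with sprintf.
# Ring-closure digits 1-2 are reserved for scaffolds, 9 for substituents.
scaffoldTemplates <- function() {
  c(benzene        = "c1cc(%s)ccc1%s",
    pyridine       = "c1cc(%s)cnc1%s",
    pyrimidine     = "c1nc(%s)ncc1%s",
    pyrazine       = "c1nc(%s)cnc1%s",
    thiophene      = "c1cc(%s)sc1%s",
    furan          = "c1cc(%s)oc1%s",
    nmethylpyrrole = "c1cc(%s)n(C)c1%s",
    imidazole      = "c1nc(%s)n(C)c1%s",
    thiazole       = "c1nc(%s)sc1%s",
    oxazole        = "c1nc(%s)oc1%s",
    naphthalene    = "c1ccc2cc(%s)ccc2c1%s",
    quinoline      = "c1ccc2nc(%s)ccc2c1%s",
    isoquinoline   = "c1ccc2cnc(%s)cc2c1%s",
    indole         = "c1cc2c(cc1%s)c(%s)cn2C",
    benzimidazole  = "c1cc2c(cc1%s)nc(%s)n2C",
    benzofuran     = "c1cc2c(cc1%s)c(%s)co2",
    benzothiophene = "c1cc2c(cc1%s)c(%s)cs2",
    cyclohexane    = "C1CC(%s)CCC1%s",
    piperidine     = "C1CC(%s)CC(%s)N1C",
    oxane          = "C1CC(%s)CC(%s)O1",
    morpholine     = "C1OC(%s)CN(C)C1%s",
    piperazine     = "C1N(C)CC(%s)N(C)C1%s",
    biphenyl       = "c1ccc(cc1)c1ccc(%s)cc1%s",
    quinazoline    = "c1cc2c(cc1%s)ncnc2%s")
}

# Substituent fragments (attachment atom first). The pharmacophore subset
# carries the latent activity signal.
substituentVocabulary <- function() {
  plain <- c("C", "CC", "CCC", "C(C)C", "C(C)(C)C", "CO", "OC", "O", "N",
             "N(C)C", "NC(C)=O", "F", "Cl", "Br", "C(F)(F)F", "OC(F)(F)F",
             "C#N", "CC#N", "C(=O)N", "C(=O)OC", "SC", "CCO", "OCC", "CN",
             "C=C", "CCN(C)C", "OCCO", "c9ccccc9", "Cc9ccccc9", "c9ccncc9",
             "C9CC9", "N9CCOCC9")
  pharm <- c("S(=O)(=O)N", "S(=O)(=O)C", "S(=O)(=O)N(C)C", "S(=O)(=O)O",
             "C(=O)O", "CC(=O)O", "C(=O)NO", "P(=O)(O)O", "CS(=O)(=O)C")
  data.frame(fragment = c(plain, pharm),
             pharm = c(rep(FALSE, length(plain)), rep(TRUE, length(pharm))),
             stringsAsFactors = FALSE)
}

#' Generate the combinatorial compound library
#'
#' Builds molecules by attaching two substituent fragments to each scaffold
#' template, standardizes them and removes duplicate structures (symmetric
#' positions can collide). Scaffold identity is recorded for overlap control
#' and cluster analyses.
#'
#' @param spec a [DomainStudySpec-class].
#' @return data.frame (compound_key, smiles, inchi, inchikey, scaffold_id,
#'   has_pharm).
#' @export
generateLibrary <- function(spec = domainStudySpec()) {
  templates <- scaffoldTemplates()
  if (spec@nScaffolds > length(templates))
    stopf("at most %d scaffolds available", length(templates))
  templates <- templates[seq_len(spec@nScaffolds)]
  vocab <- substituentVocabulary()
  nv <- nrow(vocab)
  rows <- withSeed(deriveSeed(spec@seed, 1L), {
    out <- list()
    for (s in seq_along(templates)) {
      nPairs <- min(spec@substituentsPerScaffold, nv * nv)
      pairIdx <- sample(nv * nv, nPairs)
      i <- ((pairIdx - 1L) %% nv) + 1L
      j <- ((pairIdx - 1L) %/% nv) + 1L
      out[[s]] <- data.frame(
        smiles_raw = sprintf(templates[s], vocab$fragment[i], vocab$fragment[j]),
        scaffold_id = s,
        has_pharm = vocab$pharm[i] | vocab$pharm[j],
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  keys <- sprintf("CPD%05d", seq_len(nrow(rows)))
  std <- standardizeCompound(rows$smiles_raw, keys)
  if (any(!std$ok))
    stopf("invalid scaffold/substituent template: %s",
          paste(head(rows$smiles_raw[!std$ok], 3), collapse = ", "))
  lib <- data.frame(compound_key = keys, smiles = std$smiles, inchi = std$inchi,
                    inchikey = std$inchikey, scaffold_id = rows$scaffold_id,
                    has_pharm = rows$has_pharm, stringsAsFactors = FALSE)
  lib[!duplicated(lib$inchi), , drop = FALSE]
}

#' Assign latent ground-truth potencies
#'
#' Log-potency model: log10(IC50 in uM) = base + effect x (pharmacophore
#' present) + scaffold effect + compound jitter. With the default effect of
#' -1.8 log units and polarized scaffold effects, thresholding at 10 uM
#' yields labels that are determined by structure (scaffold + pharmacophore)
#' up to a small jitter; with effect 0 the pharmacophore signal vanishes
#' (null data).
#'
#' @param library data.frame from [generateLibrary()].
#' @param spec a [DomainStudySpec-class].
#' @param base_log10_um base potency, log10 uM (default 1.5).
#' @param jitter_sd compound-level potency jitter, log10 units (default 0.1).
#' @return `library` with columns true_log10_um, true_um and true_label.
#' @export
assignLatentActivity <- function(library, spec = domainStudySpec(),
                                 base_log10_um = 1.5, jitter_sd = 0.1) {
  withSeed(deriveSeed(spec@seed, 2L), {
    scafEff <- rnorm(max(library$scaffold_id), 0, spec@scaffoldEffectSD)
    jit <- rnorm(nrow(library), 0, jitter_sd)
    library$true_log10_um <- base_log10_um +
      spec@pharmacophoreEffect * library$has_pharm +
      scafEff[library$scaffold_id] + jit
  })
  library$true_um <- 10^library$true_log10_um
  library$true_label <- ifelse(library$true_um <= 10, "active", "inactive")
  library
}

# Split scaffolds into shared / domain-exclusive pools.
scaffoldPools <- function(nScaffolds, overlap) {
  nShared <- round(overlap * nScaffolds)
  shared <- seq_len(nShared)
  rest <- setdiff(seq_len(nScaffolds), shared)
  list(shared = shared,
       public = c(shared, rest[seq_along(rest) %% 2L == 1L]),
       proprietary = c(shared, rest[seq_along(rest) %% 2L == 0L]))
}

# Draw measurement rows for one compound in one domain.
measurementRows <- function(key, smiles, trueLog, domain, spec, conflicted) {
  nMeas <- if (runif(1) < spec@replicateProb) 2L + rpois(1, 0.5) else 1L
  if (conflicted) {
    gap <- 0.35 + abs(rnorm(1, 0, 0.15))
    vals <- 10^c(1 - gap, 1 + gap, 1 + rnorm(max(0, nMeas - 2L), 0, spec@measurementNoiseSD))
    nMeas <- length(vals)
  } else {
    vals <- 10^(trueLog + rnorm(nMeas, 0, spec@measurementNoiseSD))
  }
  cellBased <- runif(nMeas) < spec@cellBasedFraction[[domain]]
  if (domain == "public_like" && spec@formatNoiseSD > 0) {
    # format-dependent readout inconsistency: cell-free measurements in the
    # public domain drift off the true potency
    vals[!cellBased] <- 10^(log10(vals[!cellBased]) +
                              rnorm(sum(!cellBased), 0, spec@formatNoiseSD))
  }
  useKi <- runif(nMeas) < 0.3
  useNM <- runif(nMeas) < 0.5
  assayType <- if (domain == "public_like") {
    sample(c("B", "A", "T", "F"), nMeas, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
  } else rep(NA_character_, nMeas)
  cellNames <- ifelse(cellBased,
                      sample(c("HEK293", "CHO-K1", "HELA", "U2OS"), nMeas, replace = TRUE),
                      "")
  data.frame(
    compound_key = key,
    canonical_smiles = smiles,
    standard_type = ifelse(useKi, "Ki", "IC50"),
    standard_value = ifelse(useNM, vals * 1000, vals),
    standard_units = ifelse(useNM, "nM", "uM"),
    standard_relation = "=",
    target_id = "SYNT1",
    domain = domain,
    assay_type = assayType,
    cell_name = if (domain == "public_like") cellNames else NA_character_,
    assay_format = if (domain == "proprietary_like")
      ifelse(cellBased, "cell_based", "cell_free") else NA_character_,
    stringsAsFactors = FALSE)
}

#' Sample the two domains and emit raw activity tables
#'
#' Draws each domain's compounds to hit the configured class skews, copies
#' the identity-overlap compounds into both domains, draws replicate
#' measurements with log-normal noise, forces the planted conflict fraction
#' of replicated compounds to straddle the 10 uM threshold, and annotates
#' assay formats. Conflicts are planted symmetrically in both domains so the
#' asymmetric curation rules produce observably different outcomes.
#'
#' @param library output of [assignLatentActivity()].
#' @param spec a [DomainStudySpec-class].
#' @return a [SyntheticStudy-class].
#' @export
sampleDomains <- function(library, spec = domainStudySpec()) {
  pools <- scaffoldPools(spec@nScaffolds, spec@scaffoldOverlap)
  n <- spec@nPerDomain
  nOv <- round(spec@identityOverlap * n)
  withSeed(deriveSeed(spec@seed, 3L), {
    sharedLib <- library[library$scaffold_id %in% pools$shared, , drop = FALSE]
    ovAct <- round(nOv / 2); ovInact <- nOv - ovAct
    pick <- function(df, label, count, what) {
      cand <- df[df$true_label == label, , drop = FALSE]
      if (nrow(cand) < count)
        stopf("library cannot supply %d %s %s compounds (only %d available)",
              count, label, what, nrow(cand))
      cand[sample(nrow(cand), count), , drop = FALSE]
    }
    overlapSet <- if (nOv > 0) {
      rbind(pick(sharedLib, "active", ovAct, "shared-scaffold"),
            pick(sharedLib, "inactive", ovInact, "shared-scaffold"))
    } else library[0, , drop = FALSE]
    rest <- library[!library$compound_key %in% overlapSet$compound_key, , drop = FALSE]
    # compounds eligible for both domains are pre-assigned to one so the
    # identity overlap stays exactly at the configured count
    eligPub <- rest$scaffold_id %in% pools$public
    eligPrp <- rest$scaffold_id %in% pools$proprietary
    both <- eligPub & eligPrp
    # both-eligible compounds are pre-assigned with probability proportional
    # to each domain's per-class demand, mirroring how the two sources
    # sample different activity strata of a common chemistry
    needPub <- c(active = round(spec@activeFractionPublic * n) - ovAct,
                 inactive = n - round(spec@activeFractionPublic * n) - ovInact)
    needPrp <- c(active = round(spec@activeFractionProprietary * n) - ovAct,
                 inactive = n - round(spec@activeFractionProprietary * n) - ovInact)
    pPub <- setNames(pmax(0, needPub) / pmax(1, needPub + needPrp),
                     c("active", "inactive"))
    toPub <- both & (runif(nrow(rest)) < pPub[rest$true_label])
    pubPool <- rest[(eligPub & !both) | toPub, , drop = FALSE]
    prpPool <- rest[(eligPrp & !both) | (both & !toPub), , drop = FALSE]

    drawDomain <- function(pool, activeFraction, domain) {
      nAct <- round(activeFraction * n) - ovAct
      nInact <- (n - round(activeFraction * n)) - ovInact
      if (nAct < 0 || nInact < 0) stop("identityOverlap too large for the class skew")
      rbind(pick(pool, "active", nAct, domain),
            pick(pool, "inactive", nInact, domain),
            overlapSet)
    }
    pubSet <- drawDomain(pubPool, spec@activeFractionPublic, "public_like")
    prpSet <- drawDomain(prpPool, spec@activeFractionProprietary, "proprietary_like")

    emit <- function(set, domain) {
      replicated <- runif(nrow(set)) < spec@replicateProb
      conflicted <- replicated & (runif(nrow(set)) < spec@conflictRate)
      trueLog <- set$true_log10_um
      if (domain == "proprietary_like" && spec@flipLabelRule) trueLog <- 2 - trueLog
      rows <- lapply(seq_len(nrow(set)), function(i) {
        measurementRows(set$compound_key[i], set$smiles[i], trueLog[i], domain,
                        spec, conflicted[i])
      })
      do.call(rbind, rows)
    }
    pubTab <- emit(pubSet, "public_like")
    prpTab <- emit(prpSet, "proprietary_like")
    gt <- rbind(
      cbind(pubSet, domain = "public_like"),
      cbind(prpSet, domain = "proprietary_like"))
    new("SyntheticStudy", spec = spec,
        tables = list(public_like = pubTab, proprietary_like = prpTab),
        groundTruth = gt[, c("compound_key", "smiles", "scaffold_id", "has_pharm",
                             "true_um", "true_label", "domain")])
  })
}

#' Generate a complete synthetic study
#'
#' Chains [generateLibrary()], [assignLatentActivity()] and
#' [sampleDomains()]; optionally writes the two activity tables, the
#' ground-truth table and the spec to a directory. Identical spec + seed
#' give byte-identical files.
#'
#' @param spec a [DomainStudySpec-class].
#' @param dir optional output directory.
#' @return a [SyntheticStudy-class] (invisibly when writing).
#' @export
generateStudy <- function(spec = domainStudySpec(), dir = NULL) {
  lib <- generateLibrary(spec)
  lib <- assignLatentActivity(lib, spec)
  study <- sampleDomains(lib, spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(study@tables$public_like, file.path(dir, "public_like.csv"),
              row.names = FALSE)
    write.csv(study@tables$proprietary_like, file.path(dir, "proprietary_like.csv"),
              row.names = FALSE)
    write.csv(study@groundTruth, file.path(dir, "ground_truth.csv"),
              row.names = FALSE)
    specList <- lapply(setNames(slotNames("DomainStudySpec"),
                                slotNames("DomainStudySpec")),
                       function(s) slot(spec, s))
    yaml::write_yaml(specList, file.path(dir, "generator_spec.yaml"))
    return(invisible(study))
  }
  study
}
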