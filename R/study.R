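## Scripted end-to-end studies on synthetic data: within-domain nested CV,
## cross-domain transfer, chemical-space diagnostics and mixed-training
## comparisons, driven by a manifest (plain list or YAML file). Studies are
## configuration: changing overlap levels or skews edits the manifest only.

#' Build a study manifest
#'
#' @param name study label.
#' @param spec named list of [DomainStudySpec-class] overrides.
#' @param stages subset of `within`, `cross`, `chemspace`, `mixing`.
#' @param algorithm,provider model family and descriptor provider.
#' @param schemes CV schemes for the `within` and `mixing` stages.
#' @param assay_format base-setup assay format for the mixing stage.
#' @param umap whether the chemspace stage also computes the 2-D embedding.
#' @param seed run seed.
#' @param config named list of [RunConfig-class] overrides.
#' @return manifest list accepted by [runStudy()].
#' @export
studyManifest <- function(name = "domain-shift",
                          spec = list(),
                          stages = c("within", "cross", "chemspace"),
                          algorithm = "xgb", provider = "estate_like",
                          schemes = "random",
                          assay_format = "cell_based",
                          umap = FALSE, seed = 1L, config = list()) {
  list(name = name, spec = spec, stages = stages, algorithm = algorithm,
       provider = provider, schemes = schemes, assay_format = assay_format,
       umap = umap, seed = seed, config = config)
}

# Curate one domain of a generated study through the standard table reader
# (the raw tables go through the same dialect path as user data).
curateStudyDomain <- function(study, domain, config) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write.csv(study@tables[[domain]], f, row.names = FALSE)
  parsed <- readActivityTable(f)
  buildTargetDataset(parsed$rows, "SYNT1", domain, config)
}

#' Run a scripted study end-to-end
#'
#' Generates the synthetic two-domain study, curates both domains and runs
#' the requested stages. The summary collates within-domain outer-CV MCCs,
#' cross-domain MCCs and bias directions, nearest-neighbor similarity means
#' and mixing comparisons; every number is computed by a stage, the reporter
#' only collates.
#'
#' @param manifest list from [studyManifest()] or path to a YAML manifest.
#' @param outdir optional output directory for the report bundle (summary
#'   JSON plus stage CSVs).
#' @return the summary list (invisibly when `outdir` is given).
#' @export
runStudy <- function(manifest, outdir = NULL) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  m <- modifyList(studyManifest(), manifest)
  cfg <- do.call(runConfig, c(m$config, list(seed = m$seed)))
  spec <- do.call(domainStudySpec, c(m$spec, list(seed = m$seed)))
  study <- generateStudy(spec, dir = if (!is.null(outdir)) file.path(outdir, "data"))

  datasets <- list(
    public_like = curateStudyDomain(study, "public_like", cfg),
    proprietary_like = curateStudyDomain(study, "proprietary_like", cfg))
  for (d in names(datasets)) {
    if (!isEligible(datasets[[d]]))
      stopf("stage curate failed for %s: %s", d, datasets[[d]]@rejectReason)
  }
  descs <- lapply(datasets, computeDescriptorMatrix, provider = m$provider,
                  nbits = cfg@fingerprintBits)
  fps <- lapply(datasets, function(ds)
    computeFingerprint(members(ds)$smiles, memberKeys(ds), nbits = cfg@fingerprintBits))

  summary <- list(study = m$name, seed = m$seed,
                  n_public = nMembers(datasets$public_like),
                  n_proprietary = nMembers(datasets$proprietary_like))
  files <- list()

  within <- list()
  if (any(c("within", "cross", "mixing") %in% m$stages)) {
    for (d in names(datasets)) {
      within[[d]] <- lapply(setNames(m$schemes, m$schemes), function(sch)
        runNestedCV(datasets[[d]], descs[[d]], m$algorithm, sch, cfg,
                    fingerprints = fps[[d]]))
    }
    summary$within_domain <- lapply(within, function(byScheme)
      lapply(byScheme, function(res) list(
        mean_outer_mcc = mean(res@outerMetrics$mcc),
        sd_outer_mcc = sd(res@outerMetrics$mcc),
        final_hyperparams = res@finalHyperparams)))
  }

  if ("cross" %in% m$stages) {
    sch <- m$schemes[1]
    crossReports <- list()
    for (trainD in names(datasets)) {
      testD <- setdiff(names(datasets), trainD)
      bundle <- retrainFinal(datasets[[trainD]], descs[[trainD]], m$algorithm,
                             within[[trainD]][[sch]]@finalHyperparams,
                             seed = deriveSeed(cfg@seed, 77L), svmMaxN = cfg@svmMaxN)
      filt <- filterLeakage(datasets[[testD]], datasets[[trainD]])
      testDesc <- computeDescriptorMatrix(filt$dataset, m$provider,
                                          nbits = cfg@fingerprintBits)
      crossReports[[paste0(trainD, "->", testD)]] <-
        evaluateCross(bundle, filt$dataset, testDesc, train_domain = trainD,
                      target = "SYNT1")
    }
    summary$cross_domain <- lapply(crossReports, function(r) list(
      mcc = unname(r@metrics@metrics[["mcc"]]),
      n_removed_leakage = r@nRemovedLeakage,
      bias_direction = r@biasDirection,
      fp = unname(r@metrics@counts[["fp"]]),
      fn = unname(r@metrics@counts[["fn"]])))
    files$cross <- crossReports
  }

  if ("chemspace" %in% m$stages) {
    nn <- nnMeanTanimoto(fps$proprietary_like, fps$public_like)
    nnRev <- nnMeanTanimoto(fps$public_like, fps$proprietary_like,
                            direction = "public_like->proprietary_like")
    phys <- lapply(datasets, function(ds)
      computePhyschem(members(ds)$smiles, memberKeys(ds)))
    summary$chemspace <- list(
      mean_nn_tanimoto_prp_to_pub = nn$mean_nn_similarity,
      mean_nn_tanimoto_pub_to_prp = nnRev$mean_nn_similarity,
      property_shifts = comparePropertyDistributions(
        phys$public_like, phys$proprietary_like)[, c("property", "standardized_shift")])
    if (isTRUE(m$umap)) {
      delta <- domainDeltaSets(datasets$public_like, datasets$proprietary_like)
      allKeys <- c(memberKeys(datasets$public_like), memberKeys(datasets$proprietary_like))
      domTags <- setNames(rep(names(datasets), vapply(datasets, nMembers, 0L)), allKeys)
      joint <- rbind(descriptorValues(descs$public_like),
                     descriptorValues(descs$proprietary_like))
      joint <- joint[!duplicated(rownames(joint)), , drop = FALSE]
      shared <- memberKeys(datasets$public_like)[
        memberInchis(datasets$public_like) %in% delta$shared]
      summary$chemspace$umap <- embedChemicalSpace(
        joint, params = cfg@umapParams, seed = cfg@seed,
        overlap_keys = shared, domains = domTags)
    }
  }

  if ("mixing" %in% m$stages) {
    f <- tempfile(fileext = ".csv")
    write.csv(study@tables$public_like, f, row.names = FALSE)
    pubRows <- deriveAssayFormat(readActivityTable(f)$rows)$rows
    unlink(f)
    pubFmt <- buildTargetDataset(pubRows, "SYNT1", "public_like", cfg)
    if (!isEligible(pubFmt))
      stopf("mixing stage: public set ineligible after format derivation (%s)",
            pubFmt@rejectReason)
    mix <- evaluateMixing(datasets$proprietary_like, pubFmt, m$assay_format,
                          cfg, algorithm = m$algorithm, provider = m$provider,
                          schemes = m$schemes)
    summary$mixing <- stats::aggregate(cbind(mcc, n_train) ~ approach + scheme,
                                       mix, mean)
    files$mixing <- mix
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeReport(rapply(summary, function(x)
      if (is.data.frame(x)) x else x, how = "replace"),
      file.path(outdir, "summary.json"))
    if (!is.null(within) && length(within)) {
      for (d in names(within)) for (sch in names(within[[d]]))
        writeReport(within[[d]][[sch]],
                    file.path(outdir, sprintf("within_%s_%s.json", d, sch)))
    }
    if (!is.null(files$cross)) {
      for (nm in names(files$cross))
        writeReport(files$cross[[nm]],
                    file.path(outdir, sprintf("cross_%s.json", gsub("->", "_to_", nm))))
    }
    if (!is.null(files$mixing))
      write.csv(files$mixing, file.path(outdir, "mixing_folds.csv"), row.names = FALSE)
    return(invisible(summary))
  }
  summary
}
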