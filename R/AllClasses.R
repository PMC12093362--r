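#' @import methods
NULL

DOMAIN_TAGS <- c("public_like", "proprietary_like")
LABELS <- c("active", "inactive")

#' Run configuration for the cross-source evaluation pipeline
#'
#' Holds the tunable parameters shared by the pipeline stages: the potency
#' threshold used to binarize IC50/Ki values (10 uM), the data set eligibility
#' rules (at least 250 compounds, at least 15 percent minority class), the
#' Tanimoto similarity threshold used for Butina clustering and for
#' similarity-restricted data set mixing (0.230), the nested cross-validation
#' geometry (5 inner folds, 9 outer folds), fingerprint folding width and the
#' 2-D embedding parameters.
#'
#' @slot activityThresholdUM potency threshold in micromolar; values at or
#'   below it are labeled active.
#' @slot minDatasetSize minimum curated data set size.
#' @slot minMinorityFraction minimum fraction of the minority class.
#' @slot similarityThreshold Tanimoto similarity threshold.
#' @slot kInner,kOuter inner and outer cross-validation fold counts.
#' @slot fingerprintBits folded width of the circular fingerprints.
#' @slot svmMaxN refuse SVM fits on training sets larger than this.
#' @slot umapParams list with n_neighbors, min_dist, n_components.
#' @slot seed integer run seed; every stochastic stage derives from it.
#' @export
setClass("RunConfig", representation(
  activityThresholdUM = "numeric",
  minDatasetSize = "integer",
  minMinorityFraction = "numeric",
  similarityThreshold = "numeric",
  kInner = "integer",
  kOuter = "integer",
  fingerprintBits = "integer",
  svmMaxN = "integer",
  umapParams = "list",
  seed = "integer"
), prototype(
  activityThresholdUM = 10,
  minDatasetSize = 250L,
  minMinorityFraction = 0.15,
  similarityThreshold = 0.230,
  kInner = 5L,
  kOuter = 9L,
  fingerprintBits = 2048L,
  svmMaxN = 5000L,
  umapParams = list(n_neighbors = 15, min_dist = 0.1, n_components = 2),
  seed = 1L
))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!(object@minMinorityFraction > 0 && object@minMinorityFraction < 0.5))
    msg <- c(msg, "minMinorityFraction must be in (0, 0.5)")
  if (object@kInner < 2L) msg <- c(msg, "kInner must be >= 2")
  if (object@kOuter < 2L) msg <- c(msg, "kOuter must be >= 2")
  if (object@similarityThreshold < 0 || object@similarityThreshold > 1)
    msg <- c(msg, "similarityThreshold must be in [0, 1]")
  if (object@activityThresholdUM <= 0) msg <- c(msg, "activityThresholdUM must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a RunConfig
#'
#' @param ... named overrides of the slots of [RunConfig-class].
#' @return a validated `RunConfig` object.
#' @examples
#' cfg <- runConfig(seed = 7L)
#' cfg
#' @export
runConfig <- function(...) {
  args <- list(...)
  obj <- new("RunConfig")
  for (nm in names(args)) {
    if (!nm %in% slotNames("RunConfig")) stopf("unknown RunConfig field '%s'", nm)
    value <- args[[nm]]
    if (is(slot(obj, nm), "integer")) value <- as.integer(value)
    slot(obj, nm) <- value
  }
  validObject(obj)
  obj
}

#' Per-target, per-domain classified compound set
#'
#' The central curated data container: standardized compounds with binary
#' activity labels for one macromolecular target in one data domain, together
#' with the full curation log (every removal carries a reason code). A data
#' set that fails the eligibility rules is kept as a rejection record with
#' `eligible = FALSE` and the failed criterion in `rejectReason`.
#'
#' @slot target target identifier.
#' @slot domain one of `public_like`, `proprietary_like`.
#' @slot compounds data.frame with columns compound_key, smiles, inchi,
#'   inchikey, label and optionally assay_format and origin.
#' @slot curationLog data.frame (compound_key, action, reason).
#' @slot eligible logical; whether the eligibility rules passed.
#' @slot rejectReason reason for rejection when not eligible.
#' @export
setClass("ClassifiedDataset", representation(
  target = "character",
  domain = "character",
  compounds = "data.frame",
  curationLog = "data.frame",
  eligible = "logical",
  rejectReason = "character"
))

setValidity("ClassifiedDataset", function(object) {
  msg <- character()
  cmp <- object@compounds
  need <- c("compound_key", "smiles", "inchi", "inchikey", "label")
  if (!all(need %in% names(cmp)))
    msg <- c(msg, paste("compounds must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(cmp$inchi)) msg <- c(msg, "duplicate InChI among members")
    if (nrow(cmp) && !all(cmp$label %in% LABELS))
      msg <- c(msg, "labels must be 'active' or 'inactive'")
  }
  if (!object@domain %in% DOMAIN_TAGS)
    msg <- c(msg, "domain must be 'public_like' or 'proprietary_like'")
  if (length(msg)) msg else TRUE
})

#' Numeric descriptor matrix under a named provider
#'
#' Rows are compounds (rownames are compound keys, aligned to the member order
#' of the data set the matrix was computed from), columns are features of one
#' descriptor provider. Compounds a provider could not cover (e.g. keys absent
#' from an embedding table) are recorded in `dropped`, never silently imputed.
#'
#' @slot provider one of `estate_like`, `embedding`, `fingerprint_bits`.
#' @slot values numeric matrix, compounds x features.
#' @slot dropped data.frame (compound_key, reason) of uncovered compounds.
#' @export
setClass("DescriptorMatrix", representation(
  provider = "character",
  values = "matrix",
  dropped = "data.frame"
))

setValidity("DescriptorMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) && is.null(rownames(object@values)))
    msg <- c(msg, "values must carry compound keys as rownames")
  if (nrow(object@values) && any(!is.finite(object@values)))
    msg <- c(msg, "descriptor values must be finite")
  if (length(msg)) msg else TRUE
})

#' Loadable embedding-vector provider
#'
#' Wraps an externally produced compound-key to fixed-length-vector table
#' (for example neural molecular embeddings). The vector width is data-driven.
#'
#' @slot vectors numeric matrix with compound keys as rownames.
#' @export
setClass("EmbeddingProvider", representation(vectors = "matrix"))

#' Butina sphere-exclusion clustering result
#'
#' @slot clusterId named integer vector, compound key to cluster id (dense
#'   from 1).
#' @slot centroids character vector of centroid compound keys, indexed by
#'   cluster id.
#' @slot threshold Tanimoto similarity threshold used.
#' @export
setClass("ClusterAssignment", representation(
  clusterId = "integer",
  centroids = "character",
  threshold = "numeric"
))

#' Fold assignment for cross-validation
#'
#' @slot fold named integer vector, compound key to fold in 1..k.
#' @slot k number of folds.
#' @slot scheme `random` (class-stratified) or `cluster` (Butina clusters
#'   never span folds).
#' @slot seed seed used for the assignment.
#' @slot clusterId named integer vector of cluster memberships (cluster
#'   scheme only; empty otherwise).
#' @export
setClass("FoldAssignment", representation(
  fold = "integer",
  k = "integer",
  scheme = "character",
  seed = "integer",
  clusterId = "integer"
))

setValidity("FoldAssignment", function(object) {
  msg <- character()
  if (!object@scheme %in% c("random", "cluster")) msg <- c(msg, "scheme must be random or cluster")
  if (length(object@fold) && (min(object@fold) < 1L || max(object@fold) > object@k))
    msg <- c(msg, "folds must lie in 1..k")
  if (is.null(names(object@fold)) && length(object@fold))
    msg <- c(msg, "fold vector must be named by compound key")
  if (length(msg)) msg else TRUE
})

#' Binary classification metrics report
#'
#' Confusion counts plus the eight evaluation statistics: sensitivity,
#' specificity, balanced accuracy, accuracy, positive and negative predictive
#' value, F-measure and the Matthews correlation coefficient. Undefined
#' ratios are reported as NaN; an MCC whose denominator contains a zero
#' factor is 0 by convention, with a note recorded.
#'
#' @slot counts named integer vector (tp, tn, fp, fn).
#' @slot metrics named numeric vector of the eight statistics.
#' @slot notes character vector of degenerate-case notes.
#' @slot context provenance list (target, domain, fold, scheme, model, ...).
#' @export
setClass("MetricsReport", representation(
  counts = "integer",
  metrics = "numeric",
  notes = "character",
  context = "list"
))

#' Fitted classifier with its training provenance
#'
#' @slot fit fitted model object (ranger, xgb.Booster or svm).
#' @slot algorithm `rf`, `xgb` or `svm`.
#' @slot provider descriptor provider tag the model was trained on.
#' @slot hyperparams named list of the hyperparameters used.
#' @slot featureNames training feature names, enforced at prediction.
#' @slot trainInchis InChIs of the training compounds (leakage guard).
#' @slot datasetHash md5 over the sorted training InChIs.
#' @slot seed fitting seed.
#' @export
setClass("ModelBundle", representation(
  fit = "ANY",
  algorithm = "character",
  provider = "character",
  hyperparams = "list",
  featureNames = "character",
  trainInchis = "character",
  datasetHash = "character",
  seed = "integer"
))

#' Nested cross-validation result
#'
#' @slot outerMetrics data.frame with one row per outer fold: the selected
#'   hyperparameters and the outer-test metrics.
#' @slot selections list of per-outer-fold selected hyperparameter lists.
#' @slot finalHyperparams the mode of the outer selections (ties resolved by
#'   higher mean outer-test MCC, then grid order).
#' @slot algorithm,scheme,provider,seed provenance.
#' @export
setClass("NestedCVResult", representation(
  outerMetrics = "data.frame",
  selections = "list",
  finalHyperparams = "list",
  algorithm = "character",
  scheme = "character",
  provider = "character",
  seed = "integer"
))

#' Cross-domain evaluation report
#'
#' Result of applying a frozen model trained on one domain to the curated
#' data set of the other domain after InChI leakage filtering.
#'
#' @slot trainDomain,testDomain,target provenance.
#' @slot nTestBefore,nRemovedLeakage,nTestAfter leakage filtering counts.
#' @slot metrics a [MetricsReport-class].
#' @slot biasDirection `overpredicts_actives`, `overpredicts_inactives` or
#'   `balanced` under the margin rule |fp - fn| > 0.05 * n.
#' @export
setClass("CrossEvalReport", representation(
  trainDomain = "character",
  testDomain = "character",
  target = "character",
  nTestBefore = "integer",
  nRemovedLeakage = "integer",
  nTestAfter = "integer",
  metrics = "MetricsReport",
  biasDirection = "character"
))

setValidity("CrossEvalReport", function(object) {
  if (object@nTestAfter != object@nTestBefore - object@nRemovedLeakage)
    "nTestAfter must equal nTestBefore - nRemovedLeakage" else TRUE
})

#' Specification of a synthetic two-domain bioactivity study
#'
#' Controls the generator that emulates the statistical structure of a
#' public/proprietary data source pair: opposite class skews (the public-like
#' domain majority-active, the proprietary-like domain majority-inactive),
#' controllable scaffold-level chemical-space overlap, a bounded fraction of
#' identical compounds shared between the domains, replicate measurements
#' with label conflicts, and cell-based/cell-free assay-format annotations.
#'
#' @slot nScaffolds number of scaffold families in the library.
#' @slot substituentsPerScaffold substituent pairs enumerated per scaffold.
#' @slot scaffoldOverlap fraction of scaffolds shared between the domains.
#' @slot identityOverlap fraction of each domain that is an exact copy of a
#'   compound in the other domain (default 0.10, the maximum the study system
#'   emulates).
#' @slot nPerDomain compounds sampled per domain.
#' @slot activeFractionPublic,activeFractionProprietary target class skews
#'   (defaults 0.8 and 0.2).
#' @slot replicateProb probability a compound gets replicate measurements.
#' @slot conflictRate fraction of replicated compounds whose replicates are
#'   forced to straddle the 10 uM threshold.
#' @slot measurementNoiseSD per-measurement noise, log10 uM units.
#' @slot scaffoldEffectSD scaffold-level potency effect, log10 uM units.
#' @slot pharmacophoreEffect potency shift (log10 uM) conferred by the
#'   activity-carrying fragment; 0 yields label-free noise (null data).
#' @slot cellBasedFraction fraction of measurements annotated cell-based,
#'   per domain (named numeric of length 2).
#' @slot formatNoiseSD extra label noise applied to measurements of the
#'   non-matching assay format (used by the mixing study; default 0).
#' @slot flipLabelRule if TRUE the proprietary-like domain reports inverted
#'   potencies (emulates an inter-source assay readout inconsistency).
#' @slot seed generator seed.
#' @export
setClass("DomainStudySpec", representation(
  nScaffolds = "integer",
  substituentsPerScaffold = "integer",
  scaffoldOverlap = "numeric",
  identityOverlap = "numeric",
  nPerDomain = "integer",
  activeFractionPublic = "numeric",
  activeFractionProprietary = "numeric",
  replicateProb = "numeric",
  conflictRate = "numeric",
  measurementNoiseSD = "numeric",
  scaffoldEffectSD = "numeric",
  pharmacophoreEffect = "numeric",
  cellBasedFraction = "numeric",
  formatNoiseSD = "numeric",
  flipLabelRule = "logical",
  seed = "integer"
), prototype(
  nScaffolds = 24L,
  substituentsPerScaffold = 120L,
  scaffoldOverlap = 0.5,
  identityOverlap = 0.10,
  nPerDomain = 500L,
  activeFractionPublic = 0.8,
  activeFractionProprietary = 0.2,
  replicateProb = 0.2,
  conflictRate = 0.05,
  measurementNoiseSD = 0.2,
  scaffoldEffectSD = 0.9,
  pharmacophoreEffect = -1.8,
  cellBasedFraction = c(public_like = 0.5, proprietary_like = 0.5),
  formatNoiseSD = 0,
  flipLabelRule = FALSE,
  seed = 1L
))

setValidity("DomainStudySpec", function(object) {
  msg <- character()
  fr <- c(object@scaffoldOverlap, object@identityOverlap, object@replicateProb,
          object@conflictRate, object@activeFractionPublic, object@activeFractionProprietary)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "all fractions must be in [0, 1]")
  if (object@nScaffolds < 2L) msg <- c(msg, "nScaffolds must be >= 2")
  if (object@scaffoldOverlap == 0 && object@identityOverlap > 0)
    msg <- c(msg, "identityOverlap > 0 requires scaffoldOverlap > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a DomainStudySpec
#'
#' @param ... named overrides of the slots of [DomainStudySpec-class].
#' @return a validated `DomainStudySpec`.
#' @export
domainStudySpec <- function(...) {
  args <- list(...)
  obj <- new("DomainStudySpec")
  for (nm in names(args)) {
    if (!nm %in% slotNames("DomainStudySpec")) stopf("unknown DomainStudySpec field '%s'", nm)
    value <- args[[nm]]
    if (is(slot(obj, nm), "integer")) value <- as.integer(value)
    if (is(slot(obj, nm), "logical")) value <- as.logical(value)
    slot(obj, nm) <- value
  }
  validObject(obj)
  obj
}

#' A generated synthetic two-domain study
#'
#' @slot spec the generating [DomainStudySpec-class].
#' @slot tables list of two raw activity tables (data.frames), one per
#'   domain, in the package's activity-table dialect.
#' @slot groundTruth data.frame of true potencies and scaffold ids; written
#'   to a separate file and never read by any pipeline stage.
#' @export
setClass("SyntheticStudy", representation(
  spec = "DomainStudySpec",
  tables = "list",
  groundTruth = "data.frame"
))
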