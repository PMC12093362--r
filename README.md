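# qsarShift

Cross-source evaluation of binary QSAR bioactivity models.

## The problem

Bioactivity data for the same macromolecular target come from very different
places: public collections (ChEMBL-like exports) are typically skewed toward
*active* compounds, while proprietary in-house decks are skewed toward
*inactives*, and the two cover different regions of chemical space. A
classifier trained on one source and applied to the other faces both shifts
at once, and its failure modes are systematic: models trained on
active-skewed data over-predict actives, models trained on inactive-skewed
data over-predict inactives. `qsarShift` is a pipeline for studying exactly
this: it curates per-target binary data sets, trains classifiers under
nested cross-validation, applies frozen models across domains with strict
leakage control, quantifies chemical-space divergence, and compiles mixed
training sets — plus a synthetic two-domain study generator so the whole
pipeline runs and is tested without any proprietary data.

## What it computes

* **Curation** — potency values (IC50/Ki, pooled) are binarized at 10 uM
  (ties active). Structures are standardized (largest organic fragment, no
  stereo, neutralized) and identified by InChI. Replicate conflicts are
  removed in the public-like domain but resolved to *active* in the
  proprietary-like domain. A data set is eligible with >= 250 compounds and
  >= 15 % minority class; everything removed is logged with a reason.
* **Descriptors** — OpenBabel ECFP4 circular fingerprints (2048 bits),
  a Kier–Hall electrotopological-state vector computed from the molecular
  graph, loadable embedding-vector tables, and seven physicochemical
  properties.
* **Splitting** — from-scratch Butina sphere-exclusion clustering at
  Tanimoto similarity >= 0.230, class-stratified random folds, and
  cluster-integrity folds for structure-aware validation.
* **Models** — random forest, XGBoost and SVM behind one fit/predict
  contract, tuned by MCC in a 5-fold inner / 9-fold outer nested CV, with
  the final model retrained on the mode of the outer selections.
* **Transfer** — frozen models evaluated on the other domain after InChI
  leakage filtering; eight statistics (sensitivity … MCC) plus an
  over-prediction bias call with a 5 % margin rule.
* **Chemical space** — directional nearest-neighbor mean Tanimoto
  similarity, seeded 2-D UMAP embeddings, physicochemical distribution
  shifts.
* **Mixing** — base + public training sets compiled by target (a), + assay
  format (b), + Tanimoto >= 0.230 to the base set (c), evaluated by random
  and cluster-based nested CV.

## Worked example

```r
library(qsarShift)

# a synthetic two-domain study under the default conditions
study <- generateStudy(domainStudySpec(seed = 3L), dir = "study3")
cfg <- runConfig(seed = 3L)

parsed <- readActivityTable("study3/public_like.csv")
pub <- buildTargetDataset(parsed$rows, "SYNT1", "public_like", cfg)
pub
#> ClassifiedDataset: target SYNT1, domain public_like
#>   490 compounds (393 active / 97 inactive), 10 curation-log entries

est <- computeDescriptorMatrix(pub, "estate_like")
res <- runNestedCV(pub, est, "xgb", "random", cfg)
res
#> NestedCVResult: xgb / random splits, 9 outer folds (seed 3)
#>   mean outer MCC: 0.681
#>   final hyperparameters: n_estimators=200, max_depth=7
```

The curated public-like domain keeps its active skew (393/490 active) while
the replicate conflicts are removed (logged); within-domain nested CV shows
the target is learnable (mean outer MCC 0.681). Applying the retrained
model to the proprietary-like domain after leakage filtering shows the
transfer penalty and the characteristic bias:

```r
bundle <- retrainFinal(pub, est, "xgb", res@finalHyperparams, seed = 3L)
prp <- buildTargetDataset(readActivityTable("study3/proprietary_like.csv")$rows,
                          "SYNT1", "proprietary_like", cfg)
filt <- filterLeakage(prp, pub)
rep <- evaluateCross(bundle, filt$dataset,
                     computeDescriptorMatrix(filt$dataset, "estate_like"),
                     train_domain = "public_like")
biasDiagnostic(rep)[c("direction", "fp", "fn")]
#> $direction
#> [1] "overpredicts_actives"
#> $fp
#> [1] 123
#> $fn
#> [1] 19
```

The model trained on the active-skewed domain produces six times more
false actives than false inactives on the inactive-skewed domain — the
over-prediction asymmetry the pipeline is built to expose. Whole studies
(within-domain CV, transfer, chemical-space diagnostics, mixing) run from a
single manifest with `runStudy()`; shipped manifests live in
`inst/manifests/`, and `exec/qsarshift` exposes the stages as shell
subcommands (`simulate`, `curate`, `split`, `train`, `evaluate-cross`, ...).

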