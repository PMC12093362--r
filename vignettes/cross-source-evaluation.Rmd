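---
title: "Evaluating bioactivity classifiers across data sources"
author: "qsarShift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating bioactivity classifiers across data sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Binary QSAR models for a macromolecular target are routinely trained on
whatever bioactivity measurements are available, and public and proprietary
sources sample chemistry and assay conditions very differently: public
collections tend to be enriched in actives (positive results get published),
while in-house screening decks are dominated by inactives. When a model
trained on one source is applied to compounds from the other, both the
covariate distribution (chemical space) and the label distribution (class
skew) shift at once. `qsarShift` implements the full evaluation study for
this situation — curation, descriptor computation, nested cross-validated
training, frozen-model transfer with leakage control, chemical-space
diagnostics, and mixed-training-set compilation — together with a synthetic
two-domain generator so that every stage is testable without access to any
proprietary data.

## Curation model

Potency measurements (IC50 and Ki are pooled as interchangeable replicates)
are binarized at **10 uM**: a value at or below the threshold is *active*.
The tie is deliberately inclusive-active, because unit conversion rounding
otherwise flips labels of compounds recorded as exactly 10 uM. Relation
qualifiers are used only when directionally informative: a `>` value above
the threshold supports *inactive*, a `<` value at or below it supports
*active*; any other qualified row is excluded and logged.

Structures are standardized before identity is decided: the largest organic
fragment is kept (salt stripping), stereochemistry is removed, charges are
neutralized where chemically attainable, and the InChI of the standardized,
stereo-free structure is the identity key everywhere (duplicate collapse,
leakage filtering, mixing collisions).

Replicate conflicts — one compound with measurements on both sides of the
threshold — are resolved asymmetrically by domain, reflecting how the two
kinds of sources are managed. In the public-like domain the compound is
removed (heterogeneous assays, no way to arbitrate). In the proprietary-like
domain any active replicate makes the compound active: in off-target work a
false positive is an acceptable cost while a missed liability is not.

A curated set is *eligible* when it has at least **250 compounds** and at
least **15 %** of the minority class, both checked on the final set (after
conflict removal); a set failing either rule is kept as a rejection record
with the failed criterion and observed counts. Every removal, at every
stage, lands in a curation log with a reason code — the removal counts are
study outputs, not incidental bookkeeping.

## Descriptor providers

Three providers sit behind one interface, and all downstream code treats the
feature width as data-driven:

* **Circular fingerprints** — extended-connectivity (Morgan-type) radius-2
  fingerprints computed with OpenBabel (ECFP4), folded to 2048 bits by
  default (configurable). Used for Tanimoto similarity, Butina clustering,
  nearest-neighbor diagnostics and the similarity-restricted mixing rule,
  and available as a binary feature matrix.
* **Electrotopological-state (E-state) vectors** — implemented here from
  the Kier–Hall theory: each heavy atom gets an intrinsic state
  $I = ((2/N)^2\,\delta^v + 1)/\delta$ ($N$ the principal quantum number,
  $\delta^v$ valence electrons minus implicit hydrogens, $\delta$ the heavy
  atom degree), perturbed by every other atom with
  $\sum_j (I_i - I_j)/(d_{ij}+1)^2$ over topological distances. Atom values
  are summed over a fixed vocabulary of atom types (element, bond pattern,
  hydrogen count, ring membership; 85 types). The historically used
  79-feature commercial aggregation is proprietary and not enumerable, so
  the vocabulary is this package's own; the hand-checked ethanol solution
  (S = 1.681, 0.250, 7.569) pins the atom-level arithmetic in the tests.
* **Embedding tables** — externally produced fixed-length vectors (for
  example neural translation-autoencoder descriptors) are loaded from a
  key + columns table; the width is whatever the table provides (512 in the
  motivating use). A key missing from the table is a miss signal: the
  compound is dropped with a log entry and the data set view narrowed;
  zero-imputation is forbidden.

Physicochemical records carry molecular weight, H-bond donor and acceptor
counts, heavy atoms, rotatable bonds, TPSA and `logp_proxy` — a computed
logP standing in for pH-corrected logD predictors that are not publicly
available; the field name flags the substitution.

## Splitting and nested cross-validation

Butina sphere-exclusion clustering is implemented from scratch: neighbor
lists at Tanimoto similarity **≥ 0.230** (note this is a *similarity*
threshold, i.e. a distance cutoff of 0.770 in the usual distance
parameterization), then repeatedly take the unassigned compound with the
most unassigned neighbors (ties: lowest input index) as a centroid and
assign it with its unassigned neighbors. Isolated compounds end as
singletons; cluster ids are dense from 1 (R indexing; external tools often
number from 0).

Folds (also 1-based) come in two schemes. *Random* folds are class-stratified
— unstratified draws at a 15 % minority can produce single-class inner folds
and undefined MCCs — with sizes differing by at most one. *Cluster* folds
assign whole Butina clusters, largest first, each to the currently smallest
fold; a cluster never spans folds, so cluster-based test folds are
structurally dissimilar from their training folds.

Model evaluation is a **5-fold inner / 9-fold outer** nested CV. Inner
selection maximizes mean inner-validation MCC over a deliberately small
grid (random forest: 50/100/200 trees x unlimited/10/20 depth; gradient
boosting: 50/100/200 rounds x depth 3/5/7; SVM: C 0.1/1/10 x linear/rbf),
ties resolved by grid order. The final model is retrained on the full set
with the **mode** of the nine outer selections — an odd outer count keeps
the mode informative — with mode ties resolved by higher mean outer-test
MCC, then grid order. Inner fold seeds derive deterministically from the run
seed and the outer fold index, so the structure is reproducible and
auditable: no outer-test compound can reach an inner fold. Kernel SVM fits
refuse training sets above a configurable cap (default 5000) because their
cost grows super-quadratically; the cap is a guard, not a tuning knob.

## Metrics

Eight statistics are computed from the confusion counts exactly as defined:
sensitivity, specificity, balanced accuracy, accuracy, PPV, NPV, F-measure
(harmonic form of PPV and sensitivity) and MCC. A ratio with a zero
denominator is reported as `NaN` — never silently 0 — and an MCC whose root
contains a zero factor is 0 by convention (a degenerate predictor carries no
correlation), with a note in the report.

## Cross-domain evaluation and bias

Frozen final models are applied to the other domain's curated set after
**InChI leakage filtering**: every test compound whose standardized InChI
occurs in the training set is removed and logged (a pure, idempotent set
operation). The evaluator refuses unfiltered input. Over-prediction bias is
called from the confusion counts with a margin: *overpredicts actives* when
fp − fn > 0.05·n, *overpredicts inactives* when fn − fp > 0.05·n, otherwise
*balanced* — without the margin, sampling noise on balanced predictions
would be labeled bias.

## Chemical-space diagnostics

Nearest-neighbor mean Tanimoto similarity is directional; the default
direction is proprietary-like → public-like (each in-house compound asks how
close its nearest public neighbor is), both directions are computable. The
2-D embedding uses UMAP (n_neighbors 15, min_dist 0.1, 2 components) through
the `umap-learn` backend with a mandatory seed; the "delta" views remove
the shared InChIs from each counterpart set, and both directions are
reported. The embedding is computed on E-state vectors by default: they
express drug-likeness features on which neural embeddings are known to give
inconsistent Tanimoto behavior. Physicochemical distributions are compared
per property by medians, quartiles and a robust standardized location shift
(median difference over pooled MAD).

These diagnostics are computed and tested for correctness only. The study
design explicitly does *not* assert that chemical-space proximity predicts
transfer performance — the shipped `diagnostics_decoupling` manifest
constructs the counterexample (high similarity, inverted label rule, poor
transfer).

## Mixed training sets

A proprietary-like base set from one experimental setup can be enriched with
public compounds three ways, nested by construction: (a) same target only;
(b) additionally the base setup's assay format; (c) additionally a maximum
Tanimoto similarity to *any* base compound of at least 0.230 — the
nearest-neighbor-to-base reading, consistent with how similarity is used in
the diagnostics, logged per compound. Public assay formats are derived from
annotations: assay types Binding/ADME/Toxicity with a cell name are
cell-based, without one cell-free; other assay types are excluded. On an
InChI collision the base label wins and the public copy is dropped with a
log entry. The base setup's format is a required user input — public
annotations cannot reconstruct another laboratory's setup.

## The synthetic two-domain generator

The generator's purpose is the *statistical* structure of a
public/proprietary source pair, not medicinal-chemistry fidelity. Molecules
are combinatorial assemblies of two substituent fragments on 24 scaffold
templates (diverse ring systems chosen so circular fingerprints separate
scaffold families around the 0.230 threshold); about 2 400 distinct
standardized structures at the default 100 substituent pairs per scaffold.
Latent potency follows
log10 IC50 [uM] = 1.3 + (−1.8)·pharmacophore + scaffold effect (SD 0.7)
+ compound jitter (SD 0.2), with a 9-fragment pharmacophore vocabulary
(sulfonamide/sulfone/acid chemistry) carrying the signal; thresholding at
10 uM makes labels learnable from structure while the scaffold term makes
them partly scaffold-dependent, which is what degrades transfer at low
scaffold overlap. Measurements add log-normal noise (SD 0.2 log units, a same-assay
replicate scale; inter-source inconsistency enters separately through the
conflict and format-noise machinery). The effect sizes were set so the
benchmark exhibits its two defining properties: labels recoverable by the
pipeline's classifiers within a domain, and a transfer penalty that grows
as scaffold overlap shrinks.

Default study conditions: 500 compounds per domain; the public-like domain
80 % active, the proprietary-like domain 20 % active (sampled to the target
within rounding, verified within ±3 percentage points); exactly 10 % of
each domain copied into the other (identity overlap, drawn from shared
scaffolds); 20 % of compounds replicated, with 5 % of replicated compounds
forced to straddle the threshold so both conflict rules are exercised;
assay formats drawn half cell-based per domain. Scaffold overlap between
the domains is a dial (default 0.5). Two study-specific switches exist:
`formatNoiseSD` adds potency noise to public cell-free measurements
(emulating format-dependent readouts for the mixing study) and
`flipLabelRule` inverts the proprietary-like readout (the
diagnostics-decoupling counterexample). Ground truth is written to a
separate table no pipeline stage reads.

What the generator does **not** emulate: real property distributions and
their source differences, assay-panel heterogeneity beyond the planted
format effect, activity cliffs, measurement censoring patterns, or target
biology. Tests passing on this benchmark therefore certify the pipeline's
mechanics and the qualitative skew/shift phenomena, not performance on real
collections.

## Problem sizes and numerical choices

The test suite runs the full study conditions (500 per domain) for the
learnability, null and bias checks, and 300 per domain for the
scaffold-overlap sweep and the mixing simulation — sizes chosen to keep a
complete run of ten seeded replicates comfortable on a single core while
staying above the 250-compound eligibility rule. Gradient-boosted (XGB) models on E-state vectors are the workhorse for
the simulation studies — on this benchmark they pair the best accuracy
with the lowest fitting cost, echoing why boosted trees are often chosen
for throughput; all three algorithm families run through the same code path
and are exercised directly in the unit tests. Seeds derive from the run
seed by a fixed affine map kept below 2^31. Degenerate inputs are contracts,
not surprises: empty molecule → error; empty fingerprint pair → similarity
0 with a warning; k folds exceeding assignable units → error naming both
counts; single-class training portions → error.

## Known limitations

* Standardization relies on OpenBabel's neutralize transform; exotic
  zwitterions (e.g. nitro groups) are left charged by design, and tautomer
  canonicalization is out of scope.
* The E-state vocabulary is this package's own; absolute feature values are
  not comparable to Molconn-Z outputs, only to themselves.
* The UMAP step shells out to the Python `umap-learn` implementation and is
  deterministic only under its seeded single-threaded mode.
* Embedding-vector providers are load-only; training an encoder is out of
  scope.
* Cross-evaluation never recalibrates; mitigating the skew-induced bias
  (e.g. by consensus or threshold shifting) is deliberately not implemented.
* There is no dedicated knob for repeating the outer CV; repeated estimates
  are obtained by varying the run seed, which re-seeds every fold draw.
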