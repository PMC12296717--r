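---
title: "Multi-platform data fusion for origin discrimination: methods and design"
author: "ChemoFusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-platform data fusion for origin discrimination: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Authenticating the geographical origin of a natural product (here the
motivating case is a medicinal fruit crop with several growing regions)
is difficult from any single analytical platform: LC-MS and GC-MS see
partially disjoint compound classes, ^1^H NMR sees abundant polar
metabolites, and mid-infrared (MIR) spectroscopy sees functional-group
composition. ChemoFusion implements a complete chemometric workflow
that combines the four platforms at three different points of the
modelling chain, compares the resulting classifiers, and exports a
small panel of *characteristic variables* whose discriminating power is
then verified on samples from origins the model never saw.

The package is organised around four S4 containers: `FeatureBlock`
(one platform's samples-by-features table, a thin
`SummarizedExperiment` subclass), `SpectrumSet` (raw per-sample
spectra), `FusionStudy` (manifest + blocks + optional planted ground
truth) and `FusionConfig` (every tunable of the workflow in one
validated object).

# Preprocessing

**NMR.** Spectra are first referenced by translating the axis so the
apex of the lock signal (TSP, 0.00 ppm) sits exactly at zero; the apex
is the tallest local maximum within ±0.05 ppm of zero, and a spectrum
without a peak there is an error, not a silent pass-through. The
referenced spectrum is then integrated into fixed-width buckets of
0.002 ppm tiling 0.4–12.0 ppm as half-open intervals `[b, b + w)`. A
bucket's value is the **sum** of the grid intensities falling in it
(on a uniform grid the sum is proportional to the integral; the
convention is recorded in the bucket metadata). Any bucket overlapping
the residual-water window 4.8–5.0 ppm is dropped whole rather than
truncated — truncation would bias bucket areas at the window edges.
With these conventions the default scheme retains exactly 5700
buckets: 5800 tiles minus the 100 whose interior intersects the open
water window; a bucket merely touching the window boundary is kept.

**MIR.** The pipeline is Savitzky–Golay smoothing, then vector
normalization (unit Euclidean norm), then removal of the uninformative
regions 3500–4000, 2200–2400 and 400–500 cm^-1^ — in that order. The
order matters and is regression-tested: normalizing before removal
scales each spectrum by the norm of the *full* smoothed spectrum, so
removing regions afterwards does not change the relative scale of the
retained points. Removed regions are closed intervals; a grid point on
the boundary is removed (a deterministic tie rule). The SG defaults
are window 5, polynomial order 3: at the typical 8 cm^-1^ FTIR
sampling interval a 5-point window spans about 40 cm^-1^, comparable
to the FWHM of the sharpest functional-group bands, whereas a much
wider window (e.g. 11 points ≈ 88 cm^-1^) visibly smears each band
over many neighbouring grid points and multiplies the number of
redundant, near-identical discriminative variables downstream. Both
parameters are exposed configuration.

**Standardization.** Every block (tabular or spectral-derived) is
Z-scored feature-wise with mean and *population* (denominator *n*)
standard deviation estimated **from the model samples only**; external
samples are transformed with the same fitted statistics. This is a
deliberate leakage guard: the external set must not influence any
statistic it is later judged with. Zero-variance features are dropped
with a warning rather than producing NaNs. The fitted `(center,
scale)` is stored in the block's metadata, and the transform is
exactly invertible (tested to 1e-9).

# The three fusion levels

Let the standardized blocks be $X_1,\dots,X_4$ with a two-class label
$y$ on the model samples; the model set is split 70/30 into train and
test by a stratified largest-remainder partition (so 70 samples split
exactly 49:21).

**Low-level (LLDF).** Direct column-wise concatenation
$[X_1|X_2|X_3|X_4]$, no selection; fused feature ids keep a block
prefix so every column stays traceable.

**Mid-level (MLDF).** Per-block feature extraction before merging,
with four selectors: PCA scores or PLS-DA latent-variable scores with
the component count chosen as the smallest $k$ whose cumulative
explained (X-)variance reaches 95% (capped at the matrix rank), or
the top-40 original variables by decision-tree or random-forest Gini
importance. The extracts are concatenated and a second-stage
classifier is trained; models are named `SELECTOR-CLASSIFIER`
(`RF-RF`, `PLSDA-kNN`, ...). Only DT/RF selectors keep original
variables, so only their models support variable screening —
score-type features are deliberately rejected by the screening code.

**High-level (HLDF).** Per block: a 100-tree random forest over all
features ranks them by normalized Gini importance and the top 120
survive; a second forest refit on the survivors ranks them again and
the top 40 are kept with the refit importances. Each block's
importances are multiplied by the block weight $1/4$ (equal weights;
$1/n$ for $n$ blocks), the four weighted lists are merged into a
160-candidate pool, sorted (ties broken by block order, then original
column index), and the top 40 train the final forest (`RF-RF-RF`).
Because the within-block weight is constant, the fused ordering within
one block always equals the refit ordering; fused importances are each
at most the block weight and total at most one. These invariants are
tested, and the whole procedure is checked against a brute-force
replay (explicit fit / sort / refit / weight / merge) on a two-block
toy.

Whether the second stage *refits* or reuses the stage-1 importances is
genuinely ambiguous in workflows described as "successive" selection;
both behaviours are implemented behind `hldfRefit` (default `TRUE` —
"successive" implies a second fit, and the refit importances are the
ones available at merge time).

**Classifiers.** SVM with RBF kernel (`e1071`), 3-nearest-neighbour
with Euclidean distance (`class`), a feed-forward neural network with
hidden layers 500/200/10 (an in-package ReLU/softmax network trained
full-batch with Adam under a fixed iteration budget and seed — the
training budget is not part of the published recipe, so it is fixed
configuration), a Gini decision tree (`rpart`), a 100-tree random
forest (`randomForest`), and the projection models PCA and PLS-DA with
2 components. PCA is made predictive by nearest group centroid in
score space and PLS-DA by its maximum predicted indicator, so all
seven produce comparable metrics; the two projection models are best
read as visualization surrogates.

# Evaluation

`scoreModel()` produces the seven-metric surface: out-of-bag accuracy
(forests only), train and test accuracy, and precision / recall / F1
for the positive class on the test set, plus the ROC and its
trapezoidal AUC. The ROC sweeps thresholds over the unique scores in
descending order with tied scores forming a single step, which makes
the AUC exactly the Mann–Whitney concordance probability (ties counted
half) — asserted against exhaustive pair counting and against `pROC`
in the tests. Two conventions deserve a note:

* the **positive class** defaults to the alphabetically first model
  group, since published tables in this field rarely state it; it is
  configurable everywhere.
* **OOB is reported as out-of-bag accuracy** (higher is better), the
  orientation consistent with "values close to 1.0 are good" used in
  comparison tables, even though the underlying forest quantity is an
  error rate. The raw forest object is retained for anyone wanting the
  other orientation.

`compareStrategies()` sorts reports by (AUC, test accuracy) and names
the best model. When several strategies tie at the top — common on a
well-separated synthetic study — the pipeline screens from the
forest-based ranking (`RF-RF` first): a single tree's importance
vector is sparse, so a tree-final model ranks only a handful of
variables meaningfully and is a poor screening source even when its
metrics tie.

# Screening and external validation

`screenTopK()` takes the first $k$ (default 38) entries of the fused
ranking; it is a pure function of the ranking, hence idempotent, and
every screened variable remains traceable to (block, original feature
id). `projectExternal()` restricts the external samples to the
screened columns (already carrying the model-set standardization),
fits a PCA **on the external samples themselves**, and summarizes the
2-D scores with a *separation index*: the ratio of mean between-group
to mean within-group pairwise distance (epsilon-guarded when a group
collapses to a point). The index is an artifact-defined proxy for the
visual "separation trend" such studies assess by eye — rotation- and
translation-invariant, and only meaningful as a comparison between
projections of the same samples. Fitting the PCA on the external set
mirrors validating "by simple PCA of the verification set"; a
model-loadings projection is available via `fitOn = "model"`.

The external-validation claim the package tests is relative: the
screened panel separates the external groups better than the
full-concatenation baseline in at least 80% of paired simulated
studies, while randomly chosen panels of the same size show no such
advantage.

# The synthetic study generator

No raw data accompany the motivating workflow, so every claim is
exercised on a seeded generator whose defaults are the package's
reference study: model groups YN and GX of 35 samples each, external
groups GD (4), FJ (4), MD (3), LQS (3) — 84 samples, 70 modelled, a
5:1 model-to-validation ratio. The four blocks are an LC-MS table of
171 features (12 planted), a GC-MS table of 78 (8 planted), an NMR
spectrum set on −0.2–12.2 ppm (30 peaks, 6 planted) and an MIR set on
400–4000 cm^-1^ (20 peaks, 4 planted) — 30 planted features in total.
The tabular widths mirror the compound counts such platforms typically
report for this crop.

Design choices worth knowing:

* **Effects are multiplicative.** Tabular log-intensities get a mean
  shift of `effectSize * noiseSd` between the model groups (so
  `effectSize` is the standardized shift; the stored intensities are
  lognormal), and informative peak amplitudes are multiplied by
  `exp(sign * c_g * effectSize * ampSigma)`. Rank-based quantities are
  unaffected by the exponential, which is why an informative feature at
  `effectSize = 2` has a two-sample AUC of Φ(2/√2) ≈ 0.921 exactly.
* **Every group gets its own coefficient** on the planted features:
  the model groups sit at 0 and 1, external groups at 1.5, 2.5, −0.5,
  −1.5. The variables that discriminate YN from GX therefore also
  spread the external groups — the qualitative finding the external
  validation emulates — while staying weak enough that they are *not*
  obvious in a full-concatenation PCA of 14 samples against thousands
  of noise features.
* **Spectral realism where it matters.** NMR lines are Gaussian with
  sd 0.0008 ppm (a few Hz) on a 0.00025 ppm grid, so a planted peak
  maps to essentially the bucket containing its apex; MIR bands have
  sd 3 cm^-1^ on an 8 cm^-1^ grid. An always-present TSP reference
  peak at 0.00 ppm and a wildly varying water band at 4.9 ppm exercise
  referencing and exclusion. Analyte peaks are placed outside the
  masked/excluded regions — planting signal where the pipeline is
  defined to discard it would make ground truth unrecoverable by
  construction.
* **Gaussian peaks, not Lorentzian**: the shape is irrelevant to the
  fusion logic under test and Gaussians admit exact analytic checks.
* **One master seed fans out to per-block child seeds** by fixed
  offsets, so adding a block never perturbs earlier blocks, and the
  planted truth (feature ids, peak positions, effect signs) is stored
  beside the data so recovery metrics never need re-simulation.

What the generator does **not** emulate: chromatographic drift,
isotope patterns, peak overlap/deconvolution ambiguity, batch effects,
phase/baseline errors (spectra are generated pre-corrected, as vendor
software would deliver them), and any compound-level chemistry —
passing tests say the *pipeline logic* behaves as claimed on data with
planted multiplicative group structure, not that the workflow will
reach any particular accuracy on real samples.

# Numerical conventions and degenerate inputs

* Bucket/exclusion overlap uses the open exclusion interval; region
  removal uses closed intervals — both directions of the tie are fixed
  and tested.
* Importance ties break by (importance desc, block order, original
  column index): rankings are total orders, reproducible bit for bit.
* Population (n) denominator for the standardization sd.
* Zero-variance features drop with a warning; an all-constant block is
  an error.
* Budgets wider than a block cap at the block width with a warning
  (the GC-MS default of 78 features is narrower than the stage-1 HLDF
  budget of 120, so capping is a normal, visible event).
* Classifier and selection budgets, seeds, and the screening size live
  in one `FusionConfig`; `configDigest()` stamps reports and screened
  panels so artifacts can be traced to the configuration that produced
  them.

# Problem sizes used by the test-suite

The property suites run the reference study (84 samples, ~6,700 fused
features) over 25 paired seeds for the recovery and external-validation
claims, 50 seeds of a smaller single-block null study (40 samples, 100
features, effect 0) for AUC calibration, and small 24–30-sample studies
for the unit and oracle tests. These sizes keep each claim's Monte
Carlo error well below the asserted margins while the full suite stays
in the minutes range on one core.

# Known limitations

* The model set is strictly two-class; multi-class fusion training is
  out of scope (the external set's four groups are only ever projected,
  never trained on).
* Only text/CSV representations of spectra and tables are read and
  written; vendor formats (Bruker/Agilent, mzML) are not.
* No peak picking, deconvolution or metabolite annotation: screened
  variables are reported as bucket centers / wavenumbers / feature ids,
  and mapping them to compounds is downstream work. Note that MIR
  variables are labelled in cm^-1^ throughout (the quantity their
  values numerically are), even though comparable published tables
  sometimes label the same numbers "nm".
* The neural network is trained with a fixed iteration budget and no
  validation-based early stopping; it is a faithful member of the
  classifier comparison, not a tuned deep model.
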