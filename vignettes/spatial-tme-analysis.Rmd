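---
title: "Spatial tumor-immune microenvironment analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial tumor-immune microenvironment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialTME)
```

# The problem

Multiplexed tissue imaging of pancreatic tumors produces maps of segmented
cells — micron-scale centroids with marker intensities — from which one wants
to explain and predict response to combined chemotherapy and anti-PD-1
immunotherapy. The working hypothesis this package operationalizes is that
response is driven less by the *abundance* of immune cells than by their
*spatial organization*: recurring multi-cellular neighborhoods ("immune
niches"), in particular a niche where dendritic cells (DC), helper T cells
(Th) and cytotoxic T lymphocytes (CTL) co-cluster, and the short-range
physical contacts between those cell types.

The pipeline runs in five stages, each exposed as ordinary functions and
orchestrated by `run_pipeline()`:

1. **Phenotyping** — assign cell types from marker intensities
   (`zscore_markers()`, `assign_lineage()`), and select CTL-rich hotspot
   windows (`select_hotspot_rois()`).
2. **Niches** — per-cell neighborhood composition within a fixed radius
   (`neighborhood_profile()`), K-means clustering into immune niches
   (`fit_niches()`), per-unit niche proportions and group comparison.
3. **Interactions** — cell-cell contact graphs under a strict distance
   threshold (`build_interaction_graph()`), type-pair intensity matrices
   (`interaction_matrix()`), group comparisons, and a label-shuffle null.
4. **Response models** — a 29-feature table per ROI (7 cell ratios, 7
   densities, 15 non-tumor pair interactions; `assemble_features()`),
   repeated-split L1 logistic regression (`fit_response_model()`), survival
   classification (`fit_survival_class_model()`), and Boruta all-relevant
   feature selection (`boruta_select()`).
5. **Clinical statistics** — response summaries, CA19-9 decline, Kaplan-Meier
   and log-rank, and a Simon two-stage design calculator.

Because the underlying patient data are not public, the package ships a
synthetic-cohort generator (`simulate_cohort()`) whose planted ground truth
drives every test.

# Data model and assumptions

A `cell_map` holds one row per segmented cell: continuous coordinates in
microns with the origin at each ROI's lower-left corner, a region-of-interest
id, a patient id, and either a type label or marker intensities. Two modeling
commitments are baked in:

* **Cell position = segmentation centroid.** All distances are
  centroid-to-centroid; membrane-to-membrane geometry is not modeled. The
  15 um interaction threshold should be read in that light (roughly one cell
  diameter of separation).
* **The type vocabulary is panel-driven, not hard-coded.** The default
  seven-marker panel (`panel_pdac7()`: CD4, CD8, CD20, CD11c, CD68, PD-L1,
  panCK resolving Th, CTL, B, DC, PD-L1+/- macrophages, tumor) and the
  extended 16-type panel (`panel_tme16()`) run on the same machinery.

ROI physical dimensions are not fixed by the protocol; the generator defaults
to 1000 x 1000 um windows, configurable everywhere.

# Phenotyping model

Marker columns are z-scored over the analysis set (population-SD convention;
a zero-variance column becomes all zeros rather than being dropped). Each
cell is then assigned the *lineage* whose panel signature row has the highest
cosine similarity to its z-scored vector; cells whose best similarity falls
below a floor (default 0.3) are labeled "other". Exact ties — possible
because signatures are sparse — are broken by a declared priority order
(tumor before T subsets before myeloid before B), making assignment
deterministic. PD-L1 status is decided *after* lineage: lineages declared in
the panel's split rule (macrophages; tumor cells in the 16-type panel) are
divided at a PD-L1 z-score threshold (default 0.5). Ki67 positivity, where
the panel declares it, is an orthogonal per-cell flag (z > 1), not a lineage.

Choices worth knowing:

* **Signature amplitude.** Signatures are stored with positive markers at
  intensity 2 on the simulated scale, i.e. positive populations sit four
  noise standard deviations above background at the generator's default
  noise (`noise_sd = 0.5`). That is typical of clean immunofluorescence
  channels and makes the stated benchmark (>= 0.9 accuracy at
  `noise_sd = 0.5` on a balanced 5000-cell map) attainable by the gating
  rule itself rather than by an unrealistic noise level.
* **Cohort-relative normalization has failure modes.** Because z-scores are
  computed over the analysis set, a marker with *no* positive population
  contributes amplified noise, and a heavily dominant class (tumor cells at
  ~70% prevalence) compresses its own z-scores. On prevalence-skewed maps
  gating accuracy drops to roughly 0.7 even at moderate noise. The pipeline
  therefore prefers ground-truth labels when they exist and treats blind
  phenotyping accuracy as composition-dependent.
* **Hotspot selection** replaces the manual choice of CTL-rich regions with
  a deterministic maximizer: a sliding window on a 10 um grid (half-open
  windows, greedy non-overlapping selection in descending CTL count). The
  grid step bounds the deviation from the continuous optimum by one step.

# Neighborhood profiles and immune niches

For each cell, the neighborhood profile is the fraction of each cell type
among neighbors within radius *r* (closed ball, index cell excluded),
computed per ROI. The reference protocol fixes the radius only conceptually;
the default here is **50 um** (about 3-4 cell diameters, the scale commonly used
for cellular-neighborhood analyses), exposed in `run_config()`.

Profiles are clustered by K-means with `n_init = 10` restarts under a fixed
seed. **K defaults to 10**, matching the reported number of immune niches.
Because K-means cluster ids are arbitrary, niches are relabeled IN-0, IN-1,
... in descending cluster-size order (centroid coordinates break exact size
ties), which makes niche identity reproducible across runs; any original
niche numbering is itself arbitrary. Cells with zero
neighbors receive the reserved label "isolated" rather than polluting the
fit with zero vectors. Clustering is pooled across patients — required for
a niche id to mean the same thing in every patient.

Per-unit (ROI or patient) niche proportions are compared between responders
and non-responders with a two-sided Mann-Whitney test by default (Welch t
optional); Benjamini-Hochberg adjusted p values are always reported next to
raw ones, since the reference protocol works with raw *P* < 0.05 across
ten niches.

# Interaction graphs

Two cells interact when their centroid distance is **strictly below 15 um**
(ties excluded — with continuous coordinates exact 15.000 um pairs are
measure-zero, but the boundary convention is fixed and tested). Edges are
undirected, per-ROI, and each unordered type pair is counted once (an A-A
edge contributes once to the diagonal), so the matrix total under the "raw"
tag equals the edge count. Three normalizations are provided:

* `raw` — edge counts (used by the exact oracle tests);
* `per_cell` (default) — entry (a, b) divided by `min(n_a, n_b)`, with
  0/0 -> 0. The reference protocol leaves the normalization of
  "interaction intensity" unstated; min-count is an explicit assumption that bounds
  the entry by the pairing capacity of the rarer type and stops ROI size
  from dominating;
* `per_area` — per mm^2 of ROI area.

`interaction_permutation_null()` contextualizes raw counts with a standard
label-shuffle null (positions and hence the graph held fixed, labels
permuted within ROI), reporting per-entry mean, SD, and z.

# Response models

The feature table has exactly 29 columns for the 7-type panel: 7 cell-type
ratios, 7 densities (cells per mm^2), and the interaction intensities of the
15 unordered pairs among the 6 non-tumor types. The pair set is a design
decision: 15 = C(6,2) is the unique pair count matching the protocol's
number, but the exact pair list is not specified.

`fit_response_model()` repeats (default 100 times): a stratified 75/25
split; feature standardization fitted on training rows only; L1-regularized
logistic regression with the penalty chosen by 5-fold cross-validation on
the training set under the one-standard-error rule (about 20 path points);
AUC on the held-out rows. Two split modes exist:

* `grouping = "patient"` (default): no patient contributes ROIs to both
  sides of a split — this prevents within-patient leakage;
* `grouping = "roi"`: ROIs split independently, reproducing the literal
  "149 ROIs were split 75/25" protocol.

The defaults are deliberately conservative; the patient-grouped mode is the
honest benchmark, the ROI mode the literal one.

Survival classification dichotomizes patients at a time cutoff (defaults
9.3 months OS, 6.1 months PFS): time >= cutoff is the long class; an event
before the cutoff the short class; patients censored before the cutoff are
excluded with a message, since their class is unknown.

**Boruta.** No random-forest package is available in the supported
environment, so the importance backend is implemented in the package's
compiled code: a bootstrap forest with per-node `mtry` feature sampling and
Gini impurity-decrease importance (the forest only scores features; it never
predicts). Each Boruta iteration appends a permuted shadow copy of every
active feature, scores the joint set, and records a hit when a real feature
beats the *maximum* shadow importance; a two-sided exact binomial test on
hits (null probability 1/2) confirms or rejects at `alpha` (default 0.01,
so confirmation is impossible before iteration 7). Rejected features leave
the forest. Two behaviors to be aware of, both visible in the calibration
tests: the test is conditional on the realized dataset, so a noise column
that happens to correlate with the labels in-sample can legitimately be
confirmed (the null confirm rate is bounded by a few percent, not by
alpha); and borderline features can remain tentative indefinitely —
`resolve_tentative()` applies the standard rough fix (median importance vs
median shadow maximum). Permutation importance is not offered: without a
prediction path there is no out-of-bag error to permute against.

# Clinical statistics

`summarize_response()` and `ca199_decline()` are exact arithmetic with the
trial-report rounding convention (one decimal on percentages).
`km_estimate()` wraps the product-limit estimator with Greenwood variance
and log-log confidence intervals; the **median convention is the smallest
observed time with S(t) <= 0.5** (at an exact 0.5 plateau this returns the
plateau's start, not the midpoint some software reports). `logrank_test()`
is the standard two-group chi-square; with no events at all it returns
statistic 0, p = 1 by convention.

`simon_two_stage()` searches (r1, n1, r, n) exhaustively with exact binomial
stage probabilities, returning the optimal (minimum expected size under p0)
or minimax (minimum n) design meeting the attained type-I and power
constraints. Two ambiguities in the source protocol are surfaced rather than
resolved:

* "alpha 0.05 (both sides)" is ambiguous for a one-sided design problem;
  the calculator takes a one-sided alpha directly, so both `alpha = 0.05`
  and `alpha = 0.025` runs are one line each and can be compared with an
  externally specified plan (for instance, stop below 6/17 with 49 total).
* "terminate if the rate is less than 6/17" is interpreted as stop when
  stage-1 successes <= 5; `evaluate_two_stage()` accepts any (r1, n1, r, n),
  so the alternative reading is evaluable directly.

The calculator reports its own search result; it does not assert agreement
with any externally specified plan.

# The synthetic world

`simulate_cohort()` generates the world the analysis assumes, with planted
ground truth:

* **Patients**: 16 responders + 31 non-responders by default (the imaging
  cohort's scale), each with 1-3 ROIs drawn uniformly.
* **Tissue**: per ROI, a homogeneous Poisson background (default 3000
  cells/mm^2 over 1000 x 1000 um, i.e. ~3000 cells, inside the stated
  2000-10000 band) typed from a tumor-dominated mixture (70% tumor, sparse
  immune infiltrate).
* **Niches**: isotropic Gaussian blobs (radius parameter = 1 SD, default
  40 um, 150 cells per blob — dense aggregates several-fold above
  background, as tissue niches are). Two default archetypes: `in8_like`
  (DC 0.25, CTL 0.30, Th 0.25, PD-L1+ M 0.10, PD-L1- M 0.05, B 0.05) and
  `in3_like` (PD-L1- M 0.60, tumor 0.25, CTL 0.10, B 0.05). The 7-marker
  panel has no fibroblast channel, so the stroma-dominated non-responder
  niche is modeled as macrophage/tumor-dominated; with the 16-type panel a
  fibroblast archetype can be declared directly.
* **The planted effect**: blob counts per ROI are Poisson with expected
  rates (0.8 `in8_like`, 2 `in3_like` for both classes); responders'
  `in8_like` rate is multiplied by `effect_size` (default 4; 1 is the null
  world).
* **Clinical**: responses CR/PR for responders (5/95), SD/PD for
  non-responders (85/15); exponential OS/PFS with non-responder medians
  6/4 months and a hazard ratio of 2 in favor of responders; uniform
  administrative censoring on 12-36 months; log-normal CA19-9 baselines
  with response-dependent beta-distributed declines.
* **Markers**: signature row + Gaussian noise (SD `noise_sd`, default 0.5),
  truncated at zero.

A single integer seed drives every sub-stream through a documented splitting
scheme (`sub_seed`), so placement, typing, and clinical draws are
independently reproducible; the RNG is R's Mersenne-Twister.

**What the generator does *not* emulate** — and hence what a green test does
not establish: realistic tissue morphology (vessels, ducts, invasive
margins), marker spillover or autofluorescence, segmentation errors
(merged/split cells), anisotropic or nested niches, and spatial correlation
between clinical outcomes and tissue beyond the planted blob-rate and
hazard-rate effects. Recovery results say the pipeline finds what the model
plants; they are not evidence about real tissue.

**Niche-recovery ground truth.** For recovery scoring, the process label
("blob member" vs "background") is the wrong target: a background-process
cell lying inside a blob spatially belongs to that niche. The exported
`planted_niche_truth()` labels each cell with the archetype of the nearest
blob center within two blob radii; the planted-recovery test clusters with
K = archetypes + 1 (one slot for background tissue) and computes the
adjusted Rand index over cells inside blob footprints.

# Numerical conventions

* Neighbor search uses exact grid binning (bin width = radius); results are
  bit-identical to the O(n^2) distance matrix, which the suite verifies on
  dozens of random maps.
* Boundary conventions: neighborhoods are closed (<= r), interactions
  strict (< threshold), hotspot windows half-open on the grid.
* K-means restarts keep the lowest within-cluster sum of squares; niche
  relabeling breaks size ties on centroid coordinates.
* Degenerate inputs have defined behavior rather than errors where a
  convention exists: constant marker columns z-score to zero; zero-neighbor
  cells are "isolated"; identical comparison groups give p = 1; a map with
  no target cells yields an empty hotspot set with a warning; all-censored
  survival gives "median not reached".
* All stochastic functions take a seed and derive sub-stream seeds
  deterministically; repeated runs are byte-identical, which the pipeline
  test asserts on whole run directories.

# Known limitations

* Gating is cohort-relative; its accuracy depends on class balance and on
  every marker having a positive population (see above).
* The min-count interaction normalization is an assumption; comparisons on
  `raw` or `per_area` matrices may rank pairs differently on ROIs of very
  unequal size or composition.
* The Boruta backend uses impurity importance only; impurity importances
  are known to favor high-cardinality continuous features, which is
  immaterial here (all features continuous on comparable scales) but would
  matter for mixed-type tables.
* The survival generator is exponential with independent uniform censoring —
  sufficient to test the Kaplan-Meier/log-rank machinery, far simpler than
  clinical reality.
* `fit_survival_class_model()` discards censored-before-cutoff patients
  rather than weighting them (e.g. by inverse probability of censoring);
  with heavy early censoring the retained classes can be biased.
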