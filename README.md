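# spatialTME

Spatial analysis of the tumor-immune microenvironment (TME) from
multiplexed-imaging cell maps, built around a question from advanced
pancreatic cancer immunochemotherapy: does the *spatial organization* of
immune cells — not just their abundance — predict treatment response?

The package is written for analysts of segmented-cell tables (one row per
cell: ROI, patient, x/y centroid in microns, marker intensities or a type
label) plus per-patient clinical tables. It implements, end to end:

* **Phenotyping** — z-score marker normalization and nearest-signature
  (cosine) gating against a declared panel, with a post-lineage PD-L1 split
  and deterministic tie-breaking; CTL-rich hotspot window selection.
* **Immune niches** — for each cell *i*, the neighborhood profile
  `p_i[t] = #{ j : d(i,j) <= r, type(j) = t } / #{ j : d(i,j) <= r }`
  (default r = 50 um), clustered by K-means into K = 10 niches (IN-0 ...
  IN-9, relabeled by size for reproducibility), with per-ROI/per-patient
  niche proportions and Mann-Whitney / Welch group comparisons under
  Benjamini-Hochberg adjustment.
* **Cell-cell interactions** — the undirected graph connecting cells with
  centroid distance strictly below 15 um; per-ROI type-pair count matrices
  `I[a,b] = #edges joining a type-a and a type-b cell`, normalized by
  `min(n_a, n_b)` (default), raw, or per mm^2; a label-shuffle permutation
  null for z-scores.
* **Response models** — a 29-feature table per ROI (7 cell ratios +
  7 densities + 15 non-tumor pair interactions), repeated stratified 75/25
  splits (patient-grouped by default), L1-regularized logistic regression
  with cross-validated penalty (one-SE rule), held-out AUC distributions;
  Boruta all-relevant selection (shadow features, max-shadow hits, exact
  binomial decisions) over a compiled in-package random-forest importance
  backend; survival classification at a time cutoff.
* **Clinical statistics** — ORR/DCR response summaries, CA19-9 decline
  classification, Kaplan-Meier curves (median = first time S(t) <= 0.5,
  Greenwood/log-log CIs, landmark rates), two-group log-rank tests, and an
  exact-binomial Simon two-stage design search (optimal and minimax).
* **Synthetic cohorts** — a generator that plants known spatial effects
  (Gaussian niche blobs, a DC/CTL/Th-rich archetype enriched in responders
  by a configurable effect size) and clinical effects (exponential survival
  with a planted hazard ratio), so every stage can be validated against
  ground truth. See the vignette for the full stated world.

## Worked example

Simulate a small cohort with a planted responder effect, discover niches,
compare interactions, and fit the response model:

```r
library(spatialTME)

spec <- cohort_spec(n_responders = 8, n_nonresponders = 8,
                    bounds = c(500, 500), effect_size = 4, seed = 11)
sim <- simulate_cohort(spec)
sim$cell_map
#> cell_map: 38706 cells, 28 ROIs, 16 patients
#>   types: Tumor=16721 PDL1neg_M=6241 CTL=5403 Th=3797 DC=3305 B=1650 PDL1pos_M=1589

prof   <- neighborhood_profile(sim$cell_map, radius = 50)
niches <- fit_niches(prof, K = 4, seed = 1)
niches
#> niche_model: K = 4 | radius 50 um | inertia 737.197
#>  IN-0  IN-1  IN-2  IN-3
#> 12486 10400  8290  7530

graph <- build_interaction_graph(sim$cell_map, threshold = 15)
imats <- interaction_matrix(graph, sim$cell_map)   # min-count normalized
grp <- setNames(ifelse(sim$clinical$responder, "responder", "non-responder"),
                sim$clinical$patient_id)
rg  <- unname(grp[sub("_R\\d+$", "", names(imats$matrices))])
compare_interactions(imats, rg, pairs = list(c("CTL", "DC"), c("Th", "DC")),
                     ref = "responder")
#>   variable statistic        p    p_adj mean_diff direction
#> 1   CTL|DC       172 4.57e-04 0.000457     0.963         1
#> 2    Th|DC       181 8.75e-05 0.000175     0.893         1

feats <- assemble_features(sim$cell_map, imats, clinical = sim$clinical)
fit_response_model(feats, n_repeats = 25, seed = 7)
#> response_model: 25 repeated 0.75 splits, grouping = patient
#>   mean AUC: 0.9203  (SD 0.16 )
```

The interaction comparison flags the planted DC-CTL and DC-Th enrichment in
responders (positive direction = higher in responders, both surviving FDR
adjustment), and the held-out AUC distribution shows the planted effect size
4 is recoverable from 28 ROIs. Trial-level statistics work the same way:

```r
summarize_response(sim$clinical)
#> response_summary (n = 16): CR 0, PR 8, SD 7, PD 1
#>   ORR 50.0%  DCR 93.8%

simon_two_stage(0.35, 0.55, alpha = 0.05, beta = 0.2)
#> simon_design (optimal): stage 1 stop if <= 5/14; reject H0 if > 20/44
#>   p0 = 0.35, p1 = 0.55 | attained alpha 0.0458, power 0.8001
#>   PET(p0) = 0.6405, E[N|p0] = 24.78
```

`run_pipeline(run_config(seed = 1), cell_map, clinical, "out/")` chains all
stages into one reproducible run directory (intermediate CSVs, a log, and a
manifest); `inst/scripts/tme-pipeline.R` is a thin command-line wrapper with
`simulate`, `phenotype`, `run`, and `design` subcommands.

## Acceptance script

`scripts/acceptance.R` re-runs the full workflow from scratch against the
installed package: it simulates a 47-patient cohort (16 responders, 1-3 ROIs
per patient) with the default planted effect, executes the niche, interaction,
response-model and clinical stages under the given seed, prints the run's
headline outputs, and writes the results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/spatial-tme-analysis.Rmd`) documents the
models and their assumptions, every tunable parameter with units and
defaults, the synthetic world and what it does and does not emulate,
numerical conventions, and known limitations.
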