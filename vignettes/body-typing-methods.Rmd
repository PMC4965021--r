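---
title: "Two-stage SOM body typing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage SOM body typing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodysom)
```

## The problem

Modern 3D body scanners deliver on the order of 140 measures per person —
lengths, girths, two angles, weight, and derived indices. Across a cohort
these measures are massively redundant: girths move together, lengths move
together, and a handful of latent shape dimensions explains most of the
variation. `bodysom` implements a two-stage unsupervised pipeline for such
data:

1. **Feature stage.** A self-organizing map (SOM) is trained with the
   *measures* as items (each measure described by its profile across all
   participants). Watershed clusters on the map's U-matrix group correlated
   measures into a small number of **meta-measures**; each participant is
   then summarized by the per-cluster means of their Z-scored measures.
2. **Body stage.** A second SOM is trained with the *participants* as items,
   described by their meta-measure profiles. U-matrix watershed clusters of
   participants that exceed a minimum-size rule become **body types**,
   labelled `F*`/`M*`/`B*` by gender composition.

Around the two clustering stages sit the supporting analyses: subsampled
consensus clustering (cluster stability), stability-versus-cohort-size
curves, polar **bodygram** profiles, and body-map "stainings" by age, BMI,
WHtR, WHR and ABSI.

## Preprocessing

Raw tables contain missing values where the scanner software could not
derive a measure. Three filters run in a fixed order
(`filter_missing()`): participants missing more than 50% of measures are
dropped first; then measures missing in more than 5% of the *remaining*
participants; finally every remaining participant with any missing value.
The order matters — measure missing-fractions are computed only after
grossly incomplete participants are gone — and a regression test pins it.

Each measure is then divided by the participant's body height
(`height_normalize()`), assuming body shape scales linearly with stature,
and Z-normalized per measure across the cohort (`z_normalize_columns()`,
sample SD with denominator N−1; at cohort scale the N vs N−1 choice is
numerically immaterial but must be fixed for reproducibility). By default
*every* measure is height-normalized, including the two angles and weight;
`exempt_kinds = "angle"` offers the physically cleaner alternative. The
classical indices BMI = weight/height², WHR = waist/hip, WHtR =
waist/height and ABSI = waist/(BMI^(2/3)·height^(1/2)) are computed by
`compute_indices()` and can enter the feature table like any other column.

## SOM training

`som_train()` implements a batch SOM on a rectangular lattice. Codebook
vectors are initialized on the plane of the first two principal axes of the
data — deterministic given the data, which anchors map orientation across
runs — with a seeded random-sample fallback (`init = "sample"`) for
degenerate inputs or when the between-cluster structure needs more than two
axes. Each epoch assigns all items to their best-matching units (BMUs) and
replaces every codebook vector with the Gaussian-neighborhood-weighted mean
of the assigned items; the Gaussian is separable over lattice rows and
columns, keeping the update linear in map side length. The neighborhood
radius decays linearly from half the larger map side to a final radius over
100 epochs. Quantization error is logged per epoch; with a fixed small
radius the batch update is monotone (a property test asserts this).

Ties in the BMU search resolve to the lowest row-major unit index; all
randomness flows through explicit integer seeds, and a pipeline-level seed
fans out to stage seeds via `stage_seed()` so stages can be rerun in
isolation.

### The final radius: one schedule does not fit both stages

The two stages see very different geometry, and the package deliberately
uses different final radii:

* The **feature map** items (measures) form compact, widely separated
  groups. A tight final radius (1) lets the map converge onto them and the
  U-matrix shows deep basins split by tall ridges.
* The **body map** items (participants) fill a high-dimensional cloud: each
  body-type component has isotropic within-cloud spread across all
  meta-measure dimensions. A tightly converged 2-D codebook sheet *folds*
  into that within-cloud variation, and the folding noise in the U-matrix
  grows as large as the between-cloud ridges — the U-matrix inverts and
  watershed fails. `assign_body_types()` therefore defaults to a final
  radius of `max(width, height)/6`, keeping the sheet smooth inside clouds
  so that basins follow between-cloud structure. This is the single most
  consequential numerical choice in the package; the planted-structure
  recovery tests pin it.

## U-matrix watershed clustering

`distance_map()` gives each unit the mean Euclidean distance between its
codebook vector and its lattice neighbors (4-neighborhood by default,
8 configurable; border units average over existing neighbors).
`detect_clusters()` segments it: every unit descends to its lowest-valued
neighbor until a local minimum seeds a basin (ties to the lowest row-major
index); adjacent basins merge, shallowest ridge first, while the ridge
prominence — saddle height minus the higher of the two basin minima — is at
most θ times the map's dynamic range. θ defaults to 0.10 and is the one
knob of the cluster detection; the adjusted-Rand recovery tests pin the
default. A perfectly flat map merges into a single basin. Items inherit the
basin of their BMU; basins without items are background.

Clusters of measures with fewer than 2 members are dissolved
(`prune_singletons()`), mirroring the exclusion of singleton measures from
downstream analysis. Meta-measures are labelled "A", "B", … following
clockwise order of their member-BMU centroids around the map center,
starting at 12 o'clock, and each participant's meta-measure vector is the
arithmetic mean of the member measures' Z-scores
(`aggregate_meta_measures()`), then row-Z-normalized
(`z_normalize_rows()`) to remove additive offsets before body typing.

Body-type clusters must hold at least `ceil(0.01 × N)` participants. The
1% fraction generalizes the absolute floor used in cohort-scale work (85
participants at N ≈ 8,500); `min_count` reinstates an absolute floor when
wanted. "Mainly one gender" is quantified as a female (or male) fraction of
at least 0.8 — the reference analyses never quantify "virtually gender
specific", so the threshold is exposed and regression-pinned. Types are
numbered by descending size within each letter group.

## Consensus and stability

`subsampled_consensus()` draws sub-cohorts without replacement (a
`with_replacement` flag preserves the classical bootstrap) and reruns the
*full* clustering procedure — SOM training included — per iteration with a
derived seed. The consensus of an item pair is the fraction of runs in
which both were drawn and co-clustered; items left unassigned by a run
count as sampled but co-clustered with no one; pairs never co-sampled are
missing and excluded from averages. Two resampling modes reflect the two
stages: for the body map the clustered items (participants) are
subsampled; for the feature map all measures are reclustered on resampled
participant sub-cohorts (`resample = "features"`).

`consensus_stats()` computes the per-cluster intra-consensus m(k) relative
to a reference partition, the cluster-by-cluster inter-consensus, and the
unweighted mean ⟨m(k)⟩ (the reference notation does not specify weighting;
unweighted is the neutral reading). `consensus_dendrogram()` agglomerates
the reference clusters by single linkage on 1 − inter. `stability_vs_size()`
repeats the consensus analysis across sub-cohort sizes, tracing mean ± SD
of the per-run cluster count and ⟨m(k)⟩ — the question "how many clusters
can a cohort of this size resolve?".

## The synthetic cohort

No public raw cohort exists at desk scale, so `generate_cohort()` emulates
the statistical structure the analysis assumes, with ground truth for
recovery tests:

* ~140 measures: 13 correlated blocks (2–27 members, 129 total) plus 11
  pure-noise singleton measures;
* one latent factor per block; measures mix their block factor with
  independent noise so the within-block correlation hits its target (0.8
  by default);
* 15 body-type components on a gender-linked mixture (roughly 6 mostly
  female, 7 mostly male, 2 mixed); component centres sit at regular-simplex
  vertices scaled by `component_separation` — each component shifts its
  signature factor by about that many SD units. A regular simplex exists
  only for up to `n_blocks + 1` components; beyond that (including the
  15-in-13 default) centres fall back to seeded random unit directions
  with near-equal pairwise separations;
* gender-specific height (165/176 ± 7 cm) and weight (71/86 ± 14 kg)
  normals, ages uniform on 40–79, waist and hip as affine transforms of the
  first two latent factors so WHR and WHtR vary with component;
* every measure is multiplied by the participant's relative height, so the
  height normalization of the preprocessing is non-trivial;
* MCAR missingness at three levels — background (0.001 per cell), planted
  bad participants (0.5% of rows at rate 0.6) and 6 bad measures (rate
  0.08) — chosen so the three filters each remove something and the
  complete-case stage drops roughly a tenth of the cohort, matching the
  attrition profile of real scanner tables. The filters are count-based,
  so MCAR suffices to exercise them.

What the generator does **not** emulate: biomechanical coupling between
measures (girth–length anticorrelation arises in real bodies, not here),
measurement error structure of a scanner, non-European reference
populations, or any dependence of measures on age. Passing recovery tests
therefore shows the pipeline recovers *planted correlated-block and
mixture structure* at realistic noise levels — not that real cohorts
contain exactly 13 meta-measures or 15 body types.

## Problem sizes in tests and analyses

The packaged analyses run at desk scale: cohorts of 1,000–2,000
participants, a 20×20 or 30×30 feature map, a 40×40–60×60 body map, and
8–20 consensus iterations. Cohort-scale work uses 50×50 feature and
130×130 body maps with 100-fold consensus; all sizes are arguments.
Two consequences of the reduced scale are visible and expected: on the
30×30 feature map a few small measure blocks lose members to the singleton
exclusion (the block *partition* on assigned measures stays essentially
exact, ARI ≈ 1), and with 15 overlapping components at n = 2,000 only
7–11 body types resolve — the same cohort-size dependence the stability
curve demonstrates, with both the resolvable cluster count and ⟨m(k)⟩
non-decreasing in sub-cohort size.

## Degenerate inputs and numerical conventions

Zero-variance measure columns and constant meta-measure profiles abort
normalization with the offending names listed. Tertile boundaries use
midpoint-interpolated empirical quantiles (type 2), ties assigned to the
lower class. Modal stainings break frequency ties toward the lower value.
Bodygram axes sit at angles 2πi/K clockwise from 12 o'clock and the Z = 0
polygon is the cohort reference; "light"/"heavy" strata split at the
gender-specific median weight. Bodygrams display column-Z meta-measures,
while the body map clusters the additionally row-Z-normalized profiles —
both scales are available, and the choice is exposed where it matters.

## Known limitations

* The watershed θ and the body-map final radius are calibrated on planted
  isotropic mixtures; strongly anisotropic or nested cluster structure may
  need different settings.
* The minimum-saddle ridge definition merges two basins if even one
  low-valued corridor connects them; the wide-final-radius body map is the
  mitigation, not a cure.
* Map-size selection (`select_map_size()`) assumes the downstream cluster
  count rises to a plateau; on noisy curves it returns the largest
  candidate with `plateau_found = FALSE` rather than guessing.
* ⟨m(k)⟩ from 8–20 iterations carries Monte-Carlo noise of a few percent;
  cohort-scale conclusions should use 100-fold consensus as in the
  reference analyses.
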