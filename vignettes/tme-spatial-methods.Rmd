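---
title: "Methods: spatial tumor-microenvironment analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial tumor-microenvironment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmespatial)
```

# Scope and data model

`tmespatial` analyses segmented single-cell tables from multiplexed tissue
imaging of tissue-microarray (TMA) cohorts. A *region* is one circular tissue
core (default 0.6 mm diameter); one or more regions form a *sample* (one
biopsy); each sample belongs to a *patient* assigned to one molecular *group*
(`FGFR2`, `IDH1`, `WT` by default, configurable). Coordinates are micrometres
in a per-region frame — cores are physically separate pieces of tissue, so no
global slide frame exists and no quantity in the package ever crosses a
region boundary except by explicit aggregation.

The pipeline starts after segmentation and intensity extraction: reading
image formats and segmenting cells are out of scope by design.

# Cell phenotyping

## Scaling

Raw intensities are transformed per marker as `arcsinh(x / cofactor)` with
cofactor 5, the standard variance-stabilising transform for cytometry-type
intensity data (linear near zero, logarithmic for bright signal), then
z-scored across all cells so every marker contributes on a comparable scale.
Zero-variance markers are mapped to all-zeros with a warning instead of
producing NaNs.

## Clustering

Cells are clustered by Leiden community detection (modularity objective,
fixed seed) on the unweighted Euclidean k-nearest-neighbor graph of the
scaled matrix, with `k = 30`. Clustering operates on the kNN graph and never
on a 2-D embedding: embeddings distort densities, and the UMAP provided by
`embed_umap()` is for visualisation only.

The default resolution is 0.25. This was a genuinely open choice, settled
empirically: on unweighted kNN graphs of point clouds, modularity optima at
resolution 1.0 partition even a single homogeneous Gaussian blob of a few
hundred cells into several communities (geometric random graphs have genuine
modular substructure at that scale), so two 10-sigma-separated blobs come
back as seven clusters. At resolution 0.25 with `k = 30` the package returns
exactly one cluster for identical cells, exactly two for two well-separated
blobs (adjusted Rand index 1 with the generating labels, stable under row
permutation), and all six planted types of the synthetic cohort; a
Jaccard-weighted shared-nearest-neighbor graph did not repair resolution
1.0, so the simpler unweighted graph was kept. Users clustering very large or
very fine-structured panels may raise the resolution; the annotation step
tolerates over-partitioning because several clusters may map to one type.

## Annotation

Cluster annotation is automatic so that the pipeline is testable end to end.
The score of cluster $c$ for type $t$ with signature entries
$s_{tm} \in \{-1, 0, +1\}$ and cluster profile $\bar{z}_{cm}$ (mean scaled
expression) is

$$\mathrm{score}(c, t) = \frac{\sum_m s_{tm}\,\bar{z}_{cm}}{\#\{m : s_{tm} \neq 0\}},$$

and the cluster receives the argmax type if the best score reaches
`min_score = 0.1`, otherwise `"Unassigned"`; exact ties also go to
`"Unassigned"` with a warning. The packaged 14-type signature keeps two
explicit catch-all types (`HLA-DR+ other`, `PanCK+Vimentin+ mixed`) for
populations that marker panels of this kind cannot resolve further.

## Batch check

`region_mixing_entropy()` reports, per cluster, the Shannon entropy of its
region composition normalised by $\log(\#\text{regions})$: 1 means cells come
evenly from all regions, 0 means a single-region cluster (a batch-effect
signature). Clusters under `flag_below = 0.5` are flagged but never altered —
the package reports, it does not correct.

# Composition statistics

Per-sample proportions pool all of a sample's regions before dividing (the
sample, i.e. the patient biopsy, is the statistical unit throughout — this
was left open for composition and fixed to sample level for consistency with
the interaction aggregation). The immune-only level restricts the denominator
to a configurable immune type set; by construction,
`immune proportion × immune share = all-cells proportion` to 1e-9.

Group comparisons use Welch's unpaired t test (one group versus all other
samples pooled) or one-way fixed-effects ANOVA with Tukey–Kramer HSD
contrasts on the pooled mean squared error. Both are implemented from the
standard formulas and are cross-checked in the tests against base R's
`t.test`, `aov` and `TukeyHSD` to 1e-8; identical inputs return `t = 0`,
`F = 0`, `p = 1` exactly. P values are reported raw — many cell types are
tested and no multiplicity correction is applied by default, which mirrors
how such panels are conventionally screened; a Benjamini–Hochberg column is
included for readers who want it, but no headline flag uses it.

`cohort_summary()` produces the patient-level demographics table (count and
percentage per clinical bin per group, one decimal).
`icca_cohort_metadata()` reconstructs a 24-patient TMA cohort (7/9/8 patients
per group; 12 patients with one core, 10 with two, 2 with three = 38 regions)
with per-bin marginals matching the published demographics; the joint
assignment of bins to individual patients and of core counts to patients is
not published, so those are deterministic package choices and the object is
documented as synthetic.

# Voronoi-contact interactions

Cell–cell "contact" is formalised as a *capped* Voronoi tessellation: two
cells interact when (a) their Voronoi cells share a facet of positive length
after the tessellation is clipped to the region bounding box padded by the
cap, and (b) their centroid distance is at most `2 * cap`. The cap defaults
to 15 µm — roughly two cell radii of maximum separation — because an
uncapped tessellation manufactures arbitrarily long-range "contacts" across
sparse regions, and the padded bounding box (rather than a convex hull)
keeps hull cells' Voronoi cells finite. The contact graph is always a
subgraph of the Delaunay triangulation, and the edge set is monotone
non-decreasing in the cap. Coincident centroids (possible in real
segmentation exports) are resolved by a seeded 0.01 µm jitter — deterministic
and far below segmentation precision; cocircular degeneracies are handled by
the tessellation library and validated against two independent oracles in
the tests (a 0.25 µm rasterised tessellation, plus an exact
perpendicular-bisector construction that certifies the raster's sub-pixel
blind spots).

The interaction proportion from type $A$ to type $B$ in a sample is

$$P(A \to B) = \frac{\#\{A\text{ cells with} \geq 1\ B\text{ contact}\}}{\#\{A\text{ cells}\}},$$

with counts and denominators summed over the sample's regions before
dividing (never the mean of per-region proportions). The numerator is
cell-level, not edge-level: the platform description this reproduces is
ambiguous on that point, but only a cell-level numerator is bounded by the
from-type cell total that serves as the denominator. Two consequences are
inherited deliberately: the measure is *not* normalised for type frequency
(abundant partners inflate it), and it is asymmetric. From-types absent from
a sample yield missing values, excluded from group averages rather than
coerced to zero. Chord exports carry type frequencies on the nodes and the
mean of the two directed proportions on the arcs.

# Nearest-neighbor distances

For each cell of a from-type, the distance to the nearest to-type cell in
the same region, excluding itself for same-type queries; cells with no
eligible target emit no row (any finite sentinel would bias means, so
exclusion is the only unbiased choice). kd-trees accelerate the queries but
the correctness contract is the brute-force pairwise minimum, asserted
exactly in the tests.

Per-sample summaries pool all per-cell distances of the sample's regions —
equivalently a region-mean average weighted by from-cell counts. Group
heatmaps then average samples *unweighted* (each patient biopsy counts
once). Group comparisons run ANOVA + Tukey on the per-sample weighted means;
a per-cell mode exists behind `unit = "cell"` but is flagged as
anti-conservative, since it treats thousands of spatially correlated cells
as independent observations. Network exports symmetrise the two directed
means (both are retained) and exclude catch-all `"Other"` types.

# The synthetic cohort generator

The generator emulates the study design the analysis assumes so that every
downstream statistic can be validated against a known truth:

- **Design**: three groups with 7/9/8 patients, one sample per patient, and
  1–3 cores of 0.6 mm allocated by deterministic largest-remainder quota so
  the default distribution yields exactly 12 + 20 + 6 = 38 regions.
- **Counts**: per-region cell counts are Poisson; the default mean of 1500
  cells per core is a plausible density for a 0.6 mm core, but tests and the
  acceptance script use 150–400 cells per core — sizes chosen so the whole
  validation battery runs in minutes on one CPU while keeping every planted
  effect detectable.
- **Composition**: per-group mean vectors (defaults mirror the cohort-level
  breakdown: ~45% tumor, ~16% fibroblast, ~24% immune with macrophages then
  granulocytes the most prevalent immune types); per-sample vectors are
  Dirichlet draws around the group mean with concentration 150, chosen once
  as a moderate level of biological overdispersion (SD ≈ 0.02 for a
  0.10-share type).
- **Spatial structure**: tumor-type cells form Thomas clusters (Poisson
  parents in the disc, Gaussian offspring with σ = 30 µm resampled into the
  disc) — the simplest clustered point process with two interpretable
  parameters, matching the nested tumor morphology of such tissues; all
  other types are uniform in the disc.
- **Planted attraction**: each from-type cell is, with probability ρ, placed
  at a Gaussian offset (σ_attr, default 10 µm) from a uniformly chosen
  already-placed to-type cell, else uniform. Conditional placement was
  chosen over a Gibbs process because it is O(n), exactly seedable, and
  plants a monotone nearest-neighbor-distance signal (mean from→to NN
  distance ≈ 28/22/18/13 µm at ρ = 0/0.3/0.6/0.9 under the test geometry).
- **Spacing**: a 2 µm minimum inter-cell distance is enforced by resampling
  the later-placed point of any violating pair with its own placement
  mechanism, so coincident points cannot break the Voronoi dual.
- **Expression**: log-intensity = 1.5 + Δ·(signature entry) + N(0, σ);
  defaults Δ = 2, σ = 0.5 give cleanly separable but noisy types (Leiden ARI
  1.0, annotation accuracy 100% at n = 3000; Δ = 0 yields ARI ≈ 0,
  confirming no hallucinated structure).

Identical configurations and seeds give bit-identical cohorts.

What the generator does **not** emulate — and what passing tests therefore
cannot show about real data: segmentation errors and doublets, marker
spillover and background gradients, batch effects between runs, spatially
varying density inside a core, cell shapes and areas (cells are points), and
truly continuous phenotypes. Results on synthetic cohorts validate the
*machinery* (definitions, estimators, calibration, power at planted effect
sizes), not biological conclusions.

# Statistical calibration and power

The test battery verifies, at fixed seeds:

- type-I error of the one-vs-rest composition test on 1000 null cohorts
  (8 samples/group, 150 cells/core) inside the 95% binomial interval of the
  nominal 0.05;
- ≥80% power at a planted 0.12 composition shift (8 samples/group, 100
  seeds) and at a planted ρ = 0.8, σ = 10 µm attraction (100 seeds);
- the attracted group has the smallest group-mean NN distance in ≥90% of
  seeds and the planted pair is the dominant cross-type chord arc in ≥80%;
- geometry against the rasterised-Voronoi + exact-bisector oracles and
  brute-force nearest neighbors;
- Welch/ANOVA/Tukey against base R to 1e-8.

# Known limitations

- The interaction proportion confounds attraction with abundance (inherited
  by design); a frequency-normalised variant is a possible extension but is
  deliberately not the default.
- Automatic signature annotation depends on the signature's coverage;
  populations without informative markers land in catch-all types.
- The per-cell distance-comparison mode is anti-conservative and exists only
  for exploration.
- T-cell functional subsetting (regulatory/helper/double-negative) is out of
  scope: no tested marker recipe is available for it.
- Survival analysis is out of scope (it needs per-patient event dates that
  the metadata model does not carry).
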