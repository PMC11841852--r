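# tmespatial

Spatial analysis of the tumor microenvironment (TME) from highly multiplexed
tissue imaging. The package takes segmented single-cell tables from platforms
such as CODEX (one row per cell: centroid in µm, one intensity per antibody
marker) and carries them through the downstream analysis used to compare
molecularly defined tumor subgroups:

1. **Cell phenotyping** — arcsinh(x/5) + z-score scaling, Leiden community
   detection on the Euclidean kNN graph, cluster expression profiles, and
   automatic cluster annotation against a ±1 marker-signature matrix.
2. **Composition statistics** — per-sample cell-type proportions (cores of a
   sample pooled; the sample is the statistical unit), compared across groups
   with Welch's unpaired t test (one-vs-rest) or one-way ANOVA with Tukey HSD
   (three-group), plus a Table-1-style cohort summary.
3. **Cell–cell interactions** — per-region contact graphs from the capped
   Voronoi tessellation (contact = shared facet after clipping and centroid
   distance ≤ 2·cap), per-sample interaction proportions
   `P(A→B) = #{A cells with ≥1 B contact} / #{A cells}`, and chord-diagram
   exports.
4. **Nearest-neighbor distances** — for each "from" cell, the Euclidean
   distance to the closest "to"-type cell in the same core; per-sample
   weighted means, group mean-distance heatmaps, ANOVA/Tukey comparisons and
   network-plot exports.
5. **Synthetic cohorts** — a generator for tissue-microarray cohorts (three
   molecular groups, 1–3 circular 0.6 mm cores per patient, Thomas-process
   tumor nests, planted composition shifts and planted spatial attractions
   between chosen type pairs) with full ground truth, so every stage is
   testable end to end without external data.

The intended user is an analyst of multiplexed-imaging studies who has
segmented cell tables and per-region metadata and wants reproducible
phenotyping, composition and spatial statistics with explicit, tested
definitions of each quantity.

## Worked example

Simulate a study-like cohort (24 patients in groups FGFR2/IDH1/WT with a
granulocyte excess and a planted granulocyte→tumor attraction in the FGFR2
group), phenotype it, and test the group differences:

```r
library(tmespatial)

cfg <- icca_like_config(cells_per_core = 200, seed = 3)
sim <- simulate_cohort(cfg)
cells <- join_cells_metadata(sim$cells, sim$meta)

ph <- phenotype(cells, default_signature())
ph
#> Phenotype model: 7620 cells, 6 clusters
#>   k = 30  resolution = 0.25  cofactor = 5
#>   cell types:
#>     Tumor                      3353 ( 44.0%)
#>     Fibroblast                 1328 ( 17.4%)
#>     Granulocyte                1035 ( 13.6%)
#>     Macrophage                  995 ( 13.1%)
#>     CD4 T cell                  492 (  6.5%)
#>     CD8 T cell                  417 (  5.5%)

comp <- compute_composition(ph$cells, "all")
compare_groups(comp, sim$meta, "one-vs-rest", "FGFR2")[, c(1, 5, 6, 9)]
#>     cell_type mean_group  mean_rest      p.value
#> 1  CD4 T cell 0.05418482 0.06879620 1.036970e-01
#> 2  CD8 T cell 0.01442074 0.06409792 3.073353e-05
#> 3  Fibroblast 0.13046798 0.18783432 3.436150e-04
#> 4 Granulocyte 0.22068635 0.10435644 1.329764e-05
#> 5  Macrophage 0.15968475 0.12294964 8.768820e-03
#> 6       Tumor 0.42055536 0.45196547 1.030230e-01
```

The planted granulocyte enrichment (and the compensating CD8 depletion) is
recovered at p < 1e-4. The planted spatial attraction shows up as a collapsed
granulocyte→tumor nearest-neighbor distance in the FGFR2 group only:

```r
d <- nn_cross_distance(ph$cells, "Granulocyte", "Tumor")
s <- summarize_sample(d, sim$meta)
group_distance_heatmap(s, sim$meta)
#>   group   from_type to_type mean_distance n_samples
#> 1 FGFR2 Granulocyte   Tumor      16.96036         7
#> 2  IDH1 Granulocyte   Tumor      70.74489         9
#> 3    WT Granulocyte   Tumor      62.77297         8
```

`run_pipeline(pipeline_config(simulation = cfg))` runs all stages in one call
and writes typed cells, composition and comparison tables, contact-graph
edges, chord/network JSON exports, a manifest and a markdown report into an
output directory; identical config and seed give byte-identical outputs.

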