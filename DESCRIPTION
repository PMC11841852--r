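Package: tmespatial
Title: Spatial Tumor-Microenvironment Analysis for Multiplexed Tissue Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of segmented single-cell tables from highly
    multiplexed tissue imaging (CODEX and similar platforms): marker-based cell
    phenotyping via arcsinh scaling, kNN-graph Leiden clustering and
    signature-based cluster annotation; per-sample cell-type composition with
    Welch and ANOVA/Tukey group comparisons; Voronoi-contact cell-cell
    interaction proportions with chord-diagram exports; nearest-neighbor
    cross-type distance statistics with network exports; and a synthetic
    tissue-microarray cohort generator with planted composition shifts and
    spatial attractions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    deldir,
    RANN,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    uwot,
    mclust,
    withr
Config/testthat/edition: 3
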