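Package: chemgenmap
Title: Multiparametric Chemical-Genetic Interaction Mapping from High-Content Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for multiparametric chemical-genetic
    interaction analysis of image-based compound screens across isogenic cell
    lines. Includes synthetic-data generators for screen designs, two-channel
    well images, well-level feature tables with known ground truth, drug
    combination grids and compound annotations; nuclei and cell segmentation
    with per-cell feature extraction; generalized-log transformation, well
    quality control, replicate reproducibility and stepwise selection of
    non-redundant phenotypic features; median-polish estimation of compound x
    cell-line interaction coefficients with empirical-Bayes moderated t-tests
    and Benjamini-Hochberg false discovery rate control; interaction-profile
    correlation, complete-linkage clustering, chemical-genetic network
    construction and the ECDF-based resolution index; and Bliss-independence
    scoring of drug combinations plus a viability-corrected proteasome
    inhibition statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    igraph,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
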