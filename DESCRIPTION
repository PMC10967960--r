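Package: vitreoct
Title: Quantification of Vitreous Immune Cells from OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational analysis of vitreous immunity from optical
    coherence tomography (OCT) B-scan stacks. Segments the vitreous and
    the retinal pigment epithelium (RPE) from the axial intensity profile,
    computes the VIT/RPE relative intensity as a turbidity proxy, detects
    hyperreflective vitreous opacities after robust speckle-background
    suppression, characterises each opacity by area, mean intensity,
    eccentricity and orientation, classifies opacities into a four-class
    size taxonomy (isolated cells, non-activated cells, activated cells,
    cell complexes), and aggregates per-eye longitudinal summaries with
    cohort-level statistics (Kolmogorov-Smirnov normality, one-way ANOVA
    with Bonferroni-adjusted pairwise comparisons, lagged Pearson
    correlations). Includes a synthetic OCT phantom generator with full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    readr,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
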