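Package: thalnet
Title: Thalamic Nuclei Connectivity and Volume Analysis for Pediatric
    Focal Epilepsy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for group-level analysis of thalamic nuclei
    in pediatric focal epilepsy: empirical-Bayes (ComBat-style) scanner
    harmonization of volume and functional-connectivity features,
    density-thresholded graph construction with node-strength area under
    the curve as the hubness statistic, normative Z-scoring of volumes and
    connectivity against a control cohort with ipsilateral/contralateral
    relabeling to the seizure focus, and a statistical battery of mixed
    repeated-measures ANOVAs (multivariate approach), planned t-tests with
    Bonferroni correction and effect sizes, and edgewise group t-maps.
    Includes a synthetic cohort generator that emulates THOMAS-style
    thalamic volumes and CONN-style Pearson connectivity matrices with
    configurable planted effects, so the full pipeline is testable without
    patient imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    car,
    igraph,
    sva,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
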