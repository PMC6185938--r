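Package: cilimetry
Title: Primary Cilium Morphometry from Multi-Channel Fluorescence Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segmentation and morphometry of primary cilia and nuclei in
    multi-channel fluorescence micrographs of retinal pigment epithelium and
    retinal organoid sections. Implements hysteresis dual-threshold
    segmentation, size-based noise removal, distance-transform watershed
    splitting of touching objects, skeleton-based cilium length estimation,
    per-field ciliation incidence, and group-level statistics (mean +/- SEM,
    one-way ANOVA, Dunnett's post hoc test versus a control group). A
    synthetic-micrograph simulator with per-object ground truth provides a
    validation surface for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    mvtnorm,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    multcomp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
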