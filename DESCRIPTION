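Package: edcprofiler
Title: High-Content Phenotypic Profiling of Dopaminergic Neurons Exposed to
    Endocrine Disruptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, simulation-driven re-implementation of a
    high-content-imaging analysis that detects endocrine-disruptor-induced
    phenotypic changes in human midbrain dopaminergic neurons. Provides a
    synthetic 384-well plate-image generator with ground truth; compartment
    segmentation (nucleus, cell, cytoplasm, membrane) with a viability rule
    and neurite skeleton morphometry; a fixed 126-feature phenotypic
    catalogue (shape, intensity, GLCM texture, context); robust-scaled
    cosine-distance profile clustering and 2-D embedding; treated-versus-
    control well classification with linear discriminant and gradient
    boosted trees including feature importances; and per-compound
    dose-response statistics (control normalization, one-way ANOVA, Tukey
    post-hoc significance tiers).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    MASS,
    xgboost,
    uwot,
    ape,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    arrow,
    ggplot2,
    knitr,
    rmarkdown
LinkingTo: Rcpp
VignetteBuilder: knitr
Config/testthat/edition: 3
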