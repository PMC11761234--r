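Package: faceasym
Title: Landmark-Based Quantification of 3D Soft-Tissue Facial Asymmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying bilateral asymmetry of the facial soft
    tissue from triangulated 3D surface scans. Implements a spatial-angle
    wireframe template built from named craniofacial landmarks, with an
    Angle Asymmetry Index and three-level severity grading per facial
    region and axis; a mirroring-and-overlapping deviation analysis
    (midsagittal reflection, trimmed iterative-closest-point rigid
    alignment, per-vertex point-to-surface deviations with axis
    decomposition); region-of-interest partitioning of the face from
    landmark-derived boundaries; concordance statistics between the two
    methods (recognition rates, consistency rates, Cohen's kappa); and a
    deterministic generator of symmetric synthetic faces with planted,
    region-localized asymmetry for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    xml2,
    yaml,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
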