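Package: rehohub
Title: Local Functional-Connectivity Hubs from Resting-State fMRI via
    Regional Homogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes regional homogeneity (ReHo, Kendall's coefficient of
    concordance over 3x3x3 voxel neighbourhoods) from preprocessed 4D BOLD
    volumes, extracts high-ReHo clusters (HRCs) by percentile thresholding
    with an optional grey-matter constraint, characterizes their size
    distribution with logarithmic binning and power-law tail regression,
    and runs longitudinal two-group statistics (paired and two-sample
    tests, mixed Group-by-Threshold ANOVA, confound residualization,
    Benjamini-Hochberg FDR) on the resulting cluster metrics. Includes a
    synthetic two-group, two-timepoint cohort generator with planted
    locally coherent patches whose sizes follow a truncated power law, so
    the whole pipeline is testable end to end without external imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    generics,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
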