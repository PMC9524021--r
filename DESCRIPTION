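Package: dccmst
Title: Time-Varying Brain Networks via DCC-GARCH and Minimum Spanning Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates time-resolved functional connectivity between regions
    of interest with the bivariate dynamic conditional correlation (DCC)
    GARCH model, builds a minimum spanning tree of the connectivity graph at
    every time point, computes node-level and network-level tree parameters
    and their per-subject temporal means and variances, and provides
    covariate-adjusted group comparisons with false-discovery-rate control
    together with covariate-adjusted symptom-severity correlations. A
    synthetic cohort generator with known DCC-GARCH ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
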