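Package: rdhtools
Title: Resource Dispersion Hypothesis Analysis for Free-Ranging Dog Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing the Resource Dispersion Hypothesis in
    free-ranging dog populations: a food-source scoring scheme with
    area-standardized resource and dog densities for census polygons;
    territory-level spatial statistics (patch richness, resource
    heterogeneity, mean pairwise resource dispersion); Gamma log-link
    regression models for dog density, territory size and group size with
    rate ratios and likelihood-ratio tests; Gamma mixed models with a
    group random intercept and an optional season-specific dispersion
    submodel; two-sample power and Mann-Whitney AUC equivalences for
    sensitivity analysis; and a synthetic landscape generator that
    emulates the census and territory study designs so every stage of the
    pipeline can be validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    geosphere
Config/testthat/edition: 3
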