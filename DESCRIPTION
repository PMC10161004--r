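Package: forestcti
Title: Community Temperature Indices and Thermophilization Analysis for
    Repeat-Census Forest Inventories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying thermophilization (the compositional shift
    of tree communities toward warm-adapted species) from repeat-census forest
    inventory data. Estimates species temperature indices from occurrence
    records by three methods (simple niche mean, modeled niche mean, modeled
    niche optimum), computes basal-area-weighted community temperature indices
    per subplot, decomposes their change into counterfactual mortality, growth
    and recruitment components, derives climatic and topographic predictors
    (15-year sliding-window climate changes, annual climatic water deficit,
    topographic heat load), and fits a hierarchical Bayesian regression of
    community temperature index over time with subplot random effects and a
    Matern spatial Gaussian field over plots. A synthetic-data generator
    emulating a forest-inventory sampling design makes the full pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mgcv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
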