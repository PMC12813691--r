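Package: dietbreadth
Title: Diet-Breadth Analysis of Multi-Marker Metabarcoding Data
Version: 0.1.0
Authors@R:
    person("Diet Breadth", "Maintainers", email = "maintainers@dietbreadth.org",
           role = c("aut", "cre"))
Description: Downstream analysis of dietary (gut-content) metabarcoding
    detection tables for omnivorous arthropods. Implements rule-based
    post-classification filters (conspecific self-host masking,
    negative-control thresholds, singleton and relative-read-abundance
    cutoffs), multi-marker taxon consolidation that merges less resolved
    lineages into compatible higher-resolved ones, descriptive diet metrics
    (relative read abundance, frequency of occurrence, richness, Shannon
    diversity, period summaries, rank-resolution profiles, co-occurrence),
    and the coefficient of omnivory CO = P/(P + Z) with stratified bootstrap
    confidence intervals and a month-constrained permutation test for sex
    differences. A synthetic cohort generator with known ground truth makes
    every stage testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
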