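Package: dysbionet
Title: Dysbiosis Scoring and Immune-Microbe Association Networks for
    Longitudinal HIV Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for downstream microbiome-immunology analysis
    of two-timepoint, multi-cohort amplicon studies: cohort exclusion cascades
    and viremia labeling, rarefaction and prevalence filtering, Shannon
    entropy, weighted UniFrac beta diversity with principal coordinates
    analysis and biplots, strata-restricted PERMANOVA, reference-based
    dysbiosis scoring against healthy controls with delta-versus-baseline
    regressions, rank-based immune group comparisons, cluster-robust
    longitudinal linear models, backward-stepwise predictive models, and an
    immune-microbe association network built from per-pair interaction
    regressions passed through a five-criterion filter cascade (FDR on the
    overall F, adjusted R-squared, slope and interaction tests, and DFFITS
    influence screening). Includes a synthetic cohort generator with planted
    microbe-to-immune effects so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    biomformat,
    phyloseq,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
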