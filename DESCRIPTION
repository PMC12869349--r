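Package: tmeco
Title: Compositional Immune-Ecotype Analysis of Tumour Microenvironments
Version: 0.1.0
Authors@R:
    person("TME", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for classifying tumour
    microenvironments by their cellular composition. Provides cell-level
    quality-control filters (minimum gene count, per-sample robust
    median-minus-3-MAD thresholds, mitochondrial fraction), sample-by-subtype
    composition matrices with per-subtype standardisation, ecotype inference by
    Ward (ward.D2) hierarchical clustering, Pearson-residual enrichment of cell
    subsets across clinical groups, binned-control module scores and
    single-sample GSEA for signature scoring of bulk cohorts, Kaplan-Meier /
    log-rank survival analysis with maximally selected cutpoint stratification,
    and a seeded Dirichlet-multinomial cohort simulator that emulates the data
    structure every stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
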