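Package: airwaysig
Title: Airway Gene-Expression Signature Scoring and Biomarker Statistics for
    Randomized Chemoprevention Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transferring gene-expression signature scores from
    reference datasets onto study samples via empirical-Bayes batch
    harmonization and principal-component projection, for gene-wise moderated
    differential expression with a consensus within-subject correlation, for
    pre-ranked gene-set enrichment and per-sample gene-set scoring, and for
    urinary analyte change statistics in two-arm, three-timepoint trial
    designs. Includes a synthetic-data generator that emulates the full trial
    structure (subject random effects, batches, RNA-quality covariates,
    treatment-by-time effects, and matched analyte measurements) so the whole
    pipeline can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    sva,
    fgsea,
    jsonlite
Config/testthat/edition: 3
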