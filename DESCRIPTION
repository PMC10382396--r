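Package: mcscore
Title: Multicentre Consensus Scoring for Cross-Centre Agreement in
    Phenotyping Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Computes a global consensus score that aggregates per-centre
    FDR-corrected p-values (q-values), standardised effect sizes and effect
    directionality from multicentre studies into a single agreement
    statistic, with a decision rule on its negative log.  Includes the full
    pipeline from raw per-animal measurements (within-centre
    standardisation, a sex + body-weight model with a batch random effect,
    Benjamini-Hochberg correction) to per-trait consensus decisions, two
    comparison baselines (the all-centres-agree rule and DerSimonian-Laird
    random-effects meta-analysis with Cochran's Q heterogeneity test), and
    a seeded synthetic multicentre data generator emulating the structure
    of consortium haematology screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
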