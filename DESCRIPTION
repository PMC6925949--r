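Package: epivar
Title: Variant Interpretation for Gene-Panel Screens of Non-Familial Epilepsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for interpreting annotated whole-exome
    variant calls against a 178-gene epilepsy panel: a six-step filter
    cascade (read depth, protein-disrupting consequence, panel membership,
    population allele frequency, an ensemble deleteriousness vote, and
    reconciliation of ClinVar/HGMD assertions), case-control odds ratios
    with Woolf confidence intervals driving the ACMG PS4 criterion, a full
    ACMG/AMP evidence-combination engine producing the five-class
    pathogenicity verdict, and cohort-level diagnostic-yield analytics
    (onset-age strata, drug-response groups, recessive-heterozygote
    exclusion, compound-heterozygote detection). Includes a synthetic-cohort
    generator with known ground truth and machine-readable fixtures of the
    published classification and cohort tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
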