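Package: stromasig
Title: Stromal Hypoxia Protein Signatures: Derivation, Scoring and Survival Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for deriving a stromal hypoxia protein signature from
    cell-line secretome and microdissected tumor-compartment proteomics, and for
    evaluating it in expression cohorts. Implements Perseus-style valid-value
    filtering, downshifted-normal imputation of missing-not-at-random intensities
    and two-sample Student's t tests; set-logic signature derivation (hypoxia-
    increased secretome proteins intersected with stroma-exclusive subtype
    differences); max-probe collapsing, summed mean-centered signature scoring and
    quartile stratification; Kaplan-Meier, log-rank and Cox survival evaluation with
    a treatment-interaction test; a random-selection permutation test of signature
    uniqueness; a greedy leave-one-out signature reduction; and seeded synthetic
    generators for secretome, paired-compartment tissue and survival-cohort data
    with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
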