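Package: aimassign
Title: Genotype QC, Marker Independence Filtering and Likelihood-Based
    Ancestry Assignment for AIM Panels
Version: 0.1.0
Authors@R: person("Forensic", "Genomics Tools", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for biogeographic ancestry investigations
    with ancestry informative marker (AIM) panels typed by amplicon
    sequencing. Converts per-nucleotide read counts into quality-controlled
    genotype calls (read-depth, heterozygote-balance and noise criteria),
    establishes marker independence via exact Hardy-Weinberg and linkage
    disequilibrium tests with Bonferroni correction and performance-based
    pruning, and assigns profiles to reference meta-populations with a
    standardized log-likelihood (z-score) outlier gate, leave-one-out
    cross-validation, likelihood-ratio evidence weights and a three-way
    Accepted/Ambiguous/Rejected classification. Includes a Balding-Nichols
    synthetic-data generator (differentiated populations, admixture, and an
    over-dispersed read-count layer) so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
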