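Package: rxminer
Title: Association Rule Mining and Guideline Audit of NSAID and
    Gastro-Protective Co-Prescriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-visit drug transactions from outpatient prescription
    records, mines co-prescription patterns with a from-scratch Apriori
    frequent-itemset engine (support, confidence and lift computed on exact
    integer counts), and audits flagged NSAID / gastro-protective-agent
    combinations against clinical practice guideline criteria (GORD diagnosis
    for H2-receptor antagonist + proton pump inhibitor use; age >= 60, GI
    complication or aspirin co-therapy for COX-2 inhibitor + PPI use).
    Includes a synthetic outpatient-cohort generator with tunable pairwise
    co-prescription structure and deterministic fixture builders for
    reproducing published worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
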