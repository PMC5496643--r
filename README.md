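# rxminer

Association-rule mining and guideline auditing of NSAID /
gastro-protective-agent co-prescription in outpatient prescription data.

## The problem

NSAIDs are routinely co-prescribed with gastro-protective agents (proton
pump inhibitors, H2-receptor antagonists), but two combinations are
guideline-restricted: an **H2RA together with a PPI** is indicated only for
gastro-oesophageal reflux disease (GORD), and a **COX-2 inhibitor together
with a PPI** only for patients at high GI risk — aged ≥ 60, with a GI
complication (ICD-10 K20–K29.9, K30–K38.9, K90–K93.8), or on aspirin.
`rxminer` is for pharmacoepidemiologists and drug-utilization-review teams
who want to screen prescription databases for these patterns and quantify
how often they are guideline-discordant.

## The method

Each patient-day of prescribing is a *transaction*: the set of 4-character
drug stems (e.g. `IBUP` for every ibuprofen strength and form) dispensed to
one patient on one day, restricted to the audited ATC classes (A02A, A02B,
M01A) and to days with at least two distinct stems. For disjoint stem sets
X, Y the package mines rules X ⇒ Y with the Apriori algorithm and reports

- support(X ⇒ Y) = P(X ∪ Y),
- confidence(X ⇒ Y) = P(Y | X),
- lift(X ⇒ Y) = P(X,Y) / (P(X)·P(Y)) — 1 means independence, > 1 positive
  association,

all computed on exact integer counts and rounded half-away-from-zero only
for display. Flagged visits are then audited: H2RA+PPI visits are
concordant iff a K21-prefix diagnosis is coded; COX-2+PPI visits are
discordant iff the patient is under 60 with no GI-complication diagnosis
and no aspirin exposure. A synthetic-cohort generator
(`generate_cohort()`) and deterministic fixture builders make the whole
analysis reproducible without access to patient-level data.

## Worked example

Mine the packaged demonstration transaction set (6,168 two-item visits) and
audit an H2RA+PPI fixture:

```r
library(rxminer)

txns <- make_demo_fixture()
rules <- mine_rules(txns, min_support = 0.01, min_confidence = 0.5)
head(format_rules(rules), 4)
#>   rule_no  lhs  rhs support confidence   lift support_count
#> 1       1 ANTC OMPZ  0.0113     0.5833 1.0903            70
#> 2       2 ARCX OMPZ  0.0113     0.5833 1.0903            70
#> 3       3 ASA. OMPZ  0.0113     0.5833 1.0903            70
#> 4       4 ASPT OMPZ  0.0113     0.5833 1.0903            70

fx <- make_audit_fixture(demo_h2ra_audit_spec())
f  <- find_h2ra_ppi_visits(fx$txns, fx$contexts)
summarize_audit(f)$tables$gord
#>   category count percent
#> 1     GORD   222    65.3
#> 2 non-GORD   118    34.7
```

Twelve rules pass the 1% support / 50% confidence thresholds on this
fixture (`nrow(rules)` is 12): each rule's `support` is the fraction of the
6,168 visits containing both drugs, `confidence` the probability of the
consequent given the antecedent (e.g. 58.33% of visits with an ANTC-stem
antacid also carry omeprazole), and `lift` the ratio of observed to
expected co-occurrence. In the audit table, 118 of 340 ranitidine +
omeprazole visits (34.7%) lack a GORD diagnosis and are therefore
guideline-discordant.

For end-to-end use on CSV inputs (`prescriptions.csv`, `diagnoses.csv`,
`patients.csv` — schemas in `?pipeline_config`), `run_pipeline()` executes
ETL → mining → audit and writes `transactions.jsonl`, `rules.csv`,
`findings.csv`, `summary.csv` and a checksummed `manifest.json`.

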