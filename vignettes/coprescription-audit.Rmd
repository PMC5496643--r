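---
title: "Mining and auditing NSAID / gastro-protective co-prescription patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and auditing NSAID / gastro-protective co-prescription patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxminer)
```

## The problem

Non-steroidal anti-inflammatory drugs (NSAIDs) irritate the upper
gastrointestinal tract, so gastro-protective agents — proton pump inhibitors
(PPIs) and histamine H2-receptor antagonists (H2RAs) — are commonly
co-prescribed with them. Clinical practice guidelines restrict two specific
combinations:

* **H2RA + PPI** together is indicated only for gastro-oesophageal reflux
  disease (GORD, ICD-10 K21.x).
* **COX-2 inhibitor + PPI** is indicated only for patients at high GI risk:
  aged 60 or over, with a GI complication, or on antiplatelet therapy
  (aspirin).

Prescription databases are large enough that such patterns cannot be audited
by hand. `rxminer` treats each patient-day of prescribing as a *transaction*
— the set of drug stems dispensed to one patient on one day — and mines
association rules over those transactions with the Apriori algorithm, then
audits the flagged visits against the guideline criteria.

## From prescription rows to transactions

Raw prescription rows carry a hospital drug code whose first four characters
identify the compound (`IBUP1T-`, `IBUP2T-` and `IBUP-S-` are all
ibuprofen). `build_transactions()`:

1. normalizes each code to its 4-character stem;
2. keeps only stems in the audited ATC classes — antacids (A02A),
   peptic-ulcer/GORD drugs (A02B) and NSAIDs including COX-2 inhibitors
   (M01A) — via the packaged catalog (`load_catalog()`);
3. groups rows into visits keyed by `patient_id|date` (a patient-day);
4. deduplicates stems within a visit, so two strengths of one drug count
   once;
5. drops visits with fewer than two distinct stems: a single-drug visit
   carries no co-prescription information.

Retained transactions plus omitted patient-days always equal the distinct
patient-days in the input, so the filter is auditable from the pipeline's
stage counts. In routine outpatient data the overwhelming majority of
patient-days (around 95%) are single-drug and fall out here.

## The association rule model

Let $P = \{P_1, \dots, P_n\}$ be the retained transactions and $X$, $Y$
disjoint sets of drug stems. For the rule $X \Rightarrow Y$:

$$\mathrm{support}(X \Rightarrow Y) = P(X \cup Y), \qquad
  \mathrm{confidence}(X \Rightarrow Y) = P(Y \mid X), \qquad
  \mathrm{lift}(X \Rightarrow Y) = \frac{P(X, Y)}{P(X)\,P(Y)}.$$

Lift below, at and above 1 indicates negative, absent and positive
association. Support and lift are symmetric in rule direction; confidence is
not, so both directions of a pair are reported as distinct rules. No
multiple-testing adjustment is applied: the statistics are descriptive
screening quantities, not hypothesis tests.

`frequent_itemsets()` implements the classical level-wise Apriori search:
frequent 1-itemsets first, then candidate $k$-itemsets joined from frequent
$(k-1)$-itemsets and pruned by the anti-monotonicity of support, with
support counted on transaction-id lists. `derive_rules()` emits the ordered
bipartitions of each frequent itemset and filters by confidence.
`brute_force_rules()` is an independent oracle — exhaustive subset
enumeration, feasible up to 12 distinct items — kept solely so the test
suite can verify the Apriori path is exactly equivalent on randomized
instances.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_support` | 0.01 | minimum fraction of transactions containing the rule's items |
| `min_confidence` | 0.50 | minimum $P(Y \mid X)$ |
| `max_rule_items` | 2 | rule size cap; 2 restricts to single-item pairs, the shape used in co-prescription screening |
| `aspirin_window_days` | 0 | look-back for aspirin co-therapy (same-day by default) |

The 1% / 50% defaults are the thresholds at which co-prescription screening
of this kind typically starts; at pair level they mean "at least 1% of
multi-drug visits contain the pair, and the consequent follows the
antecedent at least half the time".

### Numerical choices

All mining statistics are ratios of integer counts, and several published
worked values are reproducible only under count-exact arithmetic. The
package therefore:

* keeps counts as integers end to end and forms proportions only on output;
* rounds displayed statistics **half-away-from-zero** via integer division
  (`round_ratio()`), 4 decimals for rule statistics and 1 for audit
  percentages, avoiding floating-point boundary artifacts;
* applies `min_support` as `count >= ceiling(min_support * n)` so the
  boundary case is included;
* orders rules by descending lift, then descending support, then
  lexicographic antecedent — a total order, so output is deterministic;
* sorts itemsets and transactions canonically, so mining is invariant to
  input row order.

## The guideline audit

`find_h2ra_ppi_visits()` flags transactions containing at least one H2RA
stem and one PPI stem; the visit is concordant iff a K21-prefix (GORD)
diagnosis is coded. `find_cox2_ppi_visits()` flags COX-2 + PPI visits; the
visit is discordant iff the patient is under 60 *and* has no GI-complication
diagnosis *and* no aspirin exposure. GI complications are the inclusive
ICD-10 ranges K20–K29.9, K30–K38.9 and K90–K93.8, tested dot-stripped with
`icd_in_ranges()`. Findings also carry same-meal and same-clinic flags
derived from each prescription's parsed dose/frequency code
(`parse_dose_freq()`: quantity, CAP/TAB, AM/PM/BID, residue kept verbatim).

Design choices that were genuinely open:

* **GORD definition.** GORD is ICD-10 prefix K21 ({K21, K210, K219}).
  Published groupings of this audit are internally inconsistent about one
  gastric-ulcer code; the K21-prefix rule is the clinically defensible
  definition and reproduces the GORD/non-GORD split exactly.
* **Age bands.** The summary uses ≥60 / 50–59 / <50. Published category
  labels print "<40" for the lowest band, but the three printed counts only
  partition the total if the band is <50; the implementation follows the
  arithmetic.
* **Aspirin look-back.** No look-back window is stated in the source
  material, so the default is same-day co-prescription, configurable in
  days.
* **Missing context.** Flagged visits without demographic context default
  to discordant but are excluded from percentage denominators and reported
  separately; no imputation is attempted.
* **Representative diagnosis.** For the diagnosis frequency table each
  visit is represented by its GORD code if any, else its first GI-range
  code, else "none"; visits with several GI codes are counted once.

## The synthetic cohort and fixtures

Real hospital prescription data cannot be redistributed, so
`generate_cohort()` emulates the statistical structure the analysis
assumes. Its defaults are the descriptive statistics of the target
outpatient population: mean age 48.4 (SD 21.4) years, 34% male, 4.7 (SD
4.4) visits per person-year, 1.80% background GI-complication coding and
0.74% arthritis coding. Per-visit drug sets are independent Bernoulli draws
from configurable prevalences; a *pairwise boost* multiplies a pair's joint
probability to `boost × p_x × p_y`, implemented by drawing the second item
conditionally on the first. This makes lift analytic: the mined lift of a
boosted pair is a consistent estimate of the boost, which the test suite
verifies within three Monte-Carlo standard errors on cohorts of more than
50,000 visits. Visit counts follow a negative binomial matched to the
visit-rate mean and SD; GI diagnoses are attached with elevated probability
(default 0.25, a value chosen once as a plausible confounding-by-indication
strength) at visits carrying a gastro-protective drug.

The generator emulates marginal demographics, visit-rate dispersion and
pairwise co-prescription structure. It does **not** model temporal
autocorrelation across a patient's visits, refill behavior, physician-level
prescribing habits, or higher-order (3-way and above) drug associations —
so green tests demonstrate correctness of the machinery under the stated
generative model, not fidelity to any particular hospital's data.

Three deterministic fixture builders reconstruct published worked numbers
exactly:

* `invert_printed_rule()` recovers the integer counts behind 4-dp rounded
  statistics by exhaustive search, and *documents* entries that admit no
  integer solution (e.g. a printed pair support of 0.0552 at n = 6,168 —
  340/6168 rounds to 0.0551 and 341/6168 to 0.0553 — and printed lift
  values generally) rather than hiding them.
* `make_pair_fixture()` realizes exact joint/marginal counts, padding with
  filler items kept strictly below the support threshold so no filler
  survives mining.
* `make_demo_fixture()` is a block design over 6,168 two-item transactions
  yielding exactly 12 single-item rules at the 1% / 50% thresholds;
  `make_audit_fixture()` expands category-cell specifications
  (`demo_h2ra_audit_spec()`, `demo_cox2_audit_spec()`) into transactions
  plus contexts reproducing the audit tables (340 H2RA+PPI visits of which
  118 non-GORD; 828 COX-2+PPI visits of which 295 discordant and 141 with a
  GI complication).

A note on scope: in the published 12-rule table, the two within-class rules
imply a different omeprazole marginal than the ten between-class rules, so
no single transaction set reproduces every row at once — the within-class
and between-class analyses evidently used different transaction subsets.
The engine therefore mines whatever transaction scope the caller supplies,
and the fixtures reconstruct each worked statistic on its own subset.

## Problem sizes in the test suite

The suite exercises the Apriori/brute-force equivalence on randomized
instances of up to 12 items and 200 transactions; the filter worked example
on 134,285 synthetic patient-days; lift calibration (independence and boost
recovery) on generated cohorts of ~56,000 visits; and the fixture
reconstructions at n = 6,168. These sizes were chosen to make every
statistical check well-powered while keeping the whole suite to a few tens
of seconds on one core.

## Limitations

* Rule statistics are descriptive; no significance testing or
  multiple-testing control is provided by design.
* The audit criteria are deliberately minimal (age, GI diagnosis ranges,
  aspirin, GORD coding); dose-appropriateness and drug–drug interaction
  scoring beyond same-meal overlap are out of scope.
* Diagnosis coding quality bounds the audit: a GI complication that was
  never coded is invisible to `icd_in_ranges()`.
* The generator's independence assumptions mean calibration results carry
  over to real data only insofar as the model holds.

## Pipeline

`run_pipeline()` wires the stages (ETL → mine → audit → report) from three
CSV inputs, writes `transactions.jsonl`, `rules.csv`, `findings.csv`,
`summary.csv` and a checksummed `manifest.json`, logs stage in/out counts so
filter behaviour is auditable, and is byte-identical on re-run with the
same inputs and configuration.
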