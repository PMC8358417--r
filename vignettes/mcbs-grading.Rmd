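---
title: "Grading recurrent ovarian cancer therapies on the ESMO-MCBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading recurrent ovarian cancer therapies on the ESMO-MCBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcbscore)
```

## The problem

Recurrent epithelial ovarian cancer is treated with palliative intent:
platinum-based chemotherapy and maintenance therapy (bevacizumab, PARP
inhibitors) in platinum-sensitive disease, non-platinum options in
platinum-resistant disease. The European Society for Medical Oncology
Magnitude of Clinical Benefit Scale (ESMO-MCBS) ranks such therapies on a
1–5 scale, where 4–5 denote *substantial* clinical benefit, by combining
relative efficacy (the hazard ratio), absolute efficacy (the gain in median
survival time), and quality-of-life (QoL) and toxicity evidence.

`mcbscore` implements this grading procedure as an auditable rule engine:
curated trial summary records go in; an evaluation form, a preliminary
grade, a ±1 QoL/toxicity adjustment, a final grade, and a rule-firing
rationale trace come out. A screening module encodes which trials are
eligible for grading at all, and a network module summarises the graded
head-to-head comparisons per treatment setting.

## The grading model

### Eligibility (screening)

Records are categorised as: **I** — phase III randomised controlled trials
with an adequate comparator and an OS or PFS primary endpoint; **III** —
designs outside scorable scope (`design = "other"`); **II** — everything
else potentially scorable (randomised phase II, non-inferiority or
response-rate primaries). "Large" is not operationalised by a patient-count
cutoff: phase III design plus an adequate comparator suffices, which
partitions the corpus exactly as published without inventing a threshold.

Comparator adequacy is setting-specific: platinum-based chemotherapy in
platinum-sensitive disease (non-platinum regimens proved inferior in a
randomised comparison), any guideline-listed option in platinum-resistant
disease, and placebo or no further treatment for maintenance. For
concomitant-start maintenance designs, where the investigational agent
starts together with a platinum doublet, we accept the platinum backbone as
adequate — the published grading treats those trials as gradable. The
class of each comparator is a curated annotation
(`inst/extdata/comparator_classes.csv`), applied by
`comparator_is_adequate()`; the per-record `comparator_adequate` flag is
the curated bottom line that the category rule consumes.

A record may then be graded iff it is category I or II, not terminated
early, not superseded by a higher-quality trial, and its primary endpoint
— or a confirmed secondary OS analysis — shows a statistically significant
benefit under a prespecified, multiplicity-controlled test. Significance is
a curated tri-state; `exploratory_or_unreported` never passes the gate (an
OS analysis not corrected for multiple testing is exploratory, however
small its p-value). Trials failing the gate return a first-class
`not_graded` result carrying the reasons, not an error.

For non-inferiority designs the primary analysis is carried by the PFS
summary, and its `significant` field curates whether the comparison
demonstrated a benefit worth grading: a non-inferiority trial whose only
finding is "not worse, no QoL or symptom advantage" is recorded as
`not_significant` and is not scored.

At most three prespecified subgroups per trial may be graded
(`subgroup_admissible()`); post-hoc or additional subgroup analyses are
reported but never scored.

### Evaluation forms and threshold tables

The form follows the primary endpoint and, for PFS primaries, OS maturity:

* **2a** — OS primary, or PFS primary with a *confirmed* secondary OS
  benefit;
* **2b** — PFS primary otherwise;
* **2c** — QoL/toxicity primary, including non-inferiority designs graded
  on QoL/toxicity;
* **3** — response-rate primary.

Forms 2a and 2b are threshold tables over three inputs: the control-arm
median (months), the absolute median gain `G` (months), and the **lower
bound `L` of the 95% confidence interval of the hazard ratio**. Using the
CI lower bound rather than the point estimate is essential: it is the only
reading consistent with all published worked examples (HR 0.82 with
CI 0.69–0.97 reaches grade 4 on form 2a; HR 0.81 with CI 0.68–0.91 stays at
grade 1 on form 2b).

Form 2a stratifies at a control median of 12 months:

| stratum | grade 4 | grade 3 | grade 2 |
|---|---|---|---|
| control ≤ 12 | L ≤ 0.65, G ≥ 3 | L ≤ 0.65, 2.5 ≤ G < 3 | L ≤ 0.70, 1.5 ≤ G < 2.5 |
| control > 12 | L ≤ 0.70, G ≥ 5 | L ≤ 0.70, 3 ≤ G < 5 | L ≤ 0.75, 1.5 ≤ G < 3 |

Form 2b stratifies at 6 months and never exceeds grade 3:

| stratum | grade 3 | grade 2 |
|---|---|---|
| control ≤ 6 | L ≤ 0.65, G ≥ 1.5 | L ≤ 0.65, G < 1.5 |
| control > 6 | L ≤ 0.65, G ≥ 3 | L ≤ 0.65, G < 3 |

Anything meeting no band floors at grade 1. All bounds are **inclusive**: a
published row with L exactly 0.65 and G exactly 1.5 grades 3 before
adjustment, which pins the convention. A control median exactly on a
stratum bound (12 or 6 months) uses the low stratum; no real row sits on a
bound, so this is a determinism choice only. The tables are exposed as data
by `form_thresholds()` and are normative against the shipped corpus: every
one of the 24 graded published rows reproduces exactly
(`run_corpus_check()`).

Form 2c is anchored by a single published example (non-inferior efficacy
with equal global QoL, improved symptom subscales and less early
discontinuation → grade 3). The full ladder — 4 for global QoL improvement
or reduced severe toxicity, 3 for subscale improvement or reduced early
discontinuation, 2 for non-inferior efficacy alone, 1 otherwise — is this
package's documented convention around that anchor, as is form 3's upper
band (ORR ≥ 60 → 3; 20 ≤ ORR < 60 → 2, the anchored band; < 20 → 1).

The 2-/3-year survival-percentage alternative pathway of form 2a is out of
scope here: no corpus row uses it, and the engine grades on medians only.

### The ±1 adjustment

On form 2b the preliminary grade is **upgraded** one point for a
prespecified QoL improvement (global or subscale) or a reduction in severe
toxicity, and **downgraded** one point when the trial shows a PFS benefit
only — a *reported, non-significant* OS result together with *reported* QoL
showing no improvement — or increased toxicity without any QoL benefit.
When mature OS or QoL results are simply unpublished, the downgrade is not
applied: absence of evidence is not evidence of absence, so unreported OS
is encoded as `exploratory_or_unreported`, never as a zero gain. On form 2a
the only adjustment is the upgrade towards grade 5. Forms 2c and 3 are not
adjusted. Conflicting evidence (a QoL improvement alongside increased
toxicity) resolves to 0 with an explanatory rationale line; no published
row exercises this tie, so it is a documented convention. The final grade
is `clamp(preliminary + adjustment, 1, 5)`.

## Properties, and one the scale does not have

Monotone under relative efficacy: at fixed gain, lowering the CI lower
bound never lowers the preliminary grade (every band condition is of the
form `L ≤ x`). The grade is **not** globally monotone in the gain: at
intermediate `L` — in (0.65, 0.70] for the low OS stratum, (0.70, 0.75]
high — only the grade-2 gain *window* is reachable, so a record can leave
the scored bands by gaining *more* months (e.g. control 10, L = 0.68:
G = 2.0 → grade 2, G = 3.5 → grade 1). This is a real feature of the
instrument's banded structure, reproduced faithfully; the property suite
therefore asserts gain-monotonicity only on the strict-HR region L ≤ 0.65
that all bands share, plus an explicit test of the non-monotone pocket.

The engine is additionally cross-checked against an independent
flat-conditions oracle (each band written as one fully spelled-out `if`)
on the 2112-cell boundary grid and on 10,000 seeded synthetic records.

## The synthetic generator

`generate_trials()` emulates the corpus population: per-setting control
medians drawn log-uniformly (5–12 months platinum-sensitive, 3–10
maintenance, 2–6 resistant — the observed ranges of the published PFS
rows), hazard ratios uniform on 0.3–1.1 (clearly active to null),
endpoint mix 70% PFS / 20% OS / 10% ORR (the corpus is PFS-dominated), and
evidence-flag rates reflecting that QoL is reported in roughly half of
trials but prespecified improvements are uncommon. Confidence intervals
come from the standard log-HR normal approximation with
`SE = 2/sqrt(events)` (events 50–400); the gain is derived as
`control × (1/HR − 1)` with 10% multiplicative log-normal noise;
significance is confirmed exactly when the CI excludes 1 in favour of the
study arm. The generator is seeded and deterministic, and its algorithm
identifier is recorded in the configuration object.

What it does *not* emulate: correlated PFS/OS outcomes within a trial
beyond a crude attenuation of the OS hazard ratio, informative censoring,
crossover, non-proportional hazards, or the editorial judgement embedded in
the curated significance and evidence flags. Passing property tests on
synthetic batches therefore demonstrates the *rule engine's* correctness
and totality, not the realism of any particular trial.

Problem sizes used by the test suite — a 2112-cell grid, 10,000 synthetic
records for oracle equivalence, batches of 400–1000 for generator
calibration checks — were chosen to cover every threshold boundary and
give stable Monte-Carlo ordering comparisons.

## The curated corpus

`load_corpus()` ships the published tables as records: 24 graded rows (14
phase III trials plus 5 phase II trials, with the niraparib cohorts and the
rucaparib and olaparib-capsule subgroup rows expanded one-per-row) and 27
ungraded trials without a statistically significant benefit. Multi-row
cells were split per subgroup during curation; the niraparib trial is
encoded as its two prespecified cohorts (no pooled analysis is printed, and
its exploratory HRD-positive row is not scored, so neither appears as a
graded record). One OS-gain cell is typographically ambiguous in the
source (a run of digits); it is recorded as 1.0 month and flagged in the
provenance notes. Hazard ratios printed without confidence intervals are
omitted from the records (the provenance keeps the printed value), since a
point estimate without an interval cannot enter the grading criterion and
would violate the record invariants.

Summing the printed per-row patient numbers reproduces the published
maintenance-setting total (3394) exactly; the published platinum-sensitive
and platinum-resistant totals do not reconcile with the printed per-trial
numbers (several footnoted trials also enrolled platinum-sensitive
patients, so those totals likely reflect full-trial enrolment not shown in
the tables). The corpus check asserts only the total that the printed
numbers support.

## Worked example

```{r example}
icon4 <- trial_record(
  "icon4", "platinum_sensitive", "phase3_rct", 802,
  "Paclitaxel plus platinum-based chemotherapy", "Platinum monotherapy", "OS",
  endpoints = list(endpoint_summary(
    "OS", control_median = 24, gain = 5,
    hazard_ratio = 0.82, hr_lower = 0.69, hr_upper = 0.97,
    significant = "confirmed")))
grade_trial(icon4)
```

```{r corpus}
corpus <- load_corpus()
nrow(run_corpus_check(corpus))  # 0: every published score reproduces
results <- grade_trials(corpus$trials)
vapply(Filter(is_substantial_benefit, results), `[[`, character(1), "trial_id")
```

## Known limitations

* Forms 2c and 3 are each anchored by a single published row; their
  unanchored bands are conventions and should not be over-interpreted.
* The engine grades curated summaries; it cannot detect miscurated
  significance or evidence flags, and it performs no survival re-analysis.
* Grades attach to a trial's *comparison*, not to a drug: arms graded
  against different comparators are not directly comparable, which is why
  the network module only records graded edges and deliberately implements
  no indirect-comparison (network meta-analysis) machinery.
* The curative-intent evaluation form of the scale is out of scope; all
  grading here is palliative (forms 2a/2b/2c/3).
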