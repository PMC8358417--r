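# mcbscore

Rule-based grading of systemic therapies for recurrent epithelial ovarian
cancer on the ESMO Magnitude of Clinical Benefit Scale (ESMO-MCBS), for
clinical researchers and health-policy analysts who need published trial
results scored reproducibly and auditably.

Palliative therapies are graded 1–5 (4–5 = substantial benefit). For each
curated trial record the package:

1. applies the eligibility **screening** rules (trial category, adequate
   comparator per setting, the statistical-significance gate, the
   ≤ 3-prespecified-subgroups rule);
2. selects the **evaluation form** from the primary endpoint and OS
   maturity — 2a (OS), 2b (PFS only), 2c (QoL/toxicity, incl.
   non-inferiority), 3 (response rate);
3. computes the **preliminary grade** from the form's threshold table over
   the control-arm median, the absolute median gain *G* (months), and the
   *lower bound L of the 95% CI of the hazard ratio* (form 2a, control
   ≤ 12 mo: grade 4 iff L ≤ 0.65 ∧ G ≥ 3; form 2b, control ≤ 6 mo: grade 3
   iff L ≤ 0.65 ∧ G ≥ 1.5; all bounds inclusive; see
   `form_thresholds()` and the vignette for the full tables);
4. applies the ±1 **QoL/toxicity adjustment** (upgrade for prespecified
   QoL/toxicity improvement; downgrade for a PFS-only benefit with
   reported, unimproved QoL and non-significant OS — never when OS/QoL are
   simply unpublished) and clamps the final grade to [1, 5];
5. emits a `graded_result` with a complete rule-firing **rationale trace**;
   ineligible trials come out `not_graded` with reasons, not as errors.

A curated corpus of 24 graded published rows (19 trials) and 27 ungraded
trials ships with the package and is the normative test bed; a seeded
synthetic-trial generator and an igraph-based comparator benefit network
(DOT/GraphML/JSON export) round out the toolkit. A thin CLI
(`inst/cli/mcbs.R`) exposes `screen`, `grade`, `simulate`, `network` and
`corpus` subcommands.

## Worked example

```r
library(mcbscore)

icon4 <- trial_record(
  "icon4", "platinum_sensitive", "phase3_rct", 802,
  "Paclitaxel plus platinum-based chemotherapy", "Platinum monotherapy", "OS",
  endpoints = list(endpoint_summary(
    "OS", control_median = 24, gain = 5,
    hazard_ratio = 0.82, hr_lower = 0.69, hr_upper = 0.97,
    significant = "confirmed")))
grade_trial(icon4)
#> <graded_result icon4> MCBS 4 (form 2a): preliminary 4, adjustment +0
#>   - form 2a selected (primary endpoint OS)
#>   - preliminary grade 4 on form 2a
#>   - final grade 4
```

A 5-month OS gain over a 24-month control median with a hazard-ratio CI
lower bound of 0.69 meets the long-survival stratum's top band of form 2a:
grade 4, substantial benefit. No QoL/toxicity evidence is recorded, so no
adjustment applies.

Against the full shipped corpus:

```r
corpus <- load_corpus()
nrow(run_corpus_check(corpus))
#> [1] 0            # every published score and form reproduces
results <- grade_trials(corpus$trials)
vapply(Filter(is_substantial_benefit, results), `[[`, character(1), "trial_id")
#> [1] "icon4"           "aurelia"         "adavosertib_gem"
```

Exactly three therapies reach substantial benefit: paclitaxel plus
platinum (sensitive setting), bevacizumab plus chemotherapy (resistant
setting), and adavosertib plus gemcitabine (phase II).

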