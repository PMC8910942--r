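# earlymcda

Reflective multicriteria decision analysis (MCDA) for appraising individual
early-access medicine requests — compassionate use, off-label use, imported
unauthorised medicines and pre-reimbursed indications — by a multidisciplinary
advisory committee. The package is aimed at health-technology-assessment
analysts and committee secretariats who need a transparent, repeatable way to
turn panel judgements into a documented appraisal, and at methodologists who
want to study the statistical behaviour of such frameworks on simulated
panels.

## The model

The framework splits its criteria into a quantitative **core model** and a
qualitative **contextual tool** (EVIDEM-style reflective MCDA). Each of the
`n` core criteria is weighted by every panellist on a 1–5 importance scale;
weights are normalised to sum to 1 per panellist,

    W_x = w_x / Σ_j w_j ,

and each raw categorical score is standardised onto the unit interval by its
scale range (`S_x = (score − min) / (max − min)`, i.e. `score / 5` on the
default 0..5 scale). A panellist's **value estimate** is the linear additive
aggregate of the **value contributions** `VC_x = W_x × S_x`:

    VE = Σ_{x=1..n} VC_x = Σ_{x=1..n} W_x S_x ∈ [0, 1],

a convex combination of standardised scores that reaches 1 exactly when every
score sits at its scale maximum. The committee-level VE is the mean of
per-panellist VEs. Contextual criteria are rated favourable / neutral /
unfavourable and reported as percentage tallies with a dominant direction,
never aggregated numerically. Test/re-test consistency of a repeated
appraisal is checked with a from-scratch Wilcoxon signed-rank test, exact (by
complete enumeration of the sign-assignment null) up to 20 non-zero paired
differences, with midranks for ties.

The bundled **final** framework has 8 core criteria (disease severity,
medical urgency, efficacy, safety, internal validity, therapeutic benefit,
external validity, and dichotomous plausibility on {0, 5}) plus 4 contextual
criteria (therapeutic alternatives, precedent and coherence, management
impact, costs and budget impact); a **pilot** version (8 quantitative + 3
qualitative) is also included.

## Worked example

```r
library(earlymcda)

fw <- default_framework("final")

# equal weights; a strong case: top scores on severity and urgency,
# moderate evidence, plausible mechanism
w <- setNames(rep(1/8, 8), core_ids(fw))
s <- setNames(c(5, 5, 4, 4, 3, 3, 2, 5), core_ids(fw))
value_estimate(w, s, fw)$ve
#> [1] 0.775
```

Each criterion contributes its weight times its standardised score:
`(1 + 1 + 0.8 + 0.8 + 0.6 + 0.6 + 0.4 + 1) / 8 = 0.775`, i.e. the case
captures 77.5% of the maximum attainable value under these weights.

A full synthetic committee round, via the CLI (also available as
`exec/earlymcda`):

```r
mcda_cli(c("simulate", "--seed", "11", "--out", "run"))
mcda_cli(c("weigh",  "--weights", "run/weights.csv", "--out", "run"))
mcda_cli(c("score",  "--weights", "run/weights.csv",
           "--scores", "run/scores_test.csv", "--out", "run"))
mcda_cli(c("retest", "--weights", "run/weights.csv",
           "--test",   "run/scores_test.csv",
           "--retest", "run/scores_retest.csv", "--out", "run"))
#> [earlymcda] verdict: consistent (group VE delta +0.000)
```

`run/value_report.json` then holds the group VE, per-panellist VEs, mean
value contributions and contextual tallies; `run/retest_comparison.json`
holds the per-criterion and VE-level Wilcoxon results and the verdict.

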