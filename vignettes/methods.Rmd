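---
title: "Methods: the additive value model, its consistency check, and the synthetic panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the additive value model, its consistency check, and the synthetic panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earlymcda)
```

## The appraisal problem

Early-access requests — compassionate use, off-label use, importation of
unauthorised medicines, pre-reimbursed indications — are decided case by
case, often under pressure and with incomplete evidence. `earlymcda`
implements a reflective MCDA framework for such decisions: a quantitative
*core model* that is weighted, scored and aggregated into a value estimate,
and a qualitative *contextual tool* whose ratings are only tallied, so that
the numbers structure deliberation rather than replace it.

## The additive value model

Each panellist $i$ assigns every core criterion $x$ a raw importance weight
$w_{ix} \in \{1,\dots,5\}$, normalised per panellist to
$W_{ix} = w_{ix} / \sum_j w_{ij}$ so that $\sum_x W_{ix} = 1$. A raw
categorical score on a scale $[m, M]$ standardises as
$S_x = (s_x - m)/(M - m)$, and the value estimate is

$$ VE_i = \sum_x W_{ix} \, S_{ix} \in [0, 1], $$

a convex combination of standardised scores. The group value estimate is the
arithmetic mean of per-panellist VEs.

Two modelling points deserve comment:

* **Standardisation divisor.** We divide by the scale *range* ($M - m$, i.e.
  5 on the default 0..5 scale), not by the count of scale categories (6).
  Only the range divisor lets an all-maximum assessment reach the advertised
  VE ceiling of exactly 1; the category-count reading would cap VE at 5/6
  and break the convex-combination interpretation.
* **Aggregation order.** The committee VE is computed per panellist and then
  averaged (`per_panellist` mode). Because the model is linear, averaging
  normalised weights first and scoring with the consensus vector
  (`consensus_weights` mode) gives the same group VE whenever panellists
  share a weight vector; both modes are provided and reported explicitly.
  Individual published committee data are generally unavailable, so neither
  order can be privileged empirically.

The dichotomous plausibility criterion is scored only at its endpoints
\{0, 5\} and standardises to 0 or 1; its polarity follows the bundled scale
definition (5 = plausible = better), consistent with every other scale and
with the VE ceiling.

Panellists with incomplete quantitative score vectors are excluded from the
VE with a warning and listed in the report; silent imputation would
fabricate committee judgements.

### Weight elicitation and summaries

Two normalisation routes share one contract (output sums to 1): the 5-point
rating-scale method (divide by the weight sum) and the point-allocation
method (multiply criterion ratings by their domain's weight, then rescale by
the sum). "Rescale to 0–1" is deliberately read as divide-by-sum rather than
min–max scaling: downstream VE requires sum-to-one weights, and min–max
would destroy that. Panel weight summaries report the mean and *sample*
standard deviation (n − 1) of the raw 1..5 weights — the usual convention
for small expert panels — overall and per professional profile
(policymakers, evaluators, clinicians, patient representatives); a
population-SD option exists. Display rounding is one decimal for means and
SDs, two decimals for VEs, integers for contextual percentages (half to
even); full precision is always retained in the returned objects and JSON.

## The consistency check

A re-test repeats the appraisal of the same case after an interval. The
package pairs the two assessments on shared panellists and applies a
Wilcoxon signed-rank test at two granularities — each core criterion's score
pairs, and the per-panellist VE pairs — because the appropriate granularity
is itself a methodological choice; both are reported, along with the group-VE
delta, and the verdict is "consistent" only if nothing reaches significance
at the chosen `alpha` (default 0.05).

The signed-rank test is implemented from scratch. Differences of zero are
discarded (Pratt's zero-rank treatment is available as an option), absolute
differences are ranked with midranks for ties, and for up to 20 non-zero
differences the two-sided p-value is *exact*: the null distribution of
$W^+$ over all $2^n$ equiprobable sign assignments of the observed
(mid)ranks is computed in full by generating-function convolution (midranks
are doubled so all sums are integers), and
$p = \min(1,\, 2\min(P(W^+ \le w), P(W^+ \ge w)))$. The 20-pair cutoff is
where the normal approximation — mean $\sum r_i / 2$, variance
$\sum r_i^2 / 4$ (automatically tie-corrected by the midranks), continuity
correction 1/2 — is adequate for this test's discreteness. The test suite
verifies the exact path bit-for-bit against brute-force $2^n$ enumeration
(all tie-free vectors to $n = 12$ and 500 random tied vectors to $n = 10$)
and against the reference implementation in `stats::wilcox.test`, which is
used only as a cross-check.

Because the exact null is discrete, the test is conservative: its type-I
error at $\alpha = 0.05$ is below 0.05, which is the right direction of
error for a consistency audit (false alarms of inconsistency are the costly
mistake).

## The synthetic panel generator

No individual committee data are published, so the generator is the
package's test bed. It emulates:

* **Composition** — default 18 panellists: 7 evaluators, 5 clinicians, 5
  policymakers, 1 patient representative (the committee structure the
  framework was built for).
* **Weights** — per-criterion location/dispersion on the 1..5 scale,
  optionally per profile. Defaults span 3.6 (plausibility) to 4.7 (urgency)
  with dispersions 0.6–0.7, the reported high-agreement regime; locations
  for the three criteria without published means (safety 4.3, therapeutic
  benefit 4.3, internal validity 4.0) were fixed once inside the published
  3.6–4.7 span, ordered as the deliberation narrative ranks them.
* **Scores** — per-criterion location/dispersion on each criterion's own
  scale (default location 3, dispersion 1: a moderately favourable case);
  dichotomous criteria draw Bernoulli between their endpoints with the
  success probability implied by the location.
* **Contextual ratings** — categorical draws from per-criterion probability
  triples (default 0.5 / 0.3 / 0.2, mildly favourable).
* **Re-test drift** — re-test score = base score + per-criterion systematic
  drift + noise rounded half away from zero (so a ±0.5 draw can move a
  score), clamped to the scale and snapped to the nearer endpoint for
  dichotomous criteria. Zero drift and zero noise reproduce the base
  assessment exactly.

Weights and scores use a **discretised truncated normal**: a latent normal
draw is rounded to the nearest integer and clamped to the scale. Plain
discretisation biases the realised mean toward the scale centre (a 4.7
location on 1..5 would realise well below 4.7), so the latent location is
*mean-calibrated* by root-finding: the latent mean is solved (monotone in
the target, `uniroot` at tolerance 1e-9) so the discrete distribution's
expectation equals the requested location. This is what makes parameter
recovery exact in expectation, not just approximate. The distribution family
is a modelling choice — only a mean/SD structure is implied by panel
reports — and is isolated behind the generator interface.

One global seed feeds independent per-purpose substreams (weights,
assessment, re-test), so adding a call to one generator never perturbs the
draws of another, and every generator is bit-reproducible under a fixed
seed and spec.

**What passing tests do and do not show.** The generator produces
exchangeable, independent panellists with symmetric unimodal judgement
noise. Real committees exhibit anchoring, deliberation-induced convergence,
profile-correlated scoring and occasionally missing ratings; tests passing
on synthetic panels demonstrate the *arithmetic and statistical machinery*
— normalisation contracts, VE bounds, exactness of the Wilcoxon null,
detection power under drift — not the behavioural validity of any real
panel's judgements.

## Numerical and design choices

* Normalized-weight sum tolerance: 1e-9 on input validation; VE weight
  check at 1e-8.
* Tallies: exact fractions retained; display percentages rounded half to
  even.
* Consensus rule for criterion selection: strict majority (> 50%) of the
  *panel* (not of ballots cast) for include or exclude; everything else is
  "adapt", and "modify" ballots count toward neither threshold — exactly
  half the panel never decides.
* Degenerate inputs: an all-zero difference vector returns $n_{nonzero} =
  0$, $p = 1$, flagged "no information"; a one-panellist stratum reports no
  SD; an empty scores file, disjoint test/re-test panels, and mismatched
  framework versions are hard errors.
* Problem sizes in the test suite (18–16-member panels, 200 Monte-Carlo
  replicates for power and recovery checks, enumeration to $n = 12$) were
  chosen as the smallest sizes at which the statistical assertions are
  stable across seeds.

## Known limitations

* The framework files carry criterion definitions as free text only; the
  evidence matrices that feed real deliberations are out of scope.
* Weight elicitation supports one domain layer for point allocation, not
  hierarchical trees, and no swing-weighting or AHP.
* Agreement statistics other than the signed-rank comparison (kappa, ICC)
  are deliberately not provided.
* Published committee-level value estimates for real cases depend on
  unpublished individual data and cannot be reproduced; the package
  reproduces the model's analytic consequences instead.
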