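---
title: "A micro-simulation model of risk-stratified breast cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A micro-simulation model of risk-stratified breast cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratscreen)
```

## Scope and intent

`stratscreen` simulates individual life courses of women from age 50 to
100 under routine and relative-risk-stratified mammography screening, and
evaluates the strategies economically from the payer perspective. The
model family is a discrete-time micro-simulation Markov model: women move
annually between health states (healthy, DCIS, invasive cancer by stage,
dead of breast cancer, dead of other causes), and screening acts purely
through the stage distribution at diagnosis — there is no explicit tumour
natural-history component. That has one important consequence, inherited
from the model class: benefit from *earlier* diagnosis within the same
stage is not captured, so screening effects are, if anything,
conservative.

## States, events, and cycle order

One cycle is one year. Within a cycle events happen in a fixed order:

1. **Density update** (every fifth year after 50): the density category is
   resampled from a 4×4 transition matrix; the combined relative risk is
   recomputed.
2. **Screening invitation** (on the birthday grid, ages 50 to 69, at the
   woman's assigned interval): attendance is drawn per invitation with
   probability equal to the adherence rate (1 under the full-adherence
   scenario). An attended screen costs the mammography fee and a one-off
   screen disutility. For cancer-free attendees a false positive occurs
   with probability 1 − specificity, triggering follow-up imaging and
   possibly a core-needle or vacuum biopsy; an attended screen may also
   produce an overdiagnosis (below).
3. **Disease onset / progression**: a healthy woman develops invasive
   cancer with probability `incidence(age) × RR`, or DCIS with its own
   age-specific probability; undetected DCIS progresses to invasive cancer
   with a constant annual probability.
4. **Diagnosis and stage assignment**: a new invasive cancer is assigned a
   stage from the stage table of the woman's screening context (her
   interval's table if she attended her most recent invitation and it lies
   within one interval of the diagnosis; the no-screening table
   otherwise). The treatment cost bundle for her molecular subtype and
   stage is charged.
5. **Utility accrual**: everyone alive at the cycle start accrues one year
   at her state's utility weight, discounted.
6. **Deaths**: women with invasive cancer face the stage- and
   years-since-diagnosis-specific breast-cancer death probability first,
   then everyone faces the age-specific other-cause probability. Deaths
   are end-of-cycle, so the dying year is still accrued; no half-cycle
   correction is applied — with annual cycles and explicit event ordering
   the residual bias is small and identical across strategies, which is
   what matters for increments.

The per-cycle ordering is this package's own choice; it is documented
here precisely because micro-simulation results can depend on it.

## Risk profiles and strategies

Risk factors are assigned independently at the start age (no joint
distribution is published): density category from the age-50 prevalences,
family history (16.1 %) and prior biopsy (28.2 %) as Bernoulli flags. Only
density evolves over life; the two flags are fixed. The combined relative
risk is the product of three per-factor multipliers. The density
multipliers (0.33, 0.90, 1.15, 1.378) and the family-history (1.55) and
biopsy (1.35) multipliers are synthetic but calibrated so the extreme
combinations reproduce the published joint span of 0.33–2.88.

Stratified strategies map RR to an interval with two thresholds: strictly
above the upper threshold → annual, strictly below the lower → triennial,
between (boundaries included) → biennial. Closing both boundaries into
the biennial band is a deliberate tie-break: the strategy definitions say
"above", "between", and "below", and treating "between X and Y" as closed
is the most literal reading. The choice is visible only for women whose
RR equals a threshold exactly, which happens with probability zero under
continuous parameter perturbations but does occur in the discrete
reference set.

Cluster membership (which interval a woman is screened at) is evaluated
once at the start age and held fixed, because subgroup reporting treats
clusters as static populations. Density evolution still changes a woman's
*disease risk* mid-life. A switch (`reassign_on_density_change = TRUE`)
re-maps the interval after density updates for users who prefer the
dynamic reading; nothing else in the package depends on the choice.

Adherence is drawn per invitation by default. The alternative reading —
a woman either always or never attends — is available as
`adherence_mode = "per_woman"`, since behavioural assumptions of this
kind are known to move non-adherence results. Stage context follows
attendance of the *most recent* invitation, so an occasional attender is
protected only for cancers arising within one interval of a screen she
actually attended; chronic non-attenders draw from the no-screening
stage table, the same distribution as women who never attend.

## Overdiagnosis and DCIS

Overdiagnosis is implemented as a per-attended-screen probability
(default 0.001) of diagnosing a never-lethal case: the woman incurs the
local-stage treatment bundle and local-stage cancer utilities, stops
being invited, but cannot die of breast cancer. Tying it to screening
events (rather than to diagnoses) is the operationalization that keeps
harm proportional to screening intensity.

DCIS is non-lethal and accrues healthy utility. Undetected DCIS can
progress to invasive cancer (6 %/year). An attended screen detects DCIS
with certainty — the parameter schema carries no separate screening
sensitivity because detection performance is already folded into the
interval-specific stage distributions — after which the woman is treated
(local-stage bundle), stops progression, and leaves the invitation pool.
Screen detection of DCIS is therefore deliberately generous; its main
effect is a small cost and a small averted-progression benefit in the
screened arms.

## Economics

Costs (2017 Euros) and utilities are discounted at 3 %/year with
end-of-cycle timing on integer years since age 50:
`discount_factor(r, t) = (1 + r)^(-t)`. The screening pathway uses the
published fee schedule (€73.50 / €94.45 / €21.10 / €39.79). Treatment is
charged as a single bundle at diagnosis by default; a `"phased"` option
spreads it evenly over three years, because the true timing is not
published — the switch exists so users can check that conclusions do not
hinge on it (with 3 % discounting the difference is a few percent of the
bundle). The distant-stage bundle includes palliative care. Every costed
or utility-bearing event can be logged (`run_life_course`) and the
discounted totals are exactly recomputable from the raw event list; the
test suite asserts this equality.

## The synthetic reference parameter set

`reference_parameters()` fixes every quantity with a published value to
that value exactly: the four risk-factor prevalence anchors, the RR span,
the fee schedule, the 54 % adherence rate, and the 3 % discount rate.
Everything else is a synthetic fill chosen once, on plausibility grounds,
and then frozen:

* **Invasive incidence** rises linearly from 0.25 %/year at 50 to 0.40 %
  at 99 — the forced monotone-in-age shape, at German registry magnitude;
  it yields a lifetime risk near 11 % and a no-screening breast-cancer
  death fraction near 4 %.
* **Background mortality** is Gompertz (0.2 %/year at 50, doubling every
  ~7 years), a standard life-table shape.
* **Stage distributions** start from (0.55, 0.33, 0.12) without screening
  and shift towards local stage with screening intensity — (0.78, 0.18,
  0.04) for annual, (0.72, 0.22, 0.06) biennial, (0.66, 0.26, 0.08)
  triennial — with mass moved out of local stage for denser breasts
  (masking) and older age bands.
* **Stage-specific breast-cancer mortality** is 1 %/5 %/35 % annually in
  the first five years after diagnosis (local/regional/distant), halved
  afterwards: distant worst everywhere, as survival data force.
* **Utilities** are EQ-5D-magnitude: healthy 0.87→0.74 by age band, cancer
  utilities ordered healthy > local > regional > distant, with a worse
  first year than later years.
* **Screening disutility** is 0.001 QALY per attended screen (a few days
  of quality-adjusted life, the order reported for mammography anxiety),
  biopsy disutility 0.01.
* **Work-up branches**: specificity 0.97 (German recall rates), follow-up
  imaging for every false positive, biopsy in 21 % of them (15 %
  core-needle, 6 % vacuum).
* **Treatment bundles** are monotone in stage within each subtype, with
  the HER2-positive pathway carrying the trastuzumab premium; the subtype
  mix is 15 % triple-negative, 12 % HER2-positive, 73 % hormone-receptor
  positive.

Because these fills are not a registry calibration, the package does not
claim to reproduce published absolute outcome levels, and its tests do
not assert them. What the generator *does* emulate — and what the
acceptance tests check — is the structure: the ordering of strategies by
screening intensity, the near strategy-independence of relative adherence
losses, harm increasing with screening frequency, and all of the
decision-layer arithmetic. Features of real data it does not emulate
include calendar-period effects, correlation between risk factors,
risk-dependent adherence, and digital-vs-film performance differences.

## Uncertainty analysis

`psa_spec()` declares independent per-parameter distributions (uniform,
beta, gamma, lognormal) over ranges; curve-valued parameters are scaled
by a sampled factor, probabilities are clamped to [0, 1] and stage
distributions renormalized, so every draw is again a valid parameter
set. A zero-width range reproduces the base value exactly, giving a
degenerate PSA that must (and in tests does) equal the point estimate.
Parameters are sampled independently because no correlation structure is
published.

`run_psa()` re-simulates every strategy and the comparator per draw with
common random numbers. CEACs report, per willingness-to-pay value, the
fraction of draws in which each strategy maximizes net benefit
`λ·effect − cost`; ties break towards the cheaper strategy so the
probabilities always sum to one. Multi-outcome comparison is provided as
separate CEACs per outcome (QALY and mortality reduction) viewed side by
side. The default WTP grid is €0–300,000 in €1,000 steps, covering every
threshold a decision maker is likely to quote. EVPI is
`E[max_s NB] − max_s E[NB]` at a user-chosen λ. The shipped defaults
(100 draws × 50,000 women; 20 × 20,000 in the acceptance script) are
scaled-down working sizes — the estimator is unbiased at any size and
both knobs are plain arguments; the full published-scale 500 × 3,000,000
configuration is reachable by setting them.

## Numerical and testing choices

* All uniform variates are pre-drawn per (woman, purpose, year) with
  fixed dimensions independent of the strategy (`crn_streams`), which is
  what makes common random numbers exact: adding a strategy can never
  perturb another arm's randomness.
* The efficiency frontier uses strict dominance followed by an
  increasing-ICER sweep for extended dominance; it is tested exactly
  against a brute-force convex-combination oracle on 1,000 random
  strategy sets.
* The micro-simulation is tested against an independent deterministic
  cohort recursion (expected-value Markov chain over the same transition
  structure, stratified by risk factors and density) within three
  Monte-Carlo standard errors, both on a stylized single-stage constant-
  hazard population and on the full reference set.
* Display rounding (nearest Euro for ICERs, whole percent for losses)
  never feeds back into computation; exact values are carried alongside.
* Qualitative acceptance checks run at 200,000 women per arm, a size at
  which the orderings under test are resolved within three standard
  errors in a few minutes on one CPU; headline examples use 20,000.

## Known limitations

Absolute outcome levels depend on synthetic fills (see above). Mode of
detection is not modelled beyond the stage mechanism, so screen-detected
and clinically detected cancers are indistinguishable except through
stage. Overdiagnosis is a reduced-form per-screen probability, not a
lead-time construct. The published QALY elasticity per adherence point
is not recoverable from printed inputs and is therefore reported by the
package but not asserted against a reference value.
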