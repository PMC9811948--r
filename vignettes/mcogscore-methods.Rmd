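---
title: "Methods: composite digital screening scores and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite digital screening scores and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcogscore)
```

## The screening problem

Mild cognitive impairment is routinely staged with interview-based
instruments — the Clinical Dementia Rating (CDR, global scores 0, 0.5, 1,
2, 3) and the 30-point MMSE-2 — that need a trained administrator and, for
the CDR, a companion who knows the participant.  A smartphone battery that
a participant can self-administer in minutes is attractive if its composite
score can be shown to (a) correlate with the MMSE-2 (convergent validity)
and (b) separate CDR 0 from CDR 0.5–1 participants (discriminative
validity).  This package implements such a battery's scoring rules and the
entire validation analysis around them, plus a synthetic cohort generator
so every stage is testable without access to participant data.

## Scoring model

The battery has three subtests:

* **Stroop** — 18 colour-word trials (6 congruent, 12 incongruent over
  red/green/blue); the raw score is correct answers divided by the total
  response time (correct/s), combining accuracy and speed.
* **Symbols** — 9 symbol–digit substitution trials through a bijective
  nine-symbol key; raw score again correct per second.  Handwritten digits
  are assumed digitised upstream; this package sees entered digits.
* **Memory** — 8 words, each recalled twice by cued multiple choice: an
  immediate trial with 4 options and a delayed trial with 8 options.  The
  raw score is the number correct out of eight on the **delayed** trial;
  time is deliberately excluded so the memory score is not coupled to the
  two time-normalised scores.

The composite (M-CogScore) is the unweighted mean of the three subtest
z-scores.  By default the z-reference (per-subtest mean and n−1 sd) is
fitted on the analysis cohort itself, over participants with all three
subtests complete; self-referenced composites therefore average exactly
zero over the reference cohort, which matches the pooled near-zero
composite mean in the published group summaries.  Externally normed
references can be supplied instead.

Two conventions deserve comment because the published description leaves
them open:

* *Which recall trial counts.*  "Number correct out of eight" does not name
  the trial.  We count the delayed trial, the standard diagnostic trial of
  word-list batteries (the immediate trial mainly checks encoding); the
  immediate trial and an "item correct only if both trials correct" rule
  are available as `score_memory(..., trial = )` for sensitivity analyses.
* *What the timer spans.*  Total time is the sum of per-item response
  times, stimulus onset to answer, excluding instruction screens; the
  app-level definition is not published, and any fixed offset shared by
  all participants would only shift the raw scale, not the z-composite's
  ordering.

A skipped item makes its section incomplete; an incomplete section yields
*no* raw score (never a zero, unlike paper-test conventions), and the
composite exists only when all three sections are complete — there is no
partial mean.

## The synthetic cohort generator

The generator reproduces the statistical structure the validation analysis
relies on, not cognitive process detail.  One latent severity factor per
participant drives everything:

* participant $i$ in group $g$ draws a shared factor $Z_0$ and
  per-instrument noise $Z_k$, and instrument $k$ sees severity
  $S_k = \mu_g + \sigma_g(\lambda Z_0 + \sqrt{1-\lambda^2} Z_k)$,
  marginally $N(\mu_g, \sigma_g^2)$, with the loading $\lambda$
  controlling within-group cross-instrument correlation;
* item correctness is Bernoulli with a logistic link in $-S_k$, with
  guessing floors of 1/4 (immediate) and 1/8 (delayed) for the cued-recall
  options;
* response times are lognormal with a location shifting linearly in
  $S_k$;
* the MMSE-2 total is a rounded linear-Gaussian function of severity
  clamped to [0, 30] — the clamp alone produces the healthy-group ceiling
  effect, with no explicit skew family;
* section-skipping propensity is logistic in severity, so missingness
  concentrates in the impaired group, as observed.

Defaults are calibrated once so that the *included* groups reproduce the
published group summaries: healthy/impaired MMSE-2 means 28.6/26.1 and
self-referenced composite means +0.47/−0.52 (checked to Monte-Carlo error
at large n).  The impaired latent sd defaults to 1.6 (healthy 1.0): a CDR
label of 0.5 *or* 1 mixes degrees of impairment, and the published group
sds — roughly double the healthy spread on both instruments — cannot be
reproduced by any common within-group severity sd.  With this
heterogeneity the generated sds come out near 1.5/2.5 (MMSE-2, published
1.2/2.8) and 0.49/0.68 (composite, published 0.47/0.77), and the two AUCs
land near 0.88 (composite) and 0.81 (MMSE-2), a gap like the published
0.85 vs 0.78.

With flow emulation on (`default_config()`), the participant flow is
reproduced with fixed counts: 108 consented (50 healthy + 55 impaired
recruited, 1 revoked consent, 2 CDR > 1 screening failures), 7 upload
failures (5 healthy / 2 impaired, drawn at random — connectivity is
severity-independent), and 26 single-section skippers (7 healthy / 19
impaired, drawn *with probability increasing in severity* within each
group, so excluded participants are older-scoring-lower, as observed; the
skipped section is multinomial 9:5:12 for Stroop:Symbols:Memory).  That
leaves exactly 38 healthy and 34 impaired included.  Demographics (age,
sex, education) are drawn per group from the published demographic
frequencies — we chose per-group frequencies rather than one pooled
distribution because the groups were recruited matched but their observed
marginals still differ slightly, and the per-group reading is the one the
generator's own calibration checks can verify.

What the generator does **not** emulate: diffusion-style response-time
dynamics, practice or fatigue effects within a session, education or age
effects on the subtest scores (demographics are matched, so the published
analysis never models them), longitudinal change, and site effects.
Passing tests therefore show that the *pipeline* recovers the assumed
structure, not that the battery works on real participants.

One free parameter is deliberately left uncalibrated: the within-group
MMSE–composite coupling (`mmse_loading`, default 0.75).  The published
pooled Spearman rho of 0.54 mixes between-group separation with
within-group correlation and does not identify the within-group value;
with the default loading the generator's pooled rho comes out near 0.6.

## Statistical conventions

The validation battery fixes conventions to match how this literature
prints its numbers; each choice is verifiable against a printed value or
is the dominant convention of the field's analysis stacks:

* **Mann-Whitney U** uses mid-rank ties and reports **min(U₁, U₂)** (the
  published education comparison prints 583 = min(709, 583); the identity
  U₁+U₂ = n₁n₂ is kept exactly).  p is the tie-corrected normal
  approximation with 0.5 continuity correction, two-sided.
* **Chi-squared** on 2×2 tables applies the **Yates** continuity
  correction by default: the published missing-data comparison prints 4.2,
  which is the corrected statistic (uncorrected: 5.1).
* **Fisher's exact test** uses the probability-mass two-sided rule (sum of
  hypergeometric probabilities not exceeding the observed table's).
* **Spearman's rho** is the Pearson correlation of mid-ranks with a
  t-approximate p (n−2 df); an exact permutation p is available for
  n ≤ 10.
* **t-tests** default to Student's pooled form (Welch available).
* **Shapiro-Wilk** acts only as an advisory gate recorded in metadata: the
  pipeline always reports the non-parametric branch, keeping reports
  comparable across cohorts.
* **Quartiles** use the linear-interpolation convention (type 7), the
  default of the published analysis stack.
* The **proportional median difference** |median₁ − median₂| / (max − min)
  normalises a group gap by the observed score range.

## ROC machinery

The decision rule is *score < c ⇒ impaired* (strict), matching the
published cut-off phrasing ("< 27", "< 0.21").  The AUC is the rank
(Mann-Whitney) statistic with between-class ties weighted 0.5; it equals
the trapezoidal area under the empirical curve to numerical identity, and
both are cross-checked against brute-force pair counting in the tests.
The Youden cut-off maximises J = sensitivity + specificity − 1 with ties
broken toward higher sensitivity — in a screening context missed cases
cost more than false alarms — then toward the smaller threshold;
distinct thresholds cannot share both sensitivity and specificity, so the
rule is deterministic.

Confidence intervals use the percentile bootstrap with **stratified
resampling of 75% of each class's size with replacement** per replicate
(10,000 replicates at study scale).  The 0.75-proportion phrasing in this
validation design is not further specified; we read it as stratified
with-replacement resampling and expose without-replacement subsampling as
a switch.  Because resampling fewer than n observations inflates replicate
variance by roughly 1/0.75, the resulting intervals are conservative: in
the package's own coverage study (binormal model with known AUC, 500 outer
replications) the proportion-1 interval covers ~95% and the
proportion-0.75 interval ~98%.  Percentile rather than BCa intervals: the
simplest method consistent with the design's wording.

The paired AUC comparison is the DeLong placement-value (structural
components) estimator of var(AUC₁ − AUC₂), accounting for the pairing,
with a two-sided normal p.  The tests check it against an independent
Monte-Carlo variance oracle (estimator mean within 15% of the true
variance of ΔAUC over 10,000 resimulations of a paired n = 30 model) and
against the pROC implementation on fixtures.  Degenerate variance with a
nonzero AUC difference reports p = 0 with a warning; with a zero
difference, p = 1.

## Pipeline order and exclusions

Dispositions are assigned in a fixed priority order — revoked consent →
CDR > 1 → upload failure → incomplete composite → included — and each
participant appears exactly once (a participant who both failed to upload
and skipped a section counts as an upload failure).  The published flow
diagram implies but does not state an order; this one follows the
chronology of the testing session.  The z-reference is fitted only after
exclusions, on included participants, so the composite scale is defined by
exactly the cohort entering the validation statistics; the published
analysis does not say whether its reference preceded the upload-failure
exclusions, and the choice is asserted, not derived.

Reports carry full-precision numbers; rounding to the field's printing
conventions (1 d.p. for chi-squared, 2 d.p. for rho/AUC/p) happens only in
the presentation script (`analysis/04_report.R`).

## Problem sizes used in the checks

The packaged checks run at sizes chosen to bound Monte-Carlo error while
staying quick on one CPU: generator calibration checks at ~4–7 thousand
participants per draw with 3-standard-error bands around
closed-form/integration oracles; AUC recovery on 2,000 per group from the
published group moments (binormal closed forms 0.864 and 0.794 against the
printed 0.85 and 0.78); bootstrap coverage with 500 outer × 500 inner
replicates; the DeLong oracle with 10,000 resimulations; and the
end-to-end AUC-ordering check over 100 seeded study-scale runs.

## Known limitations

* Printed values that depend on the unavailable raw data (rho = 0.54,
  U = 187/189 and 287, the cut-offs 27 and 0.21 with their
  sensitivity/specificity pairs, DeLong p = 0.21, bootstrap CI endpoints)
  are not reproduced numerically; property-based substitutes cover the
  machinery that would compute them.
* Two printed values are internally inconsistent with their own inputs and
  are not asserted anywhere: the Fisher p of 0.81 for the sex table
  ([[17,21],[15,19]] sits at the hypergeometric mode, so the two-sided
  probability-mass p is 1.0), and the education MWU p of 0.22 (the tie-
  corrected normal approximation on the printed counts gives 0.45; only
  U = 583 reproduces).  The abstract's U = 187 vs the results section's
  189 for the same comparison is likewise irreconcilable without raw data.
* The generator's MMSE-2 sds (≈1.5/2.5) bracket but do not exactly match
  the published 1.2/2.8; matching them exactly would need a skewed or
  mixture MMSE family that the ceiling-by-clamping design deliberately
  avoids.
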