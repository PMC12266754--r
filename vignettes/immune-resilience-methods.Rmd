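---
title: "Immune-resilience metrics: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune-resilience metrics: models, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irpipe)
```

## The problem

Immune resilience (IR) is the capacity to preserve immunocompetence and
restrain inflammation during immunological stress and aging. Two
transcriptomic metrics summarise it in bulk blood expression: a
survival-associated signature (SAS-1, tracking immunocompetence) and a
mortality-associated signature (MAS-1, tracking inflammation). Their
median-split combination yields four IR profiles — `H-L` (SAS-1 high,
MAS-1 low; optimal), `H-H`, `L-L`, and `L-H` (extreme degradation) — which
stratify mortality, infection outcomes, and vaccine responses. A parallel
cell-count metric, the immune health grade (IHG), grades the balance of
absolute CD4⁺ and CD8⁺ T-cell counts. This package implements the metrics,
the downstream statistics, and a simulator that plants all of the
structures the analysis assumes.

## Signature scoring and strata

Expression is gene-wise z-scored across samples (sample sd, denominator
n−1). Zero-variance genes cannot be standardised and are dropped with a
warning rather than imputed. A signature score is the **unweighted mean of
oriented z-scores** over the members present:

$$s_j = \frac{1}{|G|}\sum_{g \in G} o_g \, z_{gj}, \qquad o_g \in \{+1,-1\}.$$

The composite is deliberately the simplest scheme consistent with
reporting scores in z-units; `score_signature()` accepts a plug-in
aggregator (`mean`, `median`, `ranksum`) so a weighted or rank-based
variant can be slotted in without touching callers. Orientation flips are
supported per gene; for signatures whose published direction is inverted
as a whole (e.g. a senescent-T-cell signature counted as a
*positive*-salutogenesis readout), the composite-level flip is expressed
by orienting every member −1 — the per-gene mechanism covers both
readings.

**Stratification rule.** A sample is `H` iff its score strictly exceeds
the reference median, `L` otherwise — a score exactly at the median is
`L`. Consequently at most ⌊n/2⌋ samples can be `H`. The reference
defaults to the scored cohort itself; for longitudinal series the
recommended (and configurable) choice is the baseline-timepoint cohort, so
follow-up samples are judged against the pre-stress distribution. Ties and
coverage failures are errors, not silent drops.

## IHG grading

Grades cross the CD4:CD8 ratio against absolute CD4: ratio ≥ cutoff with
CD4 ≥ `cd4_high` is grade I (high CD4, restrained CD8 expansion); ratio
below the cutoff with preserved CD4 is III; the CD4-depleted counterparts
II and IV are subgraded a/b/c by descending CD4 bands. The numeric
defaults (ratio 1.0; CD4 800 cells/µL; bands 500/200) are *reconstructed*
from the qualitative grade descriptions — the exact published cutoffs live
outside the text this package was built from — so they are explicit
`ihg_thresholds()` parameters, every output records the thresholds used,
and nothing downstream hard-codes them. Grade III is not subgraded (no
IIIa/b/c is ever described), boundary convention is ≥ on the high side of
each cutoff, and the extreme-degrader set is exactly {IIc, IVc} under any
thresholds.

## Triad burden

The pathogenic triad (inflammaging, immune aging, senescent-cell burden)
is tracked by three positive- and three negative-salutogenesis readouts.
The continuous composite is

$$\text{burden} = \overline{\text{neg}}_w - \overline{\text{pos}}_w,$$

weighted means with unit default weights. Because the defining figure is
not available as text, whether the published burden is continuous or
categorical is open; both are implemented — the continuous mode above and
a count mode (number of readouts in their unfavourable median half, 0–6) —
and neither is asserted as canonical. Group contrasts are ordinary linear
models with likelihood-ratio p-values, covering older-vs-younger and
degraded-vs-optimal contrasts in one call.

## Trajectories

Per-subject profile sequences over ≥ 3 ordered timepoints are classified
against an optimal (`H-L`) baseline: all-`H-L` = **preserver**; departure
with final `H-L` = **reconstituter**; non-`H-L` final = **degrader**.
Subjects with a non-optimal baseline get an explicit `not-classifiable`
label rather than silent exclusion — they are analysed separately and
silent drops corrupt denominators. With several intermediate timepoints,
reconstitution is judged by the final state alone (matching the
T0/T1/T6 design); a missing intermediate is ignored, a missing final is an
error because the final state anchors the call. The classifier also
exposes the raw final profile so a finer post-hoc grouping (e.g. splitting
degraders by their final profile) can be layered on.

## Survival and the equivalence age

`fit_ph()` wraps a Cox proportional-hazards fit with Efron tie handling
(standard for moderately tied, year-granular times); delegation to the
mature `survival` package is intentional — the contract, validation, and
downstream statistics are this package's. With log-linear age effect
$\beta_a$ and degraded-group offset $\beta_g$, equating
$h(a^*|\text{optimal}) = h(40|\text{degraded})$ gives

$$a^* = 40 + \beta_g/\beta_a,$$

the **equivalence age**; the **survival gap** $\beta_g/\beta_a$ carries a
delta-method CI (ratio of asymptotically normal coefficients). A numeric
root-finder solves the same hazard-matching equation through the model's
linear predictor and agrees with the closed form to < 0.01 years on
log-linear fits; it exists so non-linear age terms can reuse the
machinery. Log-linear age is the default because it admits the closed
form; whether the published figure used a flexible hazard instead cannot
be settled from the text, and both paths ship. Reference age defaults to
40. Age-stratified HRs are independent fits in half-open bins; empty or
degenerate bins are reported missing rather than failing the table.

## Screens

Benjamini–Hochberg is implemented directly (step-up with cumulative
minima) and cross-checked against the reference implementation in tests.
The linear screen treats each feature as the outcome
(`feature ~ response + covariates`), fitting all features simultaneously
from one QR decomposition of the shared design; for a binary group
contrast this direction is equivalent in screen semantics to the reverse
regression and is the fast, exact choice. The logistic screen puts the
binary response on the left. Octile dose–response uses equal-count
quantile bins with ties assigned to the lower bin (no tie policy is
published; rank-minimum is deterministic). The 2×2 summary reports
row-wise proportions, the odds ratio with Haldane–Anscombe 0.5 correction
only when a zero cell is present, two-sided Fisher exact p (sum of tables
with probability ≤ observed), and χ² without continuity correction.

## The simulator's stated world

Defaults are fixed once, from the cohort conditions the analysis assumes,
and are not tuned against test outcomes:

- **Ages 40–92, uniform**; 55% female; n configurable. This matches the
  adult mortality-cohort span the survival machinery targets.
- **Signature blocks**: factor model — member gene = `√ρ · latent +
  √(1−ρ) · noise`, so within-set correlation is exactly ρ (default 0.3, a
  typical bulk-signature coherence). SAS-cluster latents share a survival
  factor, MAS-cluster latents a mortality factor. Orientation-(−1) members
  load negatively. Gene baselines ~ N(7, 1.5) on the log scale make
  z-scoring a real step.
- **Profile prevalences** default to 0.35/0.15/0.15/0.35. Median splits
  force both marginals to ½ (so H-L and L-H must be equal); the SAS–MAS
  factor correlation is set by inverting the Gaussian quadrant formula,
  ρ = sin(2π(¼ − P(H-L))). With the age drift on, realised prevalences are
  accurate to ~0.015.
- **Age drift**: the survival factor falls and the mortality factor rises
  with age (loading 0.3), with the core factor correlation adjusted so the
  target quadrant probabilities are preserved.
- **TCF7 coupling**: the target log-odds slope of SAS-1-high per TCF7 z
  (default 1.0) is mapped to a latent Gaussian correlation via the
  logit ≈ 1.7 × probit approximation — exact to ~1–2%, verified by
  recovery against the latent truth. Recovery against *measured* strata is
  attenuated ~10% by signature measurement noise, as it would be in real
  data.
- **Survival**: exponential baseline by default (closed-form event
  fraction, used by the tests); Gompertz optional since age already enters
  the linear predictor. Per-year log-hazard slope 0.1467 and degraded
  offset 2.273 (intermediate profiles 0.8) reproduce the headline ~9.7
  hazard ratio and ~15.5-year gap; administrative censoring at 9 years
  with the baseline rate calibrated deterministically to a 20% event
  fraction — equivalently ~80% censored, a configurable guess since the
  source cohort's censoring fraction is not published.
- **Trajectory mix**: 39% degraders (anchored to the published
  post-vaccination degrader fraction), remainder split 0.35/0.26 between
  preservers and reconstituters.
- **IHG grade prevalences**: control-like — 60% grade I (inside the
  published 55–70% control range) and 0.4% combined IIc/IVc (the published
  control rarity); counts are truncated log-normals per grade region, so
  planted grades are recovered exactly.
- **Proteomics**: 1304 proteins with 349 SAS-only, 274 MAS-only, 25
  shared associations (totals 374/299/25), effect 0.8 abundance units per
  score z on unit noise — strong enough that a screen at n = 300 reaches
  ≥ 95% sensitivity.
- **Determinism**: one global seed; every generator draws from a named
  FNV-hash substream, so partial pipelines rerun identically and no
  generator perturbs the caller's RNG.

**What the simulator does not emulate**: raw reads, single-cell data,
assay chemistry, batch effects, non-proportional hazards, informative
censoring, or correlated measurement error between platforms. A green
recovery test therefore establishes that the estimators recover the
parameters of this generative family — not that real cohorts satisfy it.

## Numerical choices

- Sample sd (n−1) in z-scoring; irrelevant to strata (monotone).
- Median = standard midpoint of sorted values; ties at the median are `L`.
- BH q-values clipped at 1; screens validate design rank and name
  collinear columns.
- The exact-overlap recovery test derives discovery sets at q < 10⁻³
  rather than the screening level 0.05: BH at 5% *tolerates* false
  discoveries by construction, so exact set recovery is only meaningful at
  a threshold that excludes them (planted effects sit at q ≪ 10⁻¹⁰).
- Baseline-rate calibration solves the marginal event-fraction equation by
  bisection on the log rate (deterministic, tolerance 10⁻¹⁰).
- `time ≤ 0` after censoring underflow is clamped to the smallest positive
  double (cannot occur with the default horizon).

## Known limitations

- The published gene memberships of the signatures are data, not code:
  tests and the simulator use synthetic placeholder sets; real GMT files
  drop in via `read_gmt()`.
- IHG cutoffs are reconstructed defaults (see above); analyses intended to
  match published grades must supply the published thresholds.
- The equivalence-age CI assumes asymptotic normality of the coefficient
  ratio; for small cohorts, bootstrap the gap instead.
- The logistic screen loops per feature and is O(features × IRLS); it is
  fine at the ~10³-feature scale it is designed for.
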