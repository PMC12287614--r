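---
title: "Two-cutoff thresholds and analytical validation for a high-sensitivity plasma p-Tau 217 immunoassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-cutoff thresholds and analytical validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twocutoff)
```

## The problem

Plasma p-Tau 217 separates amyloid-positive from amyloid-negative
individuals well, but not perfectly: the two concentration distributions
overlap. A single cutoff forces a call on every sample, including the
many that sit in the overlap. The two-cutoff design instead declares a
*lower* cutoff below which a sample is called negative, an *upper* cutoff
above which it is called positive, and an intermediate ("gray") zone in
between where no call is made and confirmatory testing (CSF or PET) is
indicated. Sensitivity, specificity and accuracy are then reported
*excluding* the intermediate zone, alongside the intermediate fraction
itself — the price paid for the higher confidence of the calls that are
made.

`twocutoff` implements this methodology end to end: the analytical
validation statistics a clinical laboratory computes when validating such
an assay (calibration, detection limits, precision, linearity,
interference, stability, cross-reactivity), the threshold-selection
machinery, the clinical performance summaries, and a synthetic-data
module that generates cohorts and bench-run tables with the statistical
structure the analyses assume.

## Group model and the rate scale

Concentrations within each amyloid group are modelled as log-normal,
parameterised by the meanlog μ and sdlog σ ("scale and shape"), fitted by
maximum likelihood (`fit_lognormal()`: μ is the mean of the logs, σ the
population SD of the logs). Thresholds are chosen on the *rate* scale:

* `fn_rate` — the mass of the positive distribution below the lower
  cutoff, `lower = exp(μ⁺ + σ⁺ z(fn))`;
* `fp_rate` — the mass of the negative distribution above the upper
  cutoff, `upper = exp(μ⁻ + σ⁻ z(1 − fp))`.

Note the directions: tolerating a larger false-negative rate *raises* the
lower cutoff, while tolerating a larger false-positive rate *lowers* the
upper cutoff; pairs whose implied `lower > upper` are infeasible and
rejected. Given a rate pair, sensitivity, specificity, the intermediate
fraction and accuracy all have closed forms in the two log-normal CDFs
(`predict_two_cutoff_performance()`), verified in the test suite against
Monte-Carlo classification of 10⁶ draws.

## Threshold optimization

`optimize_thresholds()` performs four steps:

1. **Point-estimate fits** of both group distributions and the observed
   prevalence.
2. **Bootstrap factor ranges** — each group is resampled with replacement
   500 times, a log-normal is fitted to every resample, and the
   25th/75th percentiles of each fitted parameter across resamples give a
   four-factor box (μ⁻, σ⁻, μ⁺, σ⁺). A parametric bootstrap is available
   behind a flag. Group values are sorted before resampling so the result
   is invariant to cohort row order.
3. **A 40-run maximin Latin hypercube** over that box: each factor is
   stratified into 40 equal bins hit exactly once (midpoint placement);
   the pairing is the best of 50 random LHS candidates followed by a
   greedy within-column exchange pass maximising the minimum pairwise
   distance. The specific space-filling construction used by the original
   commercial software is unpublished; maximin LHS is the conventional
   choice and its stratification property is exact by construction.
4. **Desirability averaging** — every rate pair on a grid (default 51 ×
   51, rates 0.002–0.30) is scored at each design setting with a
   Derringer–Suich desirability and the scores averaged across the 40
   settings; the pair with the best average is the robust optimum,
   converted to concentrations via the point-estimate fits.

Whether the original analysis optimised a response-surface model fitted
to the 40 runs or the closed form directly is unknown; we optimise the
closed form directly with robustness averaging, which needs no surrogate
model and is deterministic under a fixed seed.

### Desirability defaults

No targets or weights are published, so the defaults are the package's
own and are configurable (`desirability_spec()`): sensitivity and
specificity maximised with target 0.95 and unacceptable bound 0.85;
intermediate fraction minimised with target 0.15 and unacceptable bound
0.45; equal weights; weighted geometric mean overall, so any metric at
its unacceptable bound vetoes the pair. The 0.85 floor mirrors the
field's ≥90%-accuracy expectation with some slack for the metric
trade-off; the 0.45 ceiling reflects that an intermediate zone near half
the cohort would defeat the purpose of a blood test. For strongly
separated groups, feasible rate pairs exist only at very small rates, and
the candidate grid must be extended into the tails (a log-spaced grid
works well).

## Calibration

The 4PL signal model is `y = d + (a − d) / (1 + (x/c)^b)` with `y(0) = a`
and closed-form inverse `x = c((a−d)/(y−d) − 1)^{1/b}`; signals must lie
strictly between the asymptotes, and interpolations outside the fitted
range are flagged.

**Weighting.** `fit_4pl()` uses 1/y² (relative) least squares by
default. The instrument's weighting scheme is unpublished, and an
unweighted fit was the natural first assumption, but it fails on this
assay's geometry: calibrator signals span ~3.5 decades, so under
constant-CV noise the absolute residuals of the top calibrators are two
orders of magnitude larger than the entire signal of the bottom ones. In
known-truth simulations the unweighted fit leaves the zero-dose asymptote
essentially a free parameter (absolute error comparable to the entire
low-end signal), which in turn destroys back-read recovery of the lowest
calibrator. With 1/y² weighting all four parameters and all back-fit
recoveries are recovered from 2%-CV duplicate data, which is also the
behaviour a laboratory observes in practice. `weighting = "none"` remains
available.

## Detection limits

* **LoB** — EP17 non-parametric 95th percentile of blank measurements:
  rank position `0.5 + 0.95 B`, linear interpolation between order
  statistics, ties kept. Computed per reagent lot; the assay LoB is the
  worst (highest) lot.
* **LoD** — `LoB + Cp · SD_L`, `Cp = 1.645 / (1 − 1/(4(L−J)))`, where
  `SD_L` pools within-sample variances across the low-level samples with
  `nᵢ − 1` weights, samples pooled *across* lots (so J is the number of
  samples; the printed bracketing of the Cp formula is typographically
  unbalanced and the standard EP17 form is used).
* **LLoQ** — the concentration at which a power law `CV% = A·conc^B`,
  fitted to (concentration, replicate CV) points by regression of log CV
  on log concentration, crosses 20% CV: `(20/A)^{1/B}`, per lot, worst
  lot reported. Profiles with all CVs under the threshold or a
  non-negative exponent are flagged "no crossing" rather than forced. The
  *functional* LLoQ multiplies the analytical value by the instrument's
  1:2 sample pre-dilution; LoB and LoD deliberately do not carry this
  factor, as they sit below the reportable range.

**Small-sample CV bias.** A CV estimated from duplicates is severely
biased low: the geometric mean of s/σ for n = 2 is exp(−0.635) ≈ 0.53,
and because the power law is fitted on the log scale this shifts the
fitted 20% crossing down roughly three-fold. `fit_precision_profile()`
therefore subtracts the exact `E[log(s/σ)] = (ψ((n−1)/2) + log 2 −
log(n−1))/2` from each point's log CV by default (`bias_correct = FALSE`
reproduces the naive fit). Even so, a crossing estimated from 18 donors
in duplicate is highly variable — across simulation seeds its 10th–90th
percentile range spans several-fold — which is worth remembering when
comparing single-study LLoQ claims.

## Precision variance components

`variance_components()` decomposes a replicate panel per sample into
between-day, run-within-day and residual components by the ANOVA method
of moments, with Searle's expected-mean-square coefficients so
unbalanced designs are handled (balanced designs reduce to the familiar
multipliers). Instruments, when present, are folded into the day stratum
— a "day" is a distinct instrument × day combination — so the
within-laboratory claim absorbs instrument differences. Negative moment
estimates are clamped to zero (standard EP05 practice). Repeatability is
the residual SD; within-laboratory SD is the root of the summed
components, hence never smaller than repeatability.

## Other analytical summaries

* **Linearity** — expected concentration at mixing ratio r is
  `r·high + (1−r)·low` from the measured endpoint pools; per-level %
  bias, mean signed/absolute bias, and nested F-tests (α = 0.05) of
  quadratic and cubic terms against the linear fit.
* **Dilution recovery** — `100 · measured · factor / neat`, judged
  against 80–120%.
* **Interference** — `100·(spiked − control)/control` per sample, mean
  per interferent at one decimal. The denominator is the control
  measurement; the statistic is *not* antisymmetric under swapping the
  pair, which is documented and tested. A reference spiked/control table
  reconstructed from a published interference study ships with the
  package (`interference_reference()`); note that one printed
  per-interferent mean (conjugated bilirubin) disagrees with the mean of
  its own printed cells in the last decimal, so the package reports the
  recomputed value.
* **Stability** — per-specimen % difference against the −70 °C control,
  mean and two-sided t-interval per condition.
* **Cross-reactivity** — apparent concentration as % of nominal averaged
  over the level series; off-target phospho-peptides judged against 5%,
  the target peptide reported as recovery.

## Clinical performance

Boundary values equal to a cutoff are classed intermediate — the
conservative convention (a boundary result defers to confirmatory
testing); the alternative conventions change results only for exact ties.
Wilson score intervals are used wherever a proportion is interval-ed
(Clopper–Pearson behind a flag); AUC is the Mann–Whitney statistic with
midrank ties and a DeLong-variance normal interval; predictive values
follow the standard Bayes formulas and are swept over a prevalence grid;
group positivity differences use the likelihood-ratio G test.

## The synthetic world

`study_cohort_spec()` encodes the validation-study conditions: 873
symptomatic participants, 56.7% amyloid prevalence, four cohort × split
strata (165/187/281/240). Group medians are 0.046 (negative) and 0.132
pg/mL (positive); the sdlogs 0.638 and 0.545 are obtained by moment
matching to the printed group SDs (0.04, 0.09 pg/mL): for a log-normal
with median m and SD s, `exp(σ²)(exp(σ²) − 1) = s²/m²` is solved for σ.
Labels are drawn Bernoulli-first, then concentrations (mixture sampling);
a quota mode gives exact-prevalence fixtures. Replicate panels add
independent Gaussian instrument/day/run/residual effects clamped at zero;
calibration signals carry multiplicative log-normal noise; the near-LLoQ
panel draws duplicates whose true CV follows the power law crossing 20%
at 0.003 pg/mL. A single seed drives everything through deterministic
per-operation substreams.

What the generator does **not** emulate: digital bead-counting (Poisson
AEB) statistics, comparator (PET/CSF) misclassification, demographic
structure in the concentrations (demographic columns are independent
marginals, cosmetic only), non-log-normal tails, and batch effects. A
green end-to-end test therefore establishes that the pipeline's
statistics are correct *under the stated model*, not that the model
captures every feature of real cohorts. In particular the synthetic
world, with log-normality exact by construction, yields somewhat lower
specificity at the published cutoffs than the real study reported —
overlap in the fitted log-normals is heavier than in the empirical
distributions.

## Numerical choices

Concentrations are kept at full precision internally and rounded only in
reports (one decimal for % metrics, two for fold ratios, 4 significant
figures for concentrations). z-quantiles come from `qnorm` at double
precision. The 4PL optimiser works on log c to keep c positive, with a
port-algorithm `nls` and a Nelder-Mead fallback; degenerate or
non-monotone fits raise explicit fit-failure errors. The LoB percentile
clamps rank positions to the observed range. Desirability ramps are
clipped to [0, 1] and any zero annihilates the geometric mean.

## Limitations

The optimizer explores a rate grid, not a continuum: its optimum is exact
on the grid (verified against exhaustive search) but grid resolution
bounds threshold resolution. The bootstrap factor box covers the truth
with IQR (~50%) coverage by construction — it is a robustness device, not
a confidence region. Published clinical AUC/accuracy values cannot be
reproduced without the raw cohort data, which is not deposited; the
acceptance suite instead verifies worked examples, closed-form identities
against independent oracles, and distribution-level properties of the
synthetic world.
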