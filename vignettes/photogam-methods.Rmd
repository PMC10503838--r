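---
title: "Models and methods behind photogam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photogam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

photogam analyses per-second locomotor traces of larval fish recorded in
multiwell plates under programmable light regimens. This vignette explains
the statistical machinery, the choices that were genuinely open and how they
were settled, and what the synthetic-data generator does and does not
emulate.

## The response and its analysis unit

Raw data are distances moved (mm) per fish per second. The response is the
**rolling sum**: at every second `t`, the total distance over the trailing
60-s window, in mm/min. The window is causal — the first 59 seconds of a
recording are undefined and, under the default regimens, fall inside the
dark acclimation that is never analysed. The trailing convention was an open
choice (a centred window would also be defensible); it was fixed because a
causal window never lets future movement influence the value at `t`.

Individual fish are extremely variable: most seconds are zeros, and the
positive part of the distribution is severely right-skewed. The analysis
unit is therefore the **assay-level group mean**: the mean rolling sum over
the fish of one group (e.g. one genotype) within one assay, at each analysed
second. Repeat (dark-light) assays are analysed at every second;
long-recording baseline assays at one second in thirty.

Two consequences of the rolling window matter for inference and recur below:

1. Adjacent per-second values share 59 of their 60 summands, so residuals on
   a 1-s grid are serially dependent over a ~60-s horizon.
2. Whenever the illumination state switches, the window mixes the two states
   for 60 s, producing a deterministic ramp at the start of every photo
   period that is an artefact of the response definition, not behaviour.

## The additive model

For group-mean series `y` the engine fits the identity-link Gaussian
additive model

```
rsums ~ geno + s(time_s, k, by = geno) + (1 | assay)
```

i.e. parametric (treatment-coded) factor main effects, one penalized smooth
of time per factor level, and a ridge-penalized assay intercept. Baseline
studies replace `geno` by illumination and developmental stage, each with
its own factor-by smooth, with no interaction term. Smooths are cubic
B-splines on equally spaced knots with a second-order difference penalty
(P-splines). This is a deliberate low-rank stand-in for thin-plate
smoothers: the two belong to the same penalized-smoother family, the basis
dimension `k` — not the basis type — is the binding modelling choice, and the
P-spline numerics are simple enough to verify against a dense generalized
ridge solve to 1e-8 (which the test suite does).

Each smooth is centred (sum-to-zero over the observed rows of its level) so
factor main effects stay estimable. The centring leaves the penalty with a
one-dimensional null space (the centred linear trend), so a smooth's
effective degrees of freedom (edf) approach 1, not 0, as its penalty grows;
a constant signal is still fitted exactly by the intercept.

Coefficients minimise `||y - Xb||^2 + sum_j lambda_j b' S_j b`. The
`lambda_j` are chosen by REML (default) or GCV; the basis-dimension defaults
mirror the source protocols (`k = 130` for 1-h repeat assays, `k = 220` and
`1200` for 12-h baselines) and are fully overridable — reduced-scale studies
in this package's tests use smaller `k`, stated below. REML was chosen over
GCV because the assay intercepts are a variance component and REML is the
stabler criterion for such terms; the selection criterion was an open
choice. The log smoothing parameters are optimized by Nelder-Mead with
restarts, clamped to `|log lambda| <= 25` (beyond which the criterion is
flat to machine precision; the clamp turns unbounded ridges, e.g. a smooth
of a constant signal, into plateaus the simplex can terminate on).

Inference uses `sigma2 = RSS / (n - edf_total)` and
`Vb = sigma2 (X'X + S_lambda)^{-1}`. Parametric terms get Wald t-tests on
`df = n - edf_total`; smooth terms get a Wald quadratic form of their
coefficients against the pseudo-inverse of their `Vb` block, referred to an
F with numerator df equal to the rounded term edf. This is a simpler
approximation than the modern penalized-smooth test and is slightly
conservative for heavily penalized terms; it is used consistently
everywhere, including the contrast trajectories.

Model adequacy is checked per smooth: `k_index`, the mean squared
time-adjacent residual difference over twice the residual variance (≈1 for
white residuals, < 1 under unmodelled trend), with a randomization p-value
from residual permutation, plus an edf-saturation flag when the smooth uses
essentially all of its basis. When the residual variance is numerically zero
relative to the response variance (noiseless recovery), the check has
nothing to measure and raises no flags. Competing fits on identical data are
ranked by `AIC = -2 logLik + 2 (edf_total + 1)`.

## Contrast trajectories and period inference

Group comparisons are made on **estimated marginal means**: predictions at a
time point with random effects zeroed and all other parametric factors
averaged with equal weights (the least-squares-means convention; whether the
source analyses used equal or observed-frequency weights is not stated, and
equal weights are the standard default). At every analysed second, all
unordered pairs are compared: `t = (EMM_a - EMM_b) / SE`, with the
Tukey-adjusted p-value `P(Q_{m,df} >= sqrt(2) |t|)` from the studentized
range distribution. For `m = 2` this reduces analytically to the two-sided
t-test and is computed as such.

The adjustment spans the pairs at each second only — **not** the thousands
of seconds. This time-wise multiplicity is a property of the per-second
workflow being reimplemented and is deliberately left uncorrected; an
FDR-over-time correction would change the method. Relatedly, on a 1-s grid
the rolling window makes residuals serially dependent while the model
assumes independence, so per-second tests are anti-conservative (standard
errors understated by roughly the square root of the window length). Both
caveats apply equally to any per-second rolling-sum GAM workflow; results on
a 1-s grid should be read as descriptive trajectories, and calibrated
error rates should be expected only at strides of the window length or more.

The trajectory is then collapsed into the **proportion of significance**: the
fraction of analysed seconds within a named set of photo periods where one
group's EMM exceeds the other's in a fixed, pre-declared direction with
adjusted `p < alpha` (`alpha = 0.05` throughout; the source does not print
its alpha and 0.05 is the conventional default). Seconds significant in the
opposite direction never count. Dark-phase proportions default to the union
of the 3rd-5th dark periods of the 4-cycle protocol and are configurable,
because protocols that omit the terminal dark exist. Proportions from two
regimens are compared with the two-proportion z test with Yates' continuity
correction, computed as the corrected chi-square of the equivalent 2x2
table (the implementation and `chisq.test(..., correct = TRUE)` agree to
1e-9 on random tables).

## The synthetic-data generator

Every downstream stage is testable without recorded data because the
generator produces complete studies with known truth. Per fish and second,

```
movement = Bernoulli(1 - pi_state) * Gamma(shape, scale) * rate(t) * exp(assay_effect)
```

`rate(t)` carries the photoperiod-locked structure: a light/dark baseline
ratio, a brief multiplicative transient after every illumination switch, and
— after each light-to-dark transition — a rebound whose amplitude saturates
in the preceding light duration `d` (minutes) as `s / (s + 1)`,
`s = d / halfsat`, and relaxes exponentially within the dark period.
Genotypes differ only in their dark-state baseline multiplier and their
rebound half-saturation: wild types rebound after ~1 min of light
(`halfsat = 1`), homozygous mutants need ~6 min (`halfsat = 6`) and carry a
basal dark deficit; this mirrors the two findings the analysis is meant to
detect (reduced dark locomotion after short illumination; catch-up with
longer illumination).

Default parameters (chosen once, as plausible for larval zebrafish wells,
and not revisited): zero-movement probability 0.65 in dark and 0.40 in
light; burst Gamma(0.7, scale 2.0 mm); baseline rate multipliers 0.35
(dark) and 1.0 (light); onset transient amplitude 1.0 decaying over 15 s;
rebound ceiling multiplier 2.5 relaxing over 600 s; assay log-SD 0.12; 6
assays x 16 fish per group. These produce group-mean rolling sums of tens of
mm/min, ~60-70% zero seconds per fish in darkness, and strongly
right-skewed positive movement — the qualitative pathology the method
exists to handle.

What the generator does **not** emulate: millisecond startle kinematics,
within-well position, bout structure (seconds are conditionally
independent given the rate), circadian drift, and heteroscedasticity beyond
what the state-dependent rates induce. Passing recovery tests therefore
demonstrate that the pipeline detects the designed-in structure under
realistic marginals — not that real recordings satisfy the model.

Determinism: every well draws from a substream seeded by
`(master seed, assay, well)`, so studies are byte-identical across runs and
generation order, and any single well can be regenerated in isolation.

## Reduced-scale study designs used by the tests

All simulation-based checks run on one CPU at sizes chosen to finish in
minutes; they are stated here as the package's own defaults for its
validation studies.

**Type-I calibration.** 200 null studies (no genotype effect anywhere),
6 assays x 3 genotypes x 16 fish, on a 600-s constant-dark baseline
protocol (2-min acclimation + 8-min analysis), aggregated at a 60-s stride
with `k = 4` per genotype smooth. Two design points deserve emphasis.
First, the stride equals the window length so that errors are independent —
at shorter strides the overlapping windows make the nominal test
anti-conservative, which would confound a calibration check. Second, the
protocol is constant-dark so the mean model is correctly specified: a
dark-light square wave cannot be represented by the `k <= 4` smooth that an
8-point grid admits, and the resulting lack-of-fit inflates the residual
variance and makes the test spuriously conservative. Under this design the
HM main-effect rejection rate at `alpha = 0.05` sits inside the exact
binomial band around 0.05, and the median dark proportion-of-significance
is ~0.

**Rebound recovery.** 25 seeds x 4 regimens (10-min acclimation +
2 x [7.5-min dark + L-min light] + 5-min final dark, L in {2, 4, 6, 7.5}),
WT vs HM at the default mechanism, 6 assays x 12 fish, per-second analysis
with `k = 20`, proportions over the two post-light dark periods. The basis
segment (~135 s) is deliberately coarser than the 60-s window so the smooth
tracks photoperiod plateaus and the rebound but not the window-boundary
ramp; chasing the ramp makes its marginal seconds flip significance
randomly between arms and turns the realized proportion into a noisy
quantity. The HM deficit is detected in every 2-min-light arm, and the
WT-exceeds-HM proportion is monotone non-increasing in light duration.

A known limitation follows from the saturating rebound form: with
half-saturations of 1 and 6 min, the WT-HM rebound gap spans only
0.417 to 0.327 of the ceiling between 2- and 7.5-min illumination, so at
this scale the proportion statistic saturates near 100% for all durations
and the duration effect expresses itself as ties rather than the steep
decline seen in real recordings, whose catch-up is sharper than the
Michaelis form permits. The monotonicity check is accordingly a direction
check, not a magnitude reproduction.

## Numerical and degenerate-input conventions

* Time is 0-based integer seconds; photo periods are half-open
  `[start, end)`, so every second belongs to exactly one period and a
  regimen's end second is out of range.
* Rolling sums are computed as differences of cumulative sums: exact for
  integer input and within 1e-12 relative of the brute-force window sum for
  floating input.
* Fixed smoothing parameters bypass selection entirely and reproduce the
  dense generalized-ridge solution to 1e-8 relative error.
* A zero contrast SE with a zero difference yields `p = 1`; with a nonzero
  difference it is an error (a degenerate design, not a significance).
* A pooled proportion of 0 or 1 makes the two-proportion chi-square 0 with
  `p = 1` and a warning; the continuity correction clips at a zero
  difference.
* Empty assay-by-group cells are dropped with a warning; a missing second in
  a trace is an error naming the well, not a silent gap.

## Reproducibility

`run_pipeline()` executes simulate/ingest → aggregate → fit → contrasts →
proportions → cross-regimen comparison, persists every intermediate
(CSV/JSON) per arm, and writes a run report carrying the seed and a config
hash; identical config and seed give byte-identical artifacts. All
randomness descends from the single master seed.
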