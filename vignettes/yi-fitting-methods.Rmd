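---
title: "Log-odds IVIM fitting: model, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log-odds IVIM fitting: model, estimators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yifit)
```

## The signal models

All b-values are in s/mm² and all diffusion coefficients in mm²/s; the
package never rescales internally (reports that quote 10⁻³ mm²/s do so at
the printing stage only). The two-compartment (bi-exponential) IVIM decay
is

$$S(b) = S_0\left[\mathrm{PF}\,e^{-b D_{fast}} +
(1-\mathrm{PF})\,e^{-b D_{slow}}\right],$$

and the liver's three-compartment extension adds a very fast pool:

$$S(b) = S_0\left[F_{slow}\,e^{-b D_{slow}} + F_{fast}\,e^{-b D_{fast}}
+ F_{vfast}\,e^{-b D_{vfast}}\right], \qquad
F_{slow}+F_{fast}+F_{vfast}=1 .$$

`biex_signal()` and `triex_signal()` evaluate these; `biex_params()` and
`triex_params()` enforce the invariants (fractions in the unit simplex,
rate ordering $D_{slow} < D_{fast} < D_{vfast}$).

## The shifted-start re-parameterization

Restarting the bi-exponential fit at a sampled b-value $b_i$ and
normalizing by $S(b_i)$ leaves the rates untouched but replaces PF with an
apparent fraction

$$\mathrm{PF}_i = \frac{\mathrm{PF}\,e^{-b_i D_{fast}}}
{\mathrm{PF}\,e^{-b_i D_{fast}} + (1-\mathrm{PF})\,e^{-b_i D_{slow}}},$$

which decreases towards zero as $b_i$ grows. Its log-odds
$Y_i = \ln[(1-\mathrm{PF}_i)/\mathrm{PF}_i]$ is exactly linear in $b_i$:
slope $D_{fast}-D_{slow}$, intercept $\ln[(1-\mathrm{PF})/\mathrm{PF}]$.
`shifted_pf()`, `yi_transform()` and `theoretical_yi_line()` are the
closed forms; the property tests assert their mutual consistency to
1e-10 over random parameter draws.

The estimator (`yi_pipeline()`) runs a segmented fit from each grid value
$b_i \in \{2,4,7,10,15,20\}$, regresses $Y_i$ on $b_i$ by unweighted OLS,
and reads off

* `d_fast_yi` = slope + $D_{slow}$ (the high-b estimate, identical across
  grid points because the high-b subset never changes),
* `f_fast` = inverse log-odds of the intercept,
* `f_vfast` = `f_tot` − `f_fast`, with `f_tot` the segmented PF at
  $b_i = 0$ (a flag switches to the full bi- or tri-exponential source).

$b = 0$ is excluded from the line fit: its measured $Y_0$ falls below the
line because the very fast pool inflates $\mathrm{PF}_0$ beyond the
bi-exponential prediction. The point is still evaluated and reported with
an extrapolated residual, which is the package's diagnostic for the very
fast component (negative, largest in magnitude on tri-exponential decays;
including b = 0 in the fit lowers R² — both asserted by tests).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| high-b threshold | 60 (inclusive) | s/mm² | perfusion pools assumed decayed above it; inclusive keeps 7 high-b points on the 16-b scheme |
| starting-b grid | 2, 4, 7, 10, 15, 20 | s/mm² | stops at 20: beyond it PF$_i$ drops towards 0.03 and leaves the quasi-linear zone of the log-odds transform |
| PF validity window | (0.05, 0.4), flag only | — | the log-odds transform is close to linear only there; points outside are flagged (`in_window`) but retained — dropping them shortens the regression's b-range and measurably destabilizes the slope |
| `d_slow` bounds | [1e-4, 3e-3] | mm²/s | liver parenchyma range |
| `d_fast` bounds | [3e-3, 0.5] | mm²/s | disjoint from `d_slow` so the ordering is structural |
| `d_vfast` bounds | [0.1, 10] | mm²/s | disjoint from `d_fast` |
| QC | PF$_i$ ∈ (0.001, 0.6); fits converged; line R² ≥ 0.5 | — | explicit numeric replacement for visual rejection of poor fits |

Nonlinear steps: the one-parameter constrained `D_fast` fit uses Brent
minimization (`stats::optimize`, tolerance 1e-10) over all points with
$b \ge b_i$ — with $D_{slow}$ and PF$_i$ fixed, the high-b residuals are
negligible, so restricting to low b is unnecessary. The full bi- and
tri-exponential fits use bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`, ftol = ptol = 1e-12, ≤1000 iterations) initialized
deterministically (segmented output for the bi-exponential; fractions
(0.7, 0.15, 0.15) and rates (1e-3, 50e-3, 0.5) for the tri-exponential).
Boundary-pinned or non-ordered solutions are flagged `converged = FALSE`.
The tri-exponential fit treats all six parameters as free within bounds
and normalizes the fractions to unit sum afterwards; a 5-parameter variant
with the sum constraint built in is available
(`constrain_fractions = TRUE`). Fitted PF values are clipped into
[1e-6, 1−1e-6] before the log-odds transform (noisy fits can leave
(0, 1)); analytic code paths use the unclipped, erroring transform.

## The exactness limit: what "noiseless" does not mean

On a noiseless bi-exponential curve the segmented fit is *not* exact: at
the canonical liver parameters (PF = 0.2, $D_{slow}$ = 1e-3,
$D_{fast}$ = 50e-3) the fast pool still contributes ≈1% of the signal at
b = 60, biasing the log-linear step's intercept. The resulting PF$_i$
error is ≈0.005 at every starting b-value, and because the bias grows in
log-odds units as PF$_i$ shrinks, it tilts the fitted line: `d_fast_yi`
lands ≈4% above truth and `f_fast` ≈0.005 below PF. The unit tests assert
these computed envelopes rather than idealized zero error. The bias
shrinks rapidly for faster $D_{fast}$ and is dwarfed by noise at realistic
SNR; it is a property of the segmented convention (threshold 60), not of
the log-odds layer.

On tri-exponential input a second, structural limit appears: once the very
fast pool has decayed, the surviving signal is bi-exponential with
fraction $F_{fast}/(1-F_{vfast})$, and that — not $F_{fast}$ itself — is
what the intercept estimates (≈0.174 vs 0.15 at the default fractions).
With the default $D_{vfast}$ = 0.5 mm²/s the pool has only decayed to
$e^{-1}$ by b = 2, so the first grid points absorb part of it and push
`f_fast` higher still (≈0.21) and the slope above $D_{fast}$. The sweep
test shows the estimate approaching the surviving-pool fraction as
$D_{vfast}$ grows. `f_tot` and the decomposition identity
`f_vfast = f_tot − f_fast` are unaffected.

## The synthetic-data generator

`generate_decay()` forward-simulates the tri-exponential model on the
16-b liver scheme (`liver_scheme()`: b = 0, 2, 4, 7, 10, 15, 20, 30, 46,
60, 72, 100, 150, 200, 400, 600 s/mm²; per-b averaging counts 3/2/1 as in
the 3 T protocol, or 2 everywhere as in the 1.5 T protocol). Noise is
applied per excitation to the magnitude — $\sqrt{(s+n_1)^2+n_2^2}$ with
$n_{1,2}\sim N(0, S_0/\mathrm{SNR})$ — and the excitations averaged,
matching scanner magnitude averaging; the closed-form Rician mean
(`rician_mean()`, written with scaled Bessel functions so high SNR cannot
overflow) is the calibration oracle. SNR is defined at b = 0 per
excitation, default 100 for an ROI-mean decay curve.

`generate_cohort()` draws per-subject truths from truncated normal
distributions around healthy-liver means (f_fast 0.150, f_vfast 0.136,
d_slow 1.0e-3, d_fast 55e-3, d_vfast 0.5 mm²/s — the last is not
estimable by these methods and is a literature-scale choice; relative
dispersion 0.2), perturbs the second scan of each pair multiplicatively by
5% (physiological scan–rescan variation), and adds independent noise per
scan. A per-subject seed stream derived from the base seed makes subject k
reproducible independently of cohort size.

What the generator emulates: decay-curve shape, noise-floor bias, per-b
averaging, between-subject spread, paired-scan jitter. What it does not:
motion and pulsation artifacts, ROI placement variability, spatially
correlated noise, echo-time weighting of compartments, field-strength
effects. Crucially, its noise is *independent across b-values*, whereas
in-vivo ROI-mean curves are dominated by scan-level, across-b correlated
physiological error. Consequences below.

## What the simulation does and does not reproduce

With the prescribed conditions (SNR 100, Rician, 100 subjects × 2 scans)
the acceptance script reproduces the in-vivo ordering for the
three-compartment fractions: the log-odds route gives smaller wSD and
higher ICC for `f_fast` and `f_vfast` than direct tri-exponential fitting,
with near-identical means for `f_tot`.

For `d_fast` it does not: the simulated CoV and wSD of `d_fast_yi` come
out *above* those of the conventional segmented fit (started at b = 2 —
the baseline whose means match the conventional column of the published
comparison; a b = 0 start yields a composite of the fast and very fast
rates with a much higher mean). The mechanism is visible in single scans:
each PF$_i$ carries the independent noise of its own normalization
$S(b_i)$, and the log-odds transform amplifies that noise hyperbolically
as PF$_i$ → 0, so the $b_i$ = 15–20 points occasionally swing the slope
hard. In-vivo decay curves, whose dominant errors are shared across the
$Y_i$ series, favour the pooled estimator; independent per-b noise
penalizes it. The simulated comparison is therefore reported as computed,
in both directions, rather than tuned to match — and the noise model's
independence assumption should be kept in mind when reading it.

```{r stability, eval = FALSE}
# the acceptance-script comparison, at desk scale
coh <- generate_cohort(cohort_spec(n_subjects = 100, seed = 1))
res <- apply_qc(fit_scans(coh, methods = c("segmented", "yi", "triex")))
method_comparison(res[res$parameter == "d_fast", ])
method_comparison(res[res$parameter %in% c("f_fast", "f_vfast", "f_tot"), ])
```

## Repeatability statistics

`cv()` uses the n−1 sample SD over all scans; `wsd()` is
$\sqrt{\sum d_i^2 / 2n}$ over pairs (the two-scan ANOVA form is
identical); `bland_altman()` uses the conventional 1.96 multiplier rather
than a t-quantile; `icc()` defaults to the two-way random-effects,
absolute-agreement, single-measurement form ICC(2,1) — the standard choice
for scan–rescan designs — computed from the mean-squares decomposition,
with the consistency form ICC(3,1) by flag; all-equal input returns 1 with
a `degenerate` flag. The test suite checks every statistic against an
independent `stats::aov`-based oracle and asserts scale/translation
invariances on random fixtures.

## Degenerate inputs and tie-breaks

Constant signal: the high-b slope is 0, the constrained `D_fast` step pins
at its lower bound, the scan fails QC without error. PF$_i$ outside (0, 1)
after a noisy fit: the point is marked invalid and excluded from the line
fit (clipping alone would produce |Y| ≈ 14 artifacts). Fewer than 3 valid
grid points: insufficient-data error, surfaced as a QC failure at cohort
level. Negative raw `f_vfast`: clipped to 0 and flagged, the raw value
retained. Equal rates ($D_{fast}=D_{slow}$): allowed in the signal model
(mono-exponential collapse) but rejected where the log-odds line needs a
non-zero slope.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen to keep the
statistics stable: 100-subject × 2-scan cohorts for the Monte-Carlo
comparisons, 100-draw parameter sweeps for the closed-form oracles, and
10⁴ replicates for the noise-calibration checks.

## Known limitations

* Nominal b-values are treated as exact; no effective-b correction.
* The segmented high-b step's contamination bias (above) caps noiseless
  accuracy at ≈0.005 in PF and a few percent in `d_fast_yi`.
* The intercept estimates $F_{fast}/(1-F_{vfast})$, not $F_{fast}$; the
  distinction matters once $F_{vfast}$ exceeds ≈0.1.
* $D_{vfast}$ is not estimated (by design), and the simulator's default
  for it is a placeholder.
* The Y$_i$ regression is unweighted even though high-$b_i$ points are
  noisier; no errors-in-variables correction.
* Scan-level QC thresholds (R² floor, PF window) are explicit but
  heuristic stand-ins for visual quality review.
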