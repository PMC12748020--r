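# yifit

Stabilized liver IVIM fitting via log-odds linearization of the perfusion
fraction.

## The problem

Intravoxel incoherent motion (IVIM) diffusion MRI separates molecular
diffusion from perfusion-driven pseudo-diffusion in a single voxel or ROI.
The standard two-compartment model is

```
S(b) = S0 [ PF exp(-b D_fast) + (1 - PF) exp(-b D_slow) ]
```

with the perfusion fraction `PF`, molecular diffusion `D_slow` and
pseudo-diffusion `D_fast` (mm²/s; b in s/mm²). In liver, a third, very fast
compartment makes the decay tri-exponential:

```
S(b) = S0 [ F_slow exp(-b D_slow) + F_fast exp(-b D_fast)
            + F_vfast exp(-b D_vfast) ]
```

Direct tri-exponential fitting is unstable, and `D_fast` is notoriously
irreproducible even in the two-compartment model. `yifit` implements an
estimator built on a re-parameterization: starting the bi-exponential fit
at `b_i` instead of 0 leaves the curve bi-exponential with the same rates
but an apparent perfusion fraction

```
PF_i = PF exp(-b_i D_fast) / [ PF exp(-b_i D_fast) + (1 - PF) exp(-b_i D_slow) ]
```

whose log-odds is exactly linear in the starting b-value:

```
Y_i = ln[(1 - PF_i) / PF_i] = b_i (D_fast - D_slow) + ln[(1 - PF) / PF]
```

Repeating a segmented fit from `b_i = 2, 4, 7, 10, 15, 20` s/mm² and
regressing `Y_i` on `b_i` therefore gives:

* **slope** → `D_fast - D_slow`, hence a `D_fast` estimate weighted over
  many b-values rather than pinned to one starting point;
* **intercept** → the log-odds of the perfusion fraction predicted by the
  bi-exponential model at b = 0. Because the very fast pool decays before
  the first grid point, this is the fast fraction `F_fast` with the very
  fast component excluded;
* `F_tot` (a conventional fit from b = 0) minus `F_fast` → `F_vfast`.

Three tri-exponential-model fractions are obtained without a
tri-exponential fit. The package also provides the conventional baselines
(segmented, full bi-exponential, full tri-exponential NLLSQ), a
tri-exponential decay simulator with Rician noise and per-b signal
averaging on the 16-b liver scheme, paired scan–rescan cohort generation,
voxelwise parameter maps, and the repeatability statistics used to compare
estimators (CoV, within-subject SD, Bland–Altman limits, ICC).

It is aimed at quantitative-MRI researchers working with liver (or other
abdominal) IVIM decay data, either as ROI-mean decay tables (CSV) or as 4D
NIfTI volumes with an FSL-style `.bval` file and an ROI mask.

## Worked example

Simulate one noisy liver scan on the 16-b-value scheme and run the
estimator:

```r
library(yifit)

sch   <- liver_scheme()                      # b = 0 ... 600 s/mm², printed NSA
truth <- triex_params(f_slow = 0.71, f_fast = 0.15, f_vfast = 0.14,
                      d_slow = 1e-3, d_fast = 50e-3, d_vfast = 0.5)
scan  <- generate_decay(truth, sch, noise_model(snr = 100), seed = 42)

fit <- yi_pipeline(scan)
fit
#> <yi_fit>
#> <yi_regression> slope = 0.0757 mm^2/s, intercept = 1.3219, R^2 = 0.8832 (6 points)
#>   d_fast_yi = 0.07673 mm^2/s, f_fast = 0.2105, f_tot = 0.2911, f_vfast = 0.0806
#>   QC: pass
```

The slope of the log-odds line plus the high-b `D_slow` gives
`d_fast_yi = 0.077` mm²/s; the intercept maps back through the inverse
log-odds to `f_fast = 0.21`; the segmented fit from b = 0 supplies
`f_tot = 0.29`, so `f_vfast = 0.08`. (At this noise level the very fast
pool, which has not fully decayed by b = 2–4, still leaks into the slope
and intercept — the methods vignette quantifies this.) Results are tidy:

```r
tidy(fit)
#> # A tibble: 5 × 2
#>   term      estimate
#> 1 d_slow     0.00103
#> 2 d_fast_yi  0.0767
#> 3 f_fast     0.210
#> 4 f_tot      0.291
#> 5 f_vfast    0.0806
glance(fit)      # slope, intercept, R², n_fit, qc_pass
autoplot(fit)    # Y_i points, fitted line, excluded b = 0 point
```

Cohort-level comparison of estimators:

```r
coh <- generate_cohort(cohort_spec(n_subjects = 17, seed = 7))
res <- apply_qc(fit_scans(coh, methods = c("segmented", "yi", "triex")))
method_comparison(res[res$parameter == "f_fast", ])
# one row per method: mean, CoV, wSD, Bland-Altman limits, ICC
```

A thin command-line wrapper over the same functions ships in
`inst/cli/yifit` (subcommands `simulate`, `fit`, `yi`, `map`, `repro`).

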