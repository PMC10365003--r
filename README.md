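# t2star

Quantification of tissue iron from multi-echo gradient-echo MRI by T2\*
relaxometry, for radiologists and imaging scientists monitoring iron
overload in regularly transfused patients (thalassemia major and related
haemoglobinopathies). Iron shortens the effective transverse relaxation
time, so a low organ T2\* means a heavy iron load; clinical practice grades
heart, liver and pancreas T2\* into severity categories that steer iron
chelation therapy.

## The model

The mean signal intensity *y* of a region of interest (or of a single
pixel), measured at each echo time TE of a multi-echo gradient-echo
acquisition, follows a mono-exponential decay

```
y(TE) = K · exp(−TE / T2*)
```

with amplitude `K` and relaxation time `T2*` (ms). The package estimates
`(K, T2*)` by log-linear initialisation followed by Levenberg–Marquardt
nonlinear least squares on the signal scale.

Magnitude reconstruction rectifies background noise, so at long TE the
measured signal flattens onto a Rician noise floor instead of decaying to
zero. Fitting that plateau inflates T2\* — badly enough to turn a severely
iron-loaded liver into an apparently mild one. `truncated_fit()` therefore
removes echoes from the long-TE end while the fit's r² is below a threshold
(default 0.995) *and* each removal improves r²: a genuine noise floor is
discarded, while slow-decaying but merely noisy series are left intact.

On top of the fitting layer the package provides pixel-wise T2\* parametric
maps with RGB rendering, severity grading with configurable
literature-based thresholds, and cohort statistics (Spearman rank
correlations with weak/moderate/strong magnitude labels, loess scatter
smoothing, paired method-agreement confidence intervals, summary tables).
A synthetic-data module generates Rician-noise decay curves, 2-D multi-echo
phantoms and rank-correlated patient cohorts so the whole chain can be
validated against known ground truth.

## Worked example

```r
library(t2star)
tes <- default_echo_train()   # TE 0.8, 1.8, ..., 9.8 ms

# severely iron-loaded liver (T2* = 1 ms) with a rectified-noise plateau
series <- simulate_decay(tes, decay_params(K = 1000, T2star = 1,
                                           noise_floor = 50, sigma = 9),
                         seed = 42)
fit_monoexp(series)    # naive fit over all 10 echoes
#> <t2_fit> T2* = 1.525 ms, K = 829.6, r^2 = 0.90638, echoes 10/10
truncated_fit(series)  # automated truncation
#> <t2_fit> T2* = 1.224 ms, K = 977.9, r^2 = 0.99497, echoes 3/10 (truncated)
```

The naive fit absorbs the noise floor and overestimates T2\* by 50%; the
truncated fit keeps the three early echoes and lands within 25% of the
truth. The error is clinically meaningful: with the default liver
thresholds (severe < 1.4 < moderate < 2.7 < mild < 6.3 < normal ms) the
naive estimate grades as `moderate` while the truncated estimate correctly
grades `severe`.

```r
cohort <- simulate_cohort(cohort_spec(39), seed = 42)
table(grade_cohort(cohort)$pancreas_grade)
#>   normal     mild moderate   severe
#>        7        4       18       10
spearman_cor(cohort$t2s_pancreas_ms, cohort$t2s_heart_ms)
#> <t2_correlation> r = 0.577 (moderate), p = 0.0001216, n = 39
```

The simulated 39-patient cohort draws organ T2\* and ferritin from
log-normal marginals through a Gaussian copula with a prescribed Spearman
correlation structure (pancreas–heart 0.504 by default), so cohort-level
statistics can be checked against the values the generator was told to
produce.

`run_pipeline()` executes the full chain on on-disk NIfTI stacks: per
patient a truncated ROI fit, a pixel-wise map (NIfTI + PNG), severity
grades, plus provenance-stamped cohort CSVs and a JSON run log. A thin CLI
(`inst/cli/t2star-cli`) exposes the same steps as shell subcommands.

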