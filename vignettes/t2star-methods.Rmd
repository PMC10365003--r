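---
title: "Methods: T2* relaxometry, truncation, and cohort simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: T2* relaxometry, truncation, and cohort simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2star)
```

## The signal model

Multi-echo gradient-echo imaging samples the transverse magnetisation decay
at a train of echo times. For magnitude images the mean ROI signal follows

$$y(\mathrm{TE}) = K\, e^{-\mathrm{TE}/T_2^*},$$

where $K$ (arbitrary units) absorbs proton density, coil sensitivity and
$T_1$ weighting, and $T_2^*$ (ms) is the effective transverse relaxation
time. Tissue iron creates microscopic field inhomogeneities that shorten
$T_2^*$, which is why organ $T_2^*$ is the standard non-invasive proxy for
iron load: heavily loaded livers reach well under 1.4 ms, while a healthy
myocardium sits above 20 ms.

The model assumes a mono-exponential decay (single tissue compartment, no
fat–water modulation), magnitude data, and an echo train short enough that
$T_1$ recovery between echoes is negligible. Bi-exponential and
noise-corrected (Rician-likelihood) models are deliberately out of scope;
so is $R_2^* = 1000/T_2^*$ reporting, which callers can derive trivially.

## Fitting

`fit_monoexp()` estimates $(K, T_2^*)$ in two stages:

1. **Log-linear initialisation.** Ordinary least squares of $\log y$ on TE
   over the strictly positive signals. Non-positive signals (possible after
   background subtraction upstream) are excluded here but retained in stage
   2. A non-negative slope means the series does not decay; this is
   reported as a degenerate-fit error rather than a fabricated estimate.
2. **Nonlinear refinement.** Unweighted Levenberg–Marquardt least squares
   on the original signal scale (`minpack.lm::nlsLM`, positivity bounds on
   both parameters, 200 iterations). The log-scale fit alone would weight
   the low-signal tail — exactly the echoes most corrupted by noise — far
   too heavily; the signal-scale fit weights echoes by their actual
   amplitude.

If the optimiser fails to converge the log-linear estimate is returned with
`converged = FALSE` — logged in the result, never silent. $r^2$ is computed
on the signal scale, so $r^2 = 1$ (within $10^{-9}$) exactly when the
retained points lie on one exponential. At least 3 echoes, 3 of them
positive, are required; scale-equivariance ($T_2^*$ invariant, $K$ linear
under global rescaling) holds to $10^{-9}$ on noiseless data.

## The noise floor and automated truncation

Magnitude reconstruction maps complex Gaussian noise into a Rician
distribution: where true signal remains, noise is approximately additive;
where it has decayed away, the measured magnitude flattens onto a Rayleigh
plateau with mean $\sigma\sqrt{\pi/2}$. Fitting that plateau biases $T_2^*$
upward — in short-$T_2^*$ organs by enough to shift the severity grade by
two categories, i.e. to misclassify a severe liver as mild.

`truncated_fit()` automates the manual remedy of discarding long-TE images.
The policy (`truncation_policy()`) removes the longest-TE echo and refits
while

* the current $r^2$ is below `r2_threshold` (default 0.995),
* more than `min_echoes` (default 3) would remain and fewer than `max_drop`
  echoes have been dropped, and
* the removal **improves** $r^2$ (`require_improvement`, default on).

The improvement gate is the package's own design choice, made because a
bare $r^2$ threshold cannot distinguish two very different reasons for a
mediocre fit. A noise-floor plateau is *structural* lack of fit: dropping
plateau echoes improves $r^2$ sharply, and the loop keeps going until the
plateau is gone. A slow decay measured over a short echo train (e.g.
$T_2^* = 20$–40 ms sampled to 9.8 ms) has a small decay range relative to
its noise, so $r^2$ stays modest *no matter how many echoes are dropped* —
and dropping them only destroys the conditioning of the slope estimate.
Under a bare threshold rule such series truncate to the minimum and the
median $T_2^*$ error at the long end grows to tens of percent; with the
gate they are left at full length. The validation suite quantifies this:
over $T_2^* \in \{1, 2, 5, 10, 20, 40\}$ ms at first-echo SNR 50 (200
replicates each, the problem size used throughout), the pooled median
relative error with truncation stays below 5%.

The threshold 0.995 itself says "accept a fit that explains all but 0.5% of
the signal variance"; on a clean 10-echo liver series it is reached without
any truncation, while a contaminated short-$T_2^*$ series typically
truncates to 3–5 echoes. The exact criterion used by deployed truncation
tools is not published; the policy object keeps the rule configurable so an
alternative (e.g. signal-below-noise-estimate) can be added without
touching the fitter.

Degenerate cases during truncation (a candidate refit that fails) stop the
loop and keep the last successful fit; the loop therefore never returns
fewer than `min_echoes` echoes and never fabricates an estimate.

## Pixel-wise mapping

`pixelwise_fit()` applies the same fitter (optionally the same truncation
policy) to every in-mask pixel independently and assembles a parametric
map. Pixels whose course cannot be fitted — rising signal, too few positive
echoes, optimiser failure — are marked invalid, excluded from ROI means,
and counted, never interpolated. On a noiseless uniform phantom the
pixel-wise values, the map ROI mean and the ROI-mean-then-fit route agree
to a relative $10^{-9}$; on noisy data the two routes differ because the
mean of per-pixel estimates is not the estimate on the mean signal — the
same reason ROI-based and pixel-based clinical software disagree on real
patients.

`render_map()` uses a fixed blue-to-red ramp (dark blue = short $T_2^*$ =
heavy iron) linearly over a configurable scale, clipped at the ends,
invalid pixels in reserved grey. Default scales span the clinically
relevant ranges: 0–20 ms for liver and pancreas, 0–50 ms for heart.
Rendering is deterministic (byte-identical PNG for identical maps).

## Severity grading

`classify()` maps $T_2^*$ onto ordered categories through three per-organ
boundaries: severe $< b_s$, moderate $[b_s, b_m)$, mild $[b_m, b_n)$,
normal $\geq b_n$. A boundary value belongs to the less-severe side — the
conservative convention, chosen because grading drives chelation
intensification and a patient exactly at a boundary should not be
over-treated by rounding. The shipped defaults (heart 10/14/20 ms, liver
1.4/2.7/6.3 ms, pancreas 10/20/26 ms) are commonly used literature values;
they live in a YAML-serialisable configuration precisely because published
cohorts rarely state their exact cut-offs and local practice varies. The
pancreas deserves a caveat: bowel-gas susceptibility can artificially lower
pancreatic $T_2^*$, but not below 10 ms, which is why 10 ms is a robust cut
for significant pancreatic overload and why values just under the normal
boundary should be read with the acquisition in mind.

## The synthetic-data generator

The generator exists so every downstream stage can be tested against known
ground truth; its defaults are fixed study conditions, not tuning knobs.

**Decay curves** (`simulate_decay()`): noiseless part
$K e^{-\mathrm{TE}/T_2^*} + \mathrm{floor}$, then Rician noise as the
magnitude of two independent Gaussian channels of SD $\sigma$. The explicit
`noise_floor` parameter produces deterministic plateau contamination for
truncation tests; with $\sigma > 0$ alone the plateau emerges naturally at
long TE. The default echo train mirrors a 1.5 T abdominal protocol: first
TE 0.8 ms, spacing 1.0 ms, 10 echoes.

**Phantoms** (`simulate_phantom()`): disjoint 2-D regions with their own
decay parameters and independent per-pixel noise; background pixels are
pure noise magnitude (Rayleigh). No anatomical realism is attempted — no
organ shapes, motion, flow or fat; passing phantom tests therefore
validates the estimator chain, not robustness to acquisition artifacts.

**Cohorts** (`simulate_cohort()`): a Gaussian copula draws latent normals
with Pearson correlation $2\sin(\pi\rho_s/6)$ — the exact conversion from
a target Spearman $\rho_s$ for a bivariate normal — then maps them through
each variable's marginal quantile function. Specifying *rank* correlation
directly makes Spearman recovery the natural test target and is invariant
to the (monotone) marginal transforms. Default marginals are log-normals
moment-matched to a transfusion-dependent thalassemia-major profile (liver
3.84 ± 3.49 ms, pancreas 18.28 ± 13.98 ms, heart 32.04 ± 14.94 ms,
ferritin 4640.75 ± 4821.93 ng/dl) — right-skewed, strictly positive, and
heavy-tailed for ferritin, which is what such cohorts look like; the
default rank-correlation structure (pancreas–heart 0.504, weak organ–liver
correlations, negative ferritin–organ correlations) matches the same
profile. The converted latent matrix is checked for positive
semidefiniteness and factorised by symmetric eigendecomposition, so a
comonotone specification ($\rho_s = 1$) is handled exactly. Demographics
(`age`, `sex`) are independent of the copula. The generator does not model
measurement error of the fitting stage, missingness, or the longitudinal
dependence of repeat scans.

## Statistical layer

* **Spearman** (`spearman_cor()`): Pearson correlation of average ranks
  over pairwise-complete pairs; perfectly concordant/discordant rankings
  return exactly ±1. Two-sided p via the t approximation
  $t = r\sqrt{(n-2)/(1-r^2)}$; for $n \le 10$ untied samples an exact
  permutation p is available behind `exact = TRUE`. Missing values are
  deleted pairwise for correlations and listwise within a summary row.
* **Magnitude labels** (`classify_magnitude()`): $|r| < 0.4$ weak,
  $0.4 \le |r| \le 0.6$ moderate, $|r| > 0.6$ strong. The band edges are
  assigned inclusively to the moderate band, consistent with labelling
  coefficients of 0.504 and 0.595 as moderate.
* **Loess** (`loess_smooth()`): degree-1 locally weighted regression with
  tricube weights and no robustness iterations, default span 0.75. The
  bandwidth at each point is the distance to the $\lceil \text{span}\cdot
  n\rceil$-th nearest observation. The ceiling convention was chosen over
  the more common floor because it makes the fit *exactly* invariant under
  duplicating the dataset (each point twice doubles every weight and leaves
  the bandwidth unchanged), a property the test suite asserts; when
  $\text{span}\cdot n$ is an integer the two conventions coincide and the
  implementation agrees with `stats::loess(surface = "direct")` to machine
  precision, which the suite uses as an independent cross-check.
* **Method agreement** (`method_agreement()`): mean paired difference with
  a two-sided paired-t CI (default 95%). Zero-variance differences yield a
  degenerate CI rather than an error, so identical methods compare cleanly.
* **Summaries** (`summarize_cohort()`, `summarize_severity_counts()`):
  mean, SD ($n-1$), median, min, max for continuous variables; counts and
  percentages for categoricals. Percentages are rounded to one decimal
  *half away from zero* — the convention that reproduces 82.1% from 32/39 —
  not banker's rounding.

## Pipeline and reproducibility

`run_pipeline()` runs read → truncated ROI fit → pixel map → grades per
patient, continues past per-patient failures (recording them), and stamps
every CSV with a configuration hash and the seed. All randomness flows from
explicit seeds; seeded simulation restores the ambient RNG state. Two runs
of one configuration are byte-identical on their CSV outputs. Stacks travel
as 4-D NIfTI (x, y, 1, echo) with a JSON sidecar listing echo times in ms —
a portable, PHI-free format; DICOM input is not supported in this version,
so scanner exports must be converted to NIfTI upstream.

## Validation problem sizes

The shipped validation suite uses: 200 replicates per $T_2^*$ grid point
for recovery; 500 replicates of the floor-contaminated short-$T_2^*$
condition ($T_2^* = 1$ ms, floor 50 a.u., first-echo SNR 50) for the
truncation-benefit rate; $10\times10$ to $16\times16$ phantoms for the
mapping equivalences; and 20 cohorts of $n = 5000$ for rank-correlation
recovery (per-seed sampling SD ≈ 0.011, so the Monte-Carlo mean pins the
recovered coefficient well inside ±0.03 of the target). These sizes make
each Monte-Carlo bound comfortably stable under reasonable seeds.

## Known limitations

* Mono-exponential only; fat–water modulation and bi-exponential decay in
  steatotic or mixed tissue are not modelled.
* Unweighted least squares; no Rician-likelihood correction, so truncation
  is the only defence against the noise floor.
* The truncation criterion of deployed clinical tools is unpublished; the
  default policy reproduces the *behaviour* (drop floor-dominated long-TE
  echoes) but is not a vendor clone.
* Grading thresholds are configuration with literature-based defaults, not
  validated constants.
* ROI masks are inputs; no automatic segmentation is provided, and the
  synthetic phantoms cannot exercise observer variability in ROI placement.
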