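---
title: "Methods: the exponential lung-weight reference model and its error budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the exponential lung-weight reference model and its error budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piglung)
```

## The problem

In porcine models of ARDS and ventilator-induced lung injury, lung weight
gain is the canonical measure of pulmonary edema. Animals arriving from
farms span roughly 16–52 kg, and relative lung size falls with body mass:
a healthy 20 kg pig carries about 15.8 g of lung per kg of body weight, a
40 kg pig only about 9.5 g/kg. Dividing a damaged lung weight by body
weight therefore makes the same relative injury look markedly worse in the
smaller animal. The remedy is to normalize by the *expected normal lung
weight* instead, which requires a reference equation from body weight to
normal lung weight — the model this package implements.

## The model

The lung weight index (LWI, g/kg) is modeled as a base-10 exponential in
body weight (BW, kg):

$$\mathrm{LWI}(\mathrm{BW}) = a \cdot 10^{\,b \cdot \mathrm{BW}}$$

- `a` (g/kg): the index extrapolated to zero body weight; reference value
  26.26 g/kg.
- `b` (1/kg): the base-10 decay coefficient; reference value −0.011 kg⁻¹,
  i.e. the index falls by a factor $10^{0.011} \approx 2.6\%$ per kg.

The reference parameters, their 95 % interval end points
(a: 23.44–28.84 g/kg; b: −0.013 to −0.009 kg⁻¹) and the derived band
curves are bundled in `pig_reference_model()` / `pig_reference_fit()`.
Expected normal lung weight is $\mathrm{LWI}(\mathrm{BW}) \cdot
\mathrm{BW}$, e.g. 316 g at 20 kg and 381 g at 40 kg.

### Why fit on the log10 scale

`fit_lwi()` estimates the parameters by ordinary least squares of
$\log_{10}(\mathrm{LWI})$ on BW; `a` is the back-transformed intercept.
Two reasons:

1. Biological scatter in relative organ size is multiplicative: animals
   deviate from the curve by a roughly constant *fraction*, not a constant
   number of g/kg. On the log scale the noise is close to homoscedastic and
   the linear model's confidence intervals are valid.
2. Residual summaries of order 0.05–0.07 are only dimensionally sensible as
   log10-scale quantities given indices of 9–16 g/kg; the package reports
   `rmse_log10` and `mae_log10` on that scale throughout.

A natural-scale nonlinear least-squares engine (`engine = "nls"`, started
from the log-linear solution with asymptotic intervals and a `scaleOffset`
so exact fits converge) is available for sensitivity analysis but is not
the default.

### The confidence band is parameter-wise

`band_upper` pairs the upper confidence bounds of `a` and `b`; `band_lower`
pairs the lower bounds. This mirrors how the reference band curves are
published and keeps each band a *bona fide* model of the same exponential
family, so it can be evaluated, plotted and fed to the error-bound
machinery like any other model. It is **not** a pointwise prediction
interval: it brackets the fitted curve (asserted on a grid in the tests),
but its coverage for a new animal is not 95 %. The object records the
construction so downstream consumers are not misled.

## Train/validation splitting and cross-validation

`split_cohort()` draws a random partition with training size
`floor(n * train_fraction)`. The floor convention is deliberate: it yields
the canonical 141/36 split of a 177-animal cohort at 80/20 and 159/18 at
90/10, whereas round-to-even would give 142/35. `cross_validate_lwi()`
implements standard k-fold with `k = 5` by default — a conventional choice
giving ~113-animal training folds at the canonical cohort size, large
enough that each fold's fit is stable.

## Bland–Altman agreement

`bland_altman()` fixes the difference direction as measured − expected, so
a negative bias means measured indices fall below the model's expectation.
With $d_i$ the paired differences, $\bar d$ their mean and $s$ their sample
SD (n − 1 denominator):

- limits of agreement: $\bar d \pm 1.96\,s$ — the multiplier is the fixed
  normal quantile 1.96, not a t quantile;
- CI of the bias: $\bar d \pm t_{0.975,\,n-1}\, s/\sqrt{n}$;
- CI of each LOA: $\mathrm{LOA} \pm t_{0.975,\,n-1}\, s\sqrt{3/n}$, the
  classical large-sample variance approximation
  $\mathrm{Var}(\mathrm{LOA}) \approx s^2(1/n + 1.96^2/(2(n-1))) \approx 3s^2/n$.

These exact choices reproduce published interval bounds from summary
statistics alone (`agreement_intervals()`), which the test suite exercises.
No regression of differences on pair means is performed; the pair means are
exported for plotting only.

## The normalization-error framework

If an injury multiplies the normal lung weight by a factor $f$, then under
body-weight normalization two animals with body weights $BW_1 < BW_2$ show
indices $f\cdot\mathrm{LWI}(BW_1) > f\cdot\mathrm{LWI}(BW_2)$, and the
apparent excess damage in the smaller animal,
$(\mathrm{idx}_1-\mathrm{idx}_2)/\mathrm{idx}_1$, is independent of $f$ (it
cancels; `naive_normalization_discrepancy()` asserts this numerically). For
20 vs 40 kg the discrepancy is ≈ 40 %.

Under expected-weight normalization the error comes only from the
uncertainty of the reference curve. `error_bounds_curve()` evaluates the
worst case at the band end-point curves: using the upper band as the
expected weight underestimates damage, the lower band overestimates it, and
`damage_estimation_error()` returns the signed fraction
$((\mathrm{measured}/\mathrm{expected}) - f)/f$. Errors are evaluated *at
the band end points only* — not optimized over the joint parameter
confidence region — matching how the published worst-case figures were
constructed, and their magnitudes are again independent of $f$. Published
worst-case expected weights are accepted as explicit inputs rather than
silently recomputed from the band curves, because the two differ slightly
(a few grams at 20/40 kg); this keeps both the printed arithmetic and the
band-derived values reproducible, and the package reports the latter
separately.

## The synthetic cohort generator

`simulate_cohort()` defines the study conditions under which the package is
tested, since the original 177-animal cohort is not redistributable:

- body weights uniform on 16.5–52 kg — the documented range of the source
  cohort; the true zoometric distribution is unpublished, so no attempt is
  made to match its shape;
- $\log_{10}(\mathrm{LWI}_i) = \log_{10} a + b\,BW_i + \varepsilon_i$ with
  $\varepsilon_i \sim N(0, \sigma)$, default $\sigma = 0.068$, the
  training-cohort residual RMSE of the reference fit. Multiplicative noise
  guarantees positive lung weights and matches the scale on which the
  reference RMSE is defined;
- a single noise level for CT- and scale-weighed animals (no published
  evidence distinguishes their dispersions); the `method` label is carried
  but not modeled;
- seeds are mandatory in every stochastic function and the global random
  state is never touched (`withr::with_seed`), so identical inputs give
  bitwise-identical cohorts.

One consequence worth recording: with log-normal multiplicative noise the
natural-scale difference measured − expected has a small *positive* mean,
$E[\mathrm{LWI}]\,(e^{(\sigma \ln 10)^2/2}-1) \approx 0.14$ g/kg at
$\sigma = 0.068$ — symmetric noise on the log scale is not symmetric on the
g/kg scale. The agreement tests assert this analytic value rather than a
zero bias.

What the generator does **not** emulate: the multi-study provenance of the
real cohort (batch effects between the 12 source studies), any CT-vs-scale
systematic offset, measurement error in body weight, and any non-uniform
body-weight distribution. Passing tests therefore demonstrate correctness
of the estimators under the stated noise model, not robustness to those
real-data features.

## CT densitometry

`lung_weight_ct()` implements the linear air–tissue mixture: a voxel's
tissue fraction is $1 - \mathrm{HU}/(-1000)$, anchored at −1000 HU (pure
gas, fraction 0), 0 HU (water-equivalent tissue, fraction 1) and +1000 HU
(bone, fraction 2). Tissue density is fixed at 1 g/cm³, so tissue volume in
cm³ equals tissue weight in grams; voxel volume is accepted in mm³ (the
validated acquisition used 1.8 mm³) and converted internally. Values
outside [−1000, 1000] HU are clamped to the end points rather than
rejected — scanners do emit such values — and the clamped-voxel count is
returned and messaged. Lung masks are inputs, not computed: excluding
airways, large vessels and bone is a segmentation problem outside this
package's scope, and the mask defines the caller's contract. An empty mask
yields an all-zero measurement with a warning rather than an error, so
batch pipelines degrade gracefully.

## Numerical choices and degenerate inputs

- Fits require ≥ 3 animals, positive weights and non-constant body weight
  (otherwise a named validation or singular-fit error).
- 95 % two-sided t-based intervals throughout; `conf_level` is exposed.
- Perfect (zero-residual) fits propagate `lm`'s "essentially perfect fit"
  warning rather than silencing it — the parameter intervals are degenerate
  there and the user should know.
- `make_phantom()` re-centres its HU jitter to exactly zero mean so the
  analytic phantom weight is exact, and refuses jitter that would push
  voxels outside the clamping range (which would break the analytic value).
- Ties in splitting/fold assignment are resolved by the seeded RNG;
  partitions are disjoint and exhaustive by construction.

## Problem sizes used in the tests

The test suite runs at the canonical cohort size where the design matters
(n = 177 with 141/36 splits; n = 141 for recovery experiments over 100
seeds) and at 5 000–20 000 synthetic records where a law-of-large-numbers
comparison against an analytic oracle is the point. These sizes were chosen
so every statistical assertion has comfortable Monte-Carlo margin while the
full suite stays interactive (a few seconds).

## Known limitations

- The reference equation is valid for female White Landrace pigs of
  16–50 kg; above ~50 kg the curve approaches a plateau and underestimates
  lung weight. `error_bounds_curve()` warns outside 16–52 kg but still
  computes.
- The confidence band is parameter-wise (see above); true pointwise
  prediction intervals would be wider.
- The generator's uniform body-weight distribution and single noise level
  are idealizations; estimates of between-study heterogeneity are out of
  scope.
- CT masks are trusted as given; no pleural-effusion or airway handling.
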