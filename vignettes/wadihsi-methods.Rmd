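---
title: "Methods: Gaussian suitability curves, the composite HSI, and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Gaussian suitability curves, the composite HSI, and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wadihsi)
```

## The model

`wadihsi` treats habitat quality for a habitat-specialist fish as a
product of independent, unimodal responses to measurable environmental
parameters. For each parameter the niche is summarized by two numbers
estimated from a site survey, with each site weighted by the local
abundance of the focal taxon:

$$\mu = \frac{\sum_i w_i x_i}{\sum_i w_i}, \qquad
  \sigma = \sqrt{\frac{\sum_i w_i (x_i - \mu)^2}{\sum_i w_i}},$$

and the suitability of a parameter value $x$ is the Gaussian response
$S(x) = \exp(-(x-\mu)^2 / 2\sigma^2) \in (0, 1]$. The composite Habitat
Suitability Index of a site is the geometric mean of its parameter scores.
The geometric mean is the deliberate choice over the arithmetic mean: it
penalizes a habitat for any single limiting parameter, which matches how a
physiological tolerance violation works — good oxygen does not compensate
for lethal salinity.

Assumptions worth stating plainly:

* **Unimodal, symmetric responses.** Each parameter has one optimum and
  suitability decays symmetrically. Skewed or bimodal tolerance (e.g.
  thermal performance curves) is not representable; see Limitations.
* **Abundance as replicate counts.** The weighted moments use the
  frequency-weight (biased, $\sum w$ denominator) form, reading "200 fish
  at site A" as 200 replicate observations of site A's conditions. An
  unbiased reliability-weight variant is available
  (`weighted_gaussian_fit(type = "reliability")`) for when weights encode
  precision rather than counts.
* **No extrapolation.** Scoring clamps parameter values to the observed
  range of the fitting data (`clamp = TRUE` default), so the curves are
  never evaluated outside the conditions that informed them. Raw
  evaluation is available for plotting.

## Parameters that matter

| Knob | Default | Units | Why |
|---|---|---|---|
| `weighted_gaussian_fit(type)` | `"frequency"` | — | abundance-as-counts reading of the weighting |
| `gaussian_suitability(clamp)` | `TRUE` | — | constrain to observed, ecologically plausible ranges |
| `texture_score(floor)` | $10^{-3}$ | score | keeps the minimum-conductivity site from annihilating the geometric mean |
| `texture_score(coefs)` | $(-0.6, 0.0126, -0.0064)$ | log10 in/hr per % | Cosby (1984) regression of saturated hydraulic conductivity on sand/clay percentages; pinned as an argument so the pedotransfer choice is auditable and swappable |
| `classify_suitability(thresholds)` | `"quantile"` | HSI | 20/40/60/80th percentiles, linear interpolation (`type = 7`) |
| `correlate_with_bootstrap(n_boot)` | 1000 | iterations | percentile CI of Pearson r over resampled site pairs |
| `boyce_index(n_windows, window_width)` | 10, 0.2 | — , fraction of range | common continuous-Boyce practice |
| `select_threshold(method)` | `"default"` (0.5) | score | plus `MaxSS` and `MinROCdist` scanning midpoints of sorted unique scores |
| `high_suitability_mask(percentile)` | 90 | % | upper-percentile definition of high-suitability habitat |
| `target_progress(targets)` | 7.5 / 30 | % | national 2040 wetland target and CBD 30x30 |
| `density_protection_summary(targets)` | 50/30/10 | % | tiered wadi-density protection targets |

## Decisions where the design was genuinely open

**Optimal ranges are $\mu \pm \sigma$.** No published rule states how the
reported "optimal ranges" derive from the curves. The $\mu \pm \sigma$
convention (intersected with observed bounds) is adopted because
back-solving the published dissolved-oxygen optimum 6.42–8.66 mg/L gives
midpoint 7.54 and half-width 1.12 — exactly a mean-and-SD pair. It is
recorded as an assumption, implemented in `optimal_range()`.

**Which pedotransfer output is normalized.** The substrate sub-score needs
a single scalar per composition; the best-known Cosby regression predicts
saturated hydraulic conductivity from sand and clay, so that is the
default. Gravel is excluded and the fines renormalized; the coefficients
are an explicit argument.

**Quantile thresholds vs published thresholds.** On the 12 published HSI
values, no standard percentile interpolation reproduces the published
thresholds (0.47/0.51/0.59/0.75) exactly, and the published table is
internally inconsistent for two sites (K2, AW1 carry labels that
contradict the printed intervals). The classifier therefore pins linear
interpolation as its default, accepts explicit overrides, and ships the
published thresholds as preset `"hajar"`; when published labels and
threshold-derived labels differ, both are available for comparison
(`hajar_metrics()$published_class` vs `classify_suitability()`).

**Tie and boundary conventions.** Classification intervals are left-closed
with the top class closed (a value equal to a threshold joins the class
above); threshold-selection ties break toward the lower threshold; MESS
uses "strictly below" for the percentile $f$; the wadi-density class
"medium" is the closed interval [0.0004, 0.0008] km/km²; equal-interval
suitability classes are left-closed with [0.75, 1] closed.

**LOOCV of an unsupervised index.** Cross-validating an index with no
external response needs a target; the only defined reading is
self-consistency, so `loocv_hsi()` compares the held-out site's predicted
HSI against its full-data HSI. This measures how much the index depends on
the site's own contribution to the curves, not predictive skill against
independent truth.

**Binarizing sites for a confusion matrix.** No rule is published for how
survey sites become observed positives/negatives. The pipeline's default
is observed-positive iff abundance exceeds the site median and
predicted-positive iff HSI exceeds a selected threshold; both are knobs,
and the published counts (4/6/2/0) ship as a fixture so the derived
metrics are testable independent of the unstated rule.

**Degenerate inputs are errors or flags, never silent.** Zero weighted
variance in a curve fit, a zero suitability score reaching the geometric
mean, a single-site texture normalization, an all-zero community, zero
background mean in the calibration ratio, and degenerate MESS reference
ranges (sentinel −1000, flagged) all stop or mark loudly.

## What the synthetic generator emulates — and what it does not

`true_model()` defaults encode the surveyed conditions: parameter bounds
are the published field ranges (depth 25–84 cm through turbidity 1.1–22
NTU); true optima sit at range midpoints with widths of a third of the
range; the abundance scale (2.6 × 10⁵) is calibrated so the noiseless
median abundance lands near the geometric midpoint (~4,200) of the
observed 979–17,708 envelope; abundance noise is multiplicative lognormal
(sdlog 0.3), mean-preserving, rounded, floored at 1 — chosen because only
the observed range is published and lognormal keeps positivity with one
dispersion knob. The community generator gives the specialist an expected
share $1/S + (0.995 - 1/S)h^\gamma$ at HSI $h$ (cap 0.995 keeps Shannon
defined at $h = 1$; default $\gamma = 2$, $S = 4$ — the published A1 row
back-solves to 4 species under $J = H/\ln S$, confirming natural logs),
with the remainder split evenly and multinomial sampling as noise. The
expected-composition Shannon is non-increasing in $h$, which is the
mechanism behind the negative HSI–diversity correlations downstream.

Quarterly field visits are supported as a per-visit mode
(`simulate_sites(seasons = 4)`) but pooled single-season output is the
default, since the published pooling rule is unstated.

Not emulated: spatial autocorrelation between sites, seasonal
autocorrelation within a site, parameter–parameter correlation (real EC,
TDS and salinity co-vary strongly), detection error in abundance, and any
hydrological realism in the grids. Passing tests therefore demonstrate
correctness of the estimators and pipeline on data satisfying the model's
own assumptions — not robustness to the violations real wadi data will
contain.

## Numerical choices and precision

* Geometric means are computed in log space; percentile thresholds use
  `stats::quantile(type = 7)`; Spearman ties get average ranks; AUC is the
  rank-based Mann–Whitney estimate with ties counted half.
* The prevalence-mismatch flag compares $10\,|FP - FN| > N$ in integer
  arithmetic so the 10-percentage-point boundary is exact.
* **Recovery precision of the weighted moments.** With sites uniform over
  a field range and abundance-weighted moments, the sampling SD of
  $\hat\mu$ at $n$ sites is approximately $0.0184\,\mathrm{span}$ at
  $n = 200$ (Gaussian weighting shrinks the effective spread to ~0.74 of
  $\sigma_{true}$ and the effective sample to ~0.92 n). Relative to the
  optimum this is ~2% for wide-range parameters (depth, EC, turbidity)
  and well under 1% for narrow-range ones (temperature, pH, BOD). The
  recovery tests therefore assert 1% optimum recovery on temperature, and
  exact agreement with a brute-force weighted-moment oracle for every
  parameter. The weighting also shrinks $\hat\sigma$ below
  $\sigma_{true}$ deterministically (to ~0.74 at bounds spanning
  3$\sigma_{true}$), so $\sigma$ is asserted against that analytic limit,
  not against $\sigma_{true}$.
* **Problem sizes in the test suite** (chosen as the smallest sizes at
  which each property is statistically crisp): curve recovery at
  $n = 200$ noiseless sites; bootstrap CI coverage over 500 trials of
  $n = 50$ bivariate-normal pairs with $\rho = 0.5$ and 1000 resamples;
  Boyce/AUC null behavior at $10^4$ draws; pipeline reproducibility on
  12 sites with 25×25–30×30 grids.

## Known limitations

* Single-Gaussian curves cannot express skewed or multimodal tolerance;
  no kernel or spline smoothing is offered.
* The HSI surface is site-based only — no spatial interpolation or
  continuous mapping.
* The bootstrap CI is the percentile interval; it is known to undercover
  slightly for small $n$ and strong correlations (BCa is not
  implemented).
* Grid areas use a constant user-supplied cell area; no geodesic
  reprojection, so grids must be equal-area for the km² numbers to mean
  what they say.
* With 12 sites, LOOCV and the confusion battery rest on very few
  effective observations; their variance across seeds is large, and the
  acceptance script reports whatever the seeded run produces rather than
  a curated value.
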