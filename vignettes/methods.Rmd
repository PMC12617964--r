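---
title: "Methods: trend, seasonality, association and alignment for search-interest series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trend, seasonality, association and alignment for search-interest series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infotrend)
```

## The problem

Online search interest in a disease — reported by search engines as a
monthly *relative search volume* (RSV), normalized to 0–100 over the
retrieval window — is a widely used proxy for public attention to a health
topic. A typical infodemiology question has four parts: is search interest
rising over time, is the rise seasonal, which environmental exposures
co-vary with it, and do the co-varying exposures also *track* it in time
once lags and local time distortions are allowed for? `infotrend`
implements that four-stage analysis for monthly series, together with a
synthetic-data generator whose ground truth makes every stage testable
without downloading anything.

A falsification outcome — search interest in an unrelated condition that
should show *no* trend — is carried through the trend stage as a negative
control: a significant trend in the control would point to a shared
confounder (rising internet use, platform changes) rather than a
topic-specific signal.

## The trend model and the MID statistic

RSV at month $t$ is modelled by ordinary least squares on a cubic B-spline
basis of the decimal-year time axis:

$$\mathrm{RSV}_t = \beta_0 + \sum_{j=1}^{4} \beta_j B_j(t) + \varepsilon_t,$$

with 4 spline degrees of freedom (excluding the intercept), boundary knots
at the first and last observed month, and the single interior knot at the
median observation time. Months are mapped to $\text{year} + (m - 0.5)/12$,
so the fitted spline's analytic first derivative
$s'(t) = \sum_j \beta_j B_j'(t)$ is a rate in RSV units *per year*. The
trend statistic is the **mean instantaneous derivative**,

$$\mathrm{MID} = \frac{1}{12}\cdot\frac{1}{n}\sum_{t=1}^{n} s'(t_i),$$

the average yearly rate divided by 12 and hence an average change in RSV
units *per month*. A positive MID is an overall rise. Because linear
functions lie inside the cubic spline space, an exactly linear series
returns its slope exactly; this is one of the suite's oracle checks.

Uncertainty comes from a **residual bootstrap** (default 1000 iterations):
residuals are resampled with replacement, added back to the fitted values,
and the model is refitted; the 95% CI is the 2.5/97.5 percentile interval
of the bootstrap MIDs and the two-sided p-value is
$2\min\{\hat P(\mathrm{MID}^* \le 0), \hat P(\mathrm{MID}^* \ge 0)\}$,
floored at $2/(B+1)$ so it is never exactly zero. Residuals are resampled
raw by default; a leverage adjustment ($e_i / \sqrt{1-h_{ii}}$) is
available behind `leverage_adjust = TRUE` for users who prefer it. The
refits reuse the QR decomposition of the fixed design matrix, so the
bootstrap is a single matrix product per run and the default 1000
iterations take milliseconds.

Two conventions here were genuinely open and are worth recording. First,
"4 df" counts spline columns with the intercept as a separate term — the
dominant convention in statistical computing — with knots as above; other
knot placements would give slightly different fits. Second, the bootstrap
p-value estimator is the standard two-sided percentile proportion; nothing
in the procedure pins down a unique choice, and the floor keeps the
estimator honest at its resolution.

## Seasonality

Month-of-year differences are tested by grouping the series by calendar
month and applying the tie-corrected Kruskal–Wallis test, with the
chi-square approximation on $k - 1$ degrees of freedom for the p-value.
At the scale this pipeline targets (about 68 months, 12 groups of 5–6) the
approximation is serviceable but not exact, so `test_seasonality(exact =
TRUE)` adds a Monte-Carlo permutation p-value; the suite checks the
statistic against the rank formula exactly and the chi-square p against a
full permutation enumeration at small pooled sizes. When every value is
tied the tie correction degenerates; the package reports $H = 0,\ p = 1$
rather than `NaN`. Per-month medians, quartiles and extremes are returned
for box-plot reporting (`autoplot()`).

## The correlation screen

Environmental series are prepared in three steps: strictly interior missing
runs are filled by linear interpolation between flanking observed months; a
parameter is excluded, with a machine-readable reason, when an edge month
is missing or more than 30% of its cells are missing (the pipeline
interpolates isolated gaps but refuses to invent a series' endpoints — the
30% cut-off is this package's generalization of dropping wholly unavailable
parameters); and series are z-standardized. Standardization is a no-op for
Spearman correlation — rank statistics are invariant to affine transforms,
and a test asserts exactly that — but it matters for DTW below, which is why
it sits in the shared preprocessing path.

Each parameter is screened against RSV with Spearman's $\rho$ (Pearson
correlation of midranks; perfect concordance is returned as exactly
$\pm 1$). The two-sided p-value uses the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n - 2$ df — at $n \approx 68$ an
exact permutation null adds nothing, though the kernel is cross-checked
against an independent implementation in the tests. Results carry the
two-tier significance convention (`p<.05`, `p<.001`) and **no multiplicity
adjustment**, matching how such screens are conventionally reported; the
number of tests is attached to the table so readers can apply their own
correction.

## Temporal alignment by dynamic time warping

Parameters that pass the screen are re-examined with dynamic time warping
between standardized series: local cost $|x_i - y_j|$, the unconstrained
symmetric three-way recurrence, no window, no slope constraint, and no
path-length normalization by default (a normalized distance is available
behind `normalize = TRUE` for cross-length comparisons). This is the
textbook DTW; with both series standardized, its distance is in
accumulated z-score units and parameters are ranked ascending — the
smallest distance is the strongest temporal alignment, absorbing modest
lags that a contemporaneous correlation would penalize. Backtracking
breaks ties diagonal-first so the reported path is reproducible; the
distance itself does not depend on tie-breaks, and the suite verifies it
against an exhaustive enumeration of all admissible warping paths on small
instances.

## The synthetic generator and what it does (not) emulate

`synth_config()` defines a study: `n_months = 68` starting December 2018,
an RSV series built as trend + optional month-of-year sinusoid + Gaussian
noise, clipped to $[0, 100]$; a flat control series with the same noise
level; and an environmental panel in which `n_env_linked` series share the
standardized noiseless RSV signal (fraction `link_strength` of their
variance, sign `link_sign`, leading RSV by `link_lag` months with edge
repetition) and `n_env_null` series are independent noise. Interior cells
are masked at `missing_rate`; the first and last months are never masked,
matching the interior-only interpolation rule. Every series has its own
RNG stream derived from `(seed, series index)`, so adding a series never
perturbs the ones already generated, and all ground truth (`true_mid`,
link flags, masked cells) is recorded.

Default choices, made once:

* **Trend shape** `smooth_rise`: a logistic ramp with steepness $n/6$,
  normalized to rise `trend_total_rise = 40` RSV units from a base of 40.
  The ramp spreads the rise over roughly three quarters of the window — a
  gradual, saturating increase of the kind search-interest series show —
  and keeps the derivative time-varying so the 4-df spline is genuinely
  exercised while remaining within its approximation capacity (the spline's
  mean-derivative bias on the noiseless ramp is about 4%).
  `true_mid` is the analytic mean per-month derivative of the noiseless
  ramp; for the linear trend it is the constructed slope exactly, and for
  the flat trend exactly zero.
* **Noise** `noise_sd = 8` RSV units — monthly RSV exports are noisy at
  roughly this order relative to a 0–100 scale.
* **Seasonality** off by default (amplitude 0), reflecting the
  no-seasonality regime the seasonality test is calibrated against; set
  `seasonal_amplitude > 0` to study power.
* **Linkage** three linked series at `link_strength = 0.7`, one month of
  lead, three null series, `missing_rate = 0.02` — isolated interior gaps,
  like a station outage in one month.

The generator emulates *statistical* features only. It does not model the
renormalization quirks of relative search volume (values depend on the
retrieval window and date), sampling jitter between retrievals, spatial
correlation between neighbouring geographies, or autocorrelated noise.
Passing tests therefore demonstrate that the pipeline recovers known
structure under clean monthly sampling with independent Gaussian noise —
not that any particular real-world association is causal, nor that the
bootstrap is calibrated under strong residual autocorrelation (a block
bootstrap is out of scope by design).

## Numerical and degenerate-input choices

* Zero-variance response: the spline fit is returned with the R² flagged
  undefined instead of `NaN`; derivatives are exactly zero.
* Constant series cannot be standardized and raise a typed error;
  all-tied seasonality returns $H = 0,\ p = 1$.
* Perfect monotone association returns $\rho = \pm 1$ exactly and a
  positive (subnormal floor) p-value, never 0.
* DTW singletons are allowed ($d = |a - b|$); empty sequences are errors.
* CIs are percentile intervals; `ci_low <= ci_high` always holds, but the
  point estimate is not forced inside the interval.
* Reports contain no timestamps or machine details, so a configuration
  reproduces its report byte for byte; all stage seeds derive from the
  pipeline seed.

## Problem sizes used by the test suite

The suite runs the calibration checks at 200 replicates × 500 bootstrap
iterations (null rejection and CI coverage), 200 replicates for MID
recovery, 500 replicates for the Kruskal–Wallis and Spearman null
calibrations, 200 small instances against the DTW path-enumeration oracle,
and a 6-geography, 68-month pipeline reproduction — sizes at which the
binomial error of the estimated rates is comfortably inside the asserted
bands while the whole suite stays interactive (about half a minute).

## Worked example

```{r example, eval = FALSE}
study <- simulate_study(synth_config(seed = 1))

est <- bootstrap_mid(study$rsv, n_boot = 1000, seed = 1)
glance(est)
ctrl <- bootstrap_mid(study$control, n_boot = 1000, seed = 2)
falsification_contrast(est, ctrl)$verdict

test_seasonality(study$rsv)

prep <- preprocess_panel(study$panel)
screen <- correlate_panel(prep$panel, study$rsv)
rank_alignment(prep$panel, study$rsv, screen)
```
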