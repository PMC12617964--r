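# infotrend

An infodemiology analysis pipeline for monthly search-interest time series.
Search engines report public interest in a topic as a monthly *relative
search volume* (RSV, normalized 0–100 per region and window); `infotrend`
answers the four questions such a series raises for epidemiologists and
health-communication researchers:

1. **Is interest rising?** RSV is fitted by OLS on a cubic B-spline basis
   (4 df) of decimal-year time. The trend statistic is the **mean
   instantaneous derivative** — the fitted spline's analytic first
   derivative $s'(t)$ averaged over observed months and divided by 12:

   $$\mathrm{MID} = \frac{1}{12n}\sum_{i=1}^{n} s'(t_i) \quad
   \text{(RSV units per month; } > 0 \text{ means rising)}$$

   A residual bootstrap (1000 iterations) supplies percentile 95% CIs and a
   two-sided p-value, and a *falsification contrast* compares the target
   series against a negative-control topic expected to show no trend.
2. **Is it seasonal?** The tie-corrected Kruskal–Wallis test across
   calendar months, with per-month summaries for box plots and an optional
   permutation p-value.
3. **What co-varies with it?** Environmental parameter panels (meteorology,
   air pollutants) are interior-interpolated, rule-excluded, standardized,
   and screened with Spearman's rank correlation at two significance tiers
   (`p<.05`, `p<.001`), unadjusted, with the test count reported.
4. **What tracks it in time?** Screened parameters are ranked by dynamic
   time warping distance to the standardized RSV series (symmetric step
   pattern, absolute-difference cost) — the smallest distance marks the
   strongest temporal alignment, tolerant of lags.

A synthetic-data generator (`synth_config()` / `simulate_study()`) produces
RSV-like series, flat control series, and environmental panels with known
ground truth (trend derivative, link strength/sign/lag, masked cells), so
the entire pipeline is testable end to end with no downloads.

## Worked example

```r
library(infotrend)

study <- simulate_study(synth_config(seed = 1))   # 68 months from 2018-12

est <- bootstrap_mid(study$rsv, n_boot = 1000, seed = 1)
est
#> <trend_estimate> MID = 0.5444 per month (95% CI 0.3817 to 0.7013), p = 0.002
#>   residual bootstrap, 1000 iterations, seed 1

ctrl <- bootstrap_mid(study$control, n_boot = 1000, seed = 2)
falsification_contrast(est, ctrl)$verdict
#> [1] "trend specific to target"

test_seasonality(study$rsv)
#> <seasonality_test> Kruskal-Wallis H = 2.298, df = 11, p = 0.997

prep <- preprocess_panel(study$panel)
screen <- correlate_panel(prep$panel, study$rsv)
screen
#> # A tibble: 6 × 5
#>   parameter   rho  p_value tier   n_effective
#> 1 linked_1  0.745 3.18e-13 p<.001          68
#> 2 linked_2  0.752 1.39e-13 p<.001          68
#> 3 linked_3  0.700 3.17e-11 p<.001          68
#> # ... null_1..null_3 with tier "none"

rank_alignment(prep$panel, study$rsv, screen)
#> # A tibble: 3 × 4
#>   parameter dtw_distance path_length  rank
#> 1 linked_2          23.2          87     1
#> 2 linked_3          24.4          89     2
#> 3 linked_1          24.9          90     3
```

Read that as: search interest rises by about 0.54 RSV units per month on
average (CI excludes 0, p = .002) while the control topic does not, so the
trend is topic-specific; there is no month-of-year seasonality (p = .997);
exactly the three truly linked environmental parameters pass the Spearman
screen at `p<.001` while the three null parameters do not; and DTW ranks
those linked parameters by how closely they track the RSV series in time.
The generator's analytic truth for this configuration is a mean derivative
of 0.59 RSV units per month, inside the bootstrap CI.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and plot
with `autoplot()`; `run_pipeline()` executes every stage for one or more
geographies and `write_report()` emits a byte-reproducible JSON report
plus CSV tables. A thin command-line wrapper with `simulate`, `trend`,
`seasonality`, `correlate`, `dtw` and `run` subcommands is installed at
`inst/cli/infotrend`.

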