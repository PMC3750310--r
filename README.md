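# cadexpo

Point and probabilistic assessment of dietary and environmental cadmium
exposure.

`cadexpo` is for exposure scientists and environmental epidemiologists
who need to turn per-food contamination/consumption summary tables into
population risk statements. It implements the full workflow of a
cross-sectional dietary cadmium survey of adults over 40 in Shanghai
(2008, n = 207), whose summary tables ship with the package, and it
generalises to any food table in the same shape.

## The model

Total daily cadmium exposure (µg/day) is

```
E = Σ_f c_f · q_f  +  c_tob · m_cig · N  +  c_w · V_w
```

with per-food cadmium concentration `c_f` (mg/kg ≡ µg/g) and daily
consumption `q_f` (g/day), tobacco cadmium `c_tob` (µg/g), tobacco mass
per cigarette `m_cig` (g), cigarettes/day `N`, and a water term fixed at
half the detection limit (`c_w` = 0.025 µg/L) times 1.2 L/day. Exposure
is characterised against the provisional tolerable daily intake (PTDI),
49.5 µg/day (25 µg/kg-bw/month at 60 kg).

The package provides:

* **Point estimation** — `exposure_breakdown()`: per-food exposure at
  four summary levels (mean, median, P90, extreme P90), source
  contribution rates, and PTDI fractions.
* **Distribution fitting** — `lognormal_from_moments()` (inputs, from
  mean/SD) and `lognormal_from_mean_median()` (reported outputs, from
  mean/median), plus point-mass and zero-inflated boundary cases.
* **Monte Carlo engine** — `build_population_model()`,
  `simulate_exposure()`, `risk_below()`: seeded propagation of the input
  distributions through the exposure equation (default n = 100,000) with
  below-PTDI risk.
* **Sensitivity analysis** — `contribution_to_variance()`: normalized
  squared Spearman rank correlations, the contribution-to-variance
  convention of spreadsheet risk tools.
* **Biomonitoring statistics** — `substitute_lod()`, `mann_whitney()`,
  `dose_correlation()`, `biomonitoring_stats()`: LOD substitution,
  nonparametric group comparisons and external–internal dose
  correlations for urinary/blood cadmium.
* **Synthetic cohorts** — `generate_cohort()`: individual-level cohorts
  calibrated to the survey's demographics, intake moments and
  internal-dose correlations, for end-to-end testing (no individual
  survey records were ever deposited).
* **Pipeline** — `run_pipeline()` and a thin CLI
  (`inst/cli/cadexpo.R`) chaining the stages with a reproducibility
  manifest.

## Worked example

```r
library(cadexpo)

bd <- exposure_breakdown(shanghai_food_table(), exposure_config())
bd$totals
#>   source exposure_mean exposure_median exposure_p90 exposure_extreme_p90
#>  dietary         12.75            3.28        20.58                94.19
#>    water          0.03            0.03         0.05                 0.05
#>  smoking          3.93            0.00        16.15                16.39
#>    total         16.71            3.31        36.78               110.63
round(bd$ptdi_fraction, 1)
#>        mean      median         p90 extreme_p90
#>        33.8         6.7        74.3       223.5
```

Mean environmental exposure is 16.7 µg/day — one third of the PTDI —
with diet contributing 12.8 µg/day (vegetables 40%, rice 38%, seafood
9%) and smoking 3.9 µg/day at the population level. Only the extreme-P90
scenario (90th-percentile contamination eaten at 90th-percentile
amounts) exceeds the limit.

Probabilistic risk from the reported total-population output
distribution:

```r
d <- lognormal_from_mean_median(23.05, 18.24)
sim <- simulate_fitted(d, n = 1e5, seed = 42)
round(summarize_draws(sim), 2)
#>   mean median    std     p5    p95    min    max
#>  23.01  18.21  17.75   5.87  56.37   1.15 352.41
risk_below(sim, 49.5) * 100
#> [1] 92.8
```

92.8% of the population stays below the PTDI. Sensitivity of the
reconstructed population model:

```r
model <- build_population_model(shanghai_food_table(), exposure_config())
popsim <- simulate_exposure(model, n = 1e5, seed = 42)
head(contribution_to_variance(popsim$input_draws, popsim$draws), 3)
#>                  input rank_correlation contribution
#> 1           cigarettes        0.4968325    35.809929
#> 2 fresh_vegetable_conc        0.4296746    26.783217
#> 3            rice_conc        0.3992087    23.119770
```

Tobacco consumption and the vegetable and rice cadmium concentrations
drive the variance — reducing contamination in those two crops, and
smoking, are where intervention pays.

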