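---
title: "Methods: point and probabilistic cadmium exposure assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point and probabilistic cadmium exposure assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadexpo)
```

## The assessment problem

Cadmium accumulates in kidney and bone over a 10–30 year half-life, so
chronic low-level intake — overwhelmingly through food, plus tobacco
smoke for smokers — is the exposure route that matters for the general
population. `cadexpo` implements the exposure-assessment workflow used in
a 2008 cross-sectional survey of 207 Shanghai residents over 40: starting
from a per-food summary table of cadmium concentrations (mg/kg) and daily
intakes (g/day), it characterises population exposure against a
health-based limit, the provisional tolerable daily intake (PTDI),
obtained from the provisional tolerable monthly intake of
25 µg/kg-bw/month at a 60 kg body weight (49.5 µg/day; see
`derive_ptdi()`).

The total-exposure equation is

$$E = \sum_f c_f\, q_f \;+\; c_{tob}\, m_{cig}\, N \;+\; c_w V_w,$$

with per-food concentration $c_f$ and consumption $q_f$, tobacco cadmium
content $c_{tob}$ (µg/g), tobacco mass per cigarette $m_{cig}$ (g),
cigarettes per day $N$, water concentration $c_w$ (µg/L) and daily water
volume $V_w$ (L). Since mg/kg ≡ µg/g, each term is directly a µg/day
dose. The package evaluates this equation three ways: deterministically
at summary levels (point estimation), stochastically by Monte Carlo
(probabilistic estimation), and per individual on cohort tables.

## Point estimation

`exposure_breakdown()` evaluates each food at four summary levels:

* **mean** — mean concentration × mean intake;
* **median** — *median* concentration × median intake;
* **P90** — mean concentration × 90th-percentile intake;
* **extreme P90** — 90th-percentile concentration × 90th-percentile
  intake, an upper-bound scenario.

The median convention deserves a note: the survey's written formula says
"mean concentration × median intake", but every published median cell is
reproducible only as median × median (rice: 0.009 × 200 = 1.80, not
0.023 × 200 = 4.60). We treat the formula text as an editorial slip and
follow the arithmetic that the published table actually used; the
written-formula variant remains available via `median_conc_is_mean =
TRUE`.

Two cells of the summary table need external information. The tuber row
prints no 90th-percentile concentration; its published extreme exposure
(0.10 µg/day) ships as a per-food override, and for tables without an
override the fallback is the normal-quantile approximation
$c_{mean} + 1.2816\, c_{std}$, emitted with a warning. The smoking and
water rows of the breakdown cannot be derived from the food table at all
(they summarise individual-level data), so they are carried as documented
defaults: smoking 3.93 / 0 / 16.15 / 16.39 µg/day across the four levels,
water at the configured constant (0.03 µg/day) for mean/median and the
published upper-bound 0.05 µg/day for the P90 levels.

A similar known blemish: the innard mean cell computes to
0.278 × 0.5 = 0.139 against a published 0.15, almost certainly intake
rounding upstream of the published table. We reproduce, not correct:
the comparison tolerance (±0.02 µg/day per cell, ±0.3 percentage points
per contribution rate) covers it.

## Distribution fitting

All stochastic inputs and all reported simulation outputs are lognormal,
so the package fixes the family to lognormal plus two boundary cases (a
point mass for constants; a Bernoulli–lognormal mixture whose zero
component holds non-consumers/non-smokers at exactly zero). No automatic
family selection or goodness-of-fit testing is performed — the family is
an assumption of the reconstruction, not an inference.

Two parameterizations cover the two data situations:

* `lognormal_from_moments(mean, std)` — method of moments,
  $\sigma^2 = \ln(1 + (s/m)^2)$, $\mu = \ln m - \sigma^2/2$. Used for
  inputs, whose tables print mean and standard deviation.
* `lognormal_from_mean_median(mean, median)` — $\mu = \ln(\text{median})$,
  $\sigma = \sqrt{2 \ln(\text{mean}/\text{median})}$. Used to
  reconstruct *reported outputs*, which are printed as mean/median
  pairs. A lognormal's mean can never fall below its median, so
  `mean < median` is a domain error and equality degenerates to a point
  mass.

How faithful is the reconstruction? For each of the five reported
stratum models, the lognormal implied by the printed mean/median predicts
the printed standard deviation within 5% and the printed 95th percentile
within 2–5%. The printed 5th percentiles, however, sit 10–28% above the
implied ones (worst for the women and non-smoker strata), so the original
simulation output was slightly heavier near its floor than an exact
lognormal. Risk statements evaluated near the PTDI (far in the upper
body of the distribution) are insensitive to this lower-tail mismatch;
we report it rather than tune around it.

## Monte Carlo engine

`build_population_model()` + `simulate_exposure()` propagate the input
distributions through the total-exposure equation with n independent
iterations (default 100,000, the reported simulation size). Choices that
matter:

* **Independence.** Concentration and intake draws are independent within
  and across foods. The summary tables carry no correlation structure, so
  none is invented; this is the model's key simplification and will
  understate variance if, e.g., heavy rice eaters also eat more
  vegetables.
* **Tobacco term.** Bernoulli(prevalence) × lognormal cigarettes/day
  (mean 9.2, SD 8.2 among smokers — back-solved from the smokers'
  reported dose 13.8 ± 12.3 µg/day at 1.5 µg Cd per cigarette) ×
  a lognormal tobacco concentration (mean 1.5 µg/g, SD 1.1, spreading the
  central 90% over roughly the 0.5–5 mg/kg range reported for tobacco) ×
  1 g tobacco/cigarette. The tobacco mass per cigarette is not stated in
  the survey; 1.0 g is the conventional figure and reproduces the
  smokers' mean dose at a plausible 9.2 cigarettes/day. Prevalences:
  66.2% (men), 3.3% (women), 29.5% (total); the smoker/non-smoker strata
  force 1 and 0.
* **Water term.** A constant 0.03 µg/day: all water samples were below
  the 0.05 µg/L detection limit, so the concentration is fixed at
  half-LOD (0.025 µg/L, the standard substitution; `substitute_lod()`)
  times 1.2 L/day.
* **Determinism.** Every simulation is reproducible bit-for-bit from
  (model, n, seed); the seed is recorded in every serialized result.
  Percentiles use linear interpolation between order statistics (R type
  7), immaterial at n = 100,000.

`risk_below()` reports the fraction of draws at or below the PTDI.
Reconstructing the reported total-population output lognormal
(mean 23.05, median 18.24) and evaluating at 49.5 µg/day gives 92.8%,
against a reported 93.4%; the women's model (14.05, 10.62) gives 98.0%
exactly. The 0.6-point gap for the total model is expected: the original
input distributions were fitted to individual-level records that were
never published, so the printed mean/median pair is the only available —
and slightly lossy — handle on the output distribution.

## Sensitivity analysis

`contribution_to_variance()` implements the rank-correlation convention
of spreadsheet risk tools: Spearman $r_i$ of each retained input draw
vector with the output, normalized as $S_i = r_i^2 / \sum_j r_j^2 \times
100$. Contributions are non-negative, sum to 100, are invariant to
strictly monotone transforms of any input (ranks don't move), and the
correlation's sign is reported alongside. Constant inputs carry zero. On
the reconstructed total-population model the two tobacco inputs jointly
dominate every single food input and vegetable and rice concentrations
lead the foods — the published ordering. The published *percentages*
(27.5/24.9/20.2/14.6) are not asserted anywhere: they depend on the
unpublished input fits, and the package's independence assumptions need
not reproduce them exactly. (The survey's own abstract and results
sections disagree on which tobacco factor holds 27.5%, so only the
unordered pair is meaningful anyway.)

## Biomonitoring statistics

Internal-dose analyses use the field-standard nonparametric toolkit, with
conventions fixed as: Mann–Whitney U from rank sums with midrank ties,
exact two-sided p when the smaller group has ≤ 8 observations and no
ties, otherwise the tie-corrected normal approximation without continuity
correction; correlations default to Pearson (the survey reports "R"
without naming a method) with Spearman available; two-sided tests at the
0.05 level throughout. LOD substitution replaces values strictly below
the limit by LOD/2 and is idempotent.

## The synthetic cohort generator

No individual-level survey data were deposited, so `generate_cohort()`
emulates the cohort the analyses assume: n = 207; 41.5% male; smoking
66.2% of men, 3.3% of women; 37.2% aged ≥ 60, with ages uniform within
the 40–59 and 60–90 bands (only band fractions were reported — the
within-band shape is our choice and is *not* calibrated); per-food
intakes as independent lognormals from the summary-table moments;
cigarettes/day among smokers lognormal (9.2, 8.2). A per-sex intake
multiplier (14.0/12.77 for men, 11.9/12.77 for women, from the reported
sex-specific dietary means) shifts men above women while leaving the
population mean unchanged at the default sex mix; it adds ~1.3%
between-sex variance per food, which is why the moment-fidelity test
disables it.

Blood and urinary cadmium come from multiplicative-noise structural
models,

$$BCd_i = (b_{0,g(i)} + b_1 E_i)\,\nu_i, \qquad
  UCd_i = (c_0 + c_1\,\mathrm{age}_i)\,\eta_i,$$

with unit-mean lognormal noise and smoking-group intercepts $b_{0,g}$
solved per realisation so the group means hit the reported 1.04 (smokers)
and 0.30 µg/L (non-smokers), and $c_0$ likewise for the overall UCd mean
1.88 µg/L. The slopes and noise spreads are calibrated in closed form to
the reported correlations. Writing $\mathrm{corr}(E, BCd) =
\mathrm{cov}/(\sigma_E \sigma_B)$ with
$\mathrm{cov} = p(1-p)\Delta E\,\Delta B + b_1 \mathrm{E}[\mathrm{Var}(E\mid g)]$
(between- plus within-group parts) and
$\mathrm{Var}(B\mid g) = \mathrm{Var}(L) + V_\nu \mathrm{E}[L^2]$ for the
linear predictor $L$, solving for a target correlation of 0.52 at the
survey's group structure gives $b_1 = 0.02$ µg/L per µg/day and noise
$\sigma = 0.717$ — which also lands the group SDs near the reported 0.86
and 0.25. The UCd analogue (target correlation 0.15 with age, SD 1.47)
gives $c_1 = 0.0158$ and $\sigma = 0.681$. Measured over 20 seeds at
n = 207, the generated cohorts recover corr(exposure, BCd) ≈ 0.52,
corr(age, UCd) ≈ 0.155, and a smoker/non-smoker BCd contrast significant
at 0.05 in every seed.

What the generator deliberately does **not** emulate: inter-food intake
correlation (none was reported), non-consumer zero-inflation of intakes,
seasonality, the 39-item questionnaire granularity beneath the 14
aggregated categories, within-band age structure, and any causal link
between diet and smoking beyond sex. Tests passing on synthetic cohorts
therefore demonstrate that the *analysis machinery* recovers the
structure the generator encodes — not that the generator reproduces real
dietary behaviour.

## Problem sizes and numerical conventions

Simulation-based checks run at n = 100,000 iterations (matching the
reported simulation size; a full population simulation takes ~1 s);
convergence tests use Dvoretzky–Kiefer–Wolfowitz bands at level 0.001
(±0.0062 at that n); generator-convergence checks use n = 50,000 cohorts
and 3-standard-error bands computed from the lognormal's analytic fourth
moment; parameter-recovery checks average 20 seeds at the survey size
n = 207. Empirical standard deviations use the n−1 denominator. Exposure
arithmetic is validated to ±0.02 µg/day per cell against the published
breakdown, with reports rounded to two decimals while all internal
computation is full precision.

## Limitations

The reconstruction ceiling is set by what was published: per-food
summaries, not records. The probabilistic mean reconstructed from
summaries (16.8 µg/day under independence) is well below the reported
probabilistic mean (23.05 µg/day), confirming that the original input
distributions were fitted to unpublished individual data with more
variance (and likely dependence) than the summary table conveys. All
probabilistic results should therefore be read as "under this package's
reconstruction of the model", with exact agreement expected only where
the published information fully determines the answer — as it does for
the point estimates and for risks evaluated on the reported output
distributions.
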