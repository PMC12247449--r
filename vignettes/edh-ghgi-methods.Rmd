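---
title: "Dry-heat extremes and wheat GHG emission intensity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dry-heat extremes and wheat GHG emission intensity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edhwheat)
library(dplyr)
```

## The problem

Wheat systems respond to compound dry-heat stress on two coupled fronts:
grain yield falls, and the soil carbon–nitrogen balance shifts toward net
greenhouse-gas release. The ratio of the two — the **GHG emission intensity**
(GHGI, kg CO₂-eq per kg grain) — is the climate cost of producing food, and
the question this package operationalises is threefold:

1. How exposed is a wheat region to dry-heat extremes, year by year?
2. How tightly are yield, net GHG balance and GHGI coupled to that exposure,
   and is the coupling strengthening?
3. Can a location-specific choice between no-till (NT) and conventional
   tillage (CT) weaken the adverse coupling, and by how much?

The package implements the full analysis chain as composable tibble-in /
tibble-out functions, and ships a synthetic gridded generator so that every
stage can be tested against data whose true couplings are known by
construction.

## Extreme-day indices

Three annual day-count indices are computed per grid cell over the fixed
**Mar 1 – Sep 30** growing window (always 214 days; February is outside the
window, so leap years change nothing):

* **HC** — heat days: daily maximum temperature strictly above 30 °C;
* **DC** — dry days: daily aridity index strictly below 0.2;
* **CDHC** — compound days: both on the same day. No cascading or lag logic
  is applied, so `CDHC ≤ min(HC, DC)` holds identically.

The aridity index is the daily ratio `AI = P / ETp`. Potential
evapotranspiration comes from the Hargreaves model,

$$ET_p = 0.0023 \times 0.408\, R_a\, (T_{max}-T_{min})^{1/2}\,(T+17.8),$$

with $T$ the daily mean temperature and $R_a$ the extraterrestrial radiation

$$R_a = \frac{S_0}{\pi}\Big(\frac{r_0}{r}\Big)^2
  \big[H \sin\phi \sin\delta + \sin H \cos\phi \cos\delta\big],
  \qquad S_0 = 118.02\ \mathrm{MJ\,m^{-2}\,d^{-1}}.$$

The solar declination, inverse relative Earth–Sun distance and sunset hour
angle follow the standard FAO-56 approximations — the usual companions of the
Hargreaves model. Numerical edge cases are handled explicitly:

* polar night clamps the `arccos` argument, so $H = 0$ and $R_a = 0$;
* `ETp` is floored at zero (it can only go negative below a mean temperature
  of −17.8 °C, where evaporative demand is nil);
* days with `ETp ≤ 1e-6` mm/day have an *undefined* aridity index: they are
  excluded from DC and CDHC rather than counted as dry, because a frozen or
  dark day is not meteorological drought;
* both thresholds are strict inequalities (`> 30`, `< 0.2`); a day with
  `AI = 0.2` exactly is not dry.

Gap-filling is deliberately absent: a cell-year that does not cover the full
214-day window raises an error, because silently imputing extreme-day counts
would bias every downstream correlation.

## CO₂-equivalent accounting

Gas fluxes in elemental mass convert linearly to CO₂ equivalents on the
GWP100 scale: $E_{CO_2} = F_{CO_2}\cdot 44/12$,
$E_{N_2O} = F_{N_2O}\cdot 44/28 \cdot 273$,
$E_{CH_4} = F_{CH_4}\cdot 16/12 \cdot 27$, summed to
$E_{GHG}$ and divided by yield for the GHGI. The converters are
unit-agnostic linear maps; `ghg_intensity()` additionally applies the factor
10 that turns g m⁻² into kg ha⁻¹. Two sign/guard conventions matter:

* positive CO₂ flux is net carbon release; sequestration is negative and
  propagates to a negative (sink) intensity;
* yields at or below `y_min = 1` kg/ha are masked to `NA` instead of
  producing unbounded ratios; masked cell-years stay missing through every
  later stage (a moving window containing one is itself `NA`).

## Factorial attribution

The emulated experiment set follows the classic
all-drivers-minus-one design: S1 holds every driver constant, S2 activates
all of them, S3–S9 each deactivate exactly one of *climate, CO₂ fertilisation,
N deposition, land use, fertiliser (incl. manure), irrigation, tillage*, and
S10/S11 isolate land-use change with management frozen at its earliest level.
A driver's contribution is the elementwise difference S2 − S(without-it);
the all-factor effect is S2 − S1. Because the synthetic design is additive
and non-interacting, the per-driver contributions sum *exactly* to the
all-factor effect — a closure property the test suite asserts at zero noise.
In real model output, interactions would land in the residual between the two
sides; the difference scheme itself has no way to see them, which is a known
limitation of the design rather than of the implementation.

## Moving-window sensitivity

Sensitivity is the correlation R between an annual extreme-day index and an
annual response (yield, net GHG, GHGI) within a 20-year moving window,
labelled by the window's **final** year: with data for 1960–2018 the windows
end 1979…2018, giving 40 windows. The sign of R is the direction of the
coupling, its magnitude the strength.

Choices that were genuinely open, and how they were settled:

* **Detrending scope.** All series are linearly detrended once over the full
  period before windowing (`detrend = "full"`), so slow co-trends (warming,
  technology, fertiliser ramps) cannot masquerade as year-to-year coupling.
  Per-window detrending is available as `detrend = "window"` for comparison;
  on the synthetic suite the two agree closely because the injected trends
  are linear.
* **Which series is detrended.** The final response variable itself (yield,
  EGHG, GHGI each directly), not its components before the ratio.
* **Window labelling.** By the final year of the window (1960–1979 → 1979).
* **Zero-variance windows** (e.g. HC ≡ 0 in a cold cell) give `NA`, excluded
  from medians and area shares — never a fabricated 0.
* **Significance.** Two-sided α = 0.05 throughout, with no multiple-testing
  correction across grid cells; treat per-cell significance maps as
  descriptive, not inferential (documented caveat).

Per-cell trends of the R series use OLS with a two-sided t test; regional
trends use the Mann–Kendall test (tie-corrected variance, continuity
correction) with a Theil–Sen slope, which needs no normality assumption.
Uncertainty across the 3 climate-dataset × 3 correlation-method combinations
is summarised per cell and window as the standard error $SE = s/\sqrt{n}$.

## Tillage effects and the recommendation scheme

For each cell, window and extreme-day index, the effect of an all-NT (or
all-CT) counterfactual is the difference in sensitivity
`D = R_tillage − R_actual`, classified by sign: for yield, `D > 0` is a
positive effect (PE); for GHG and GHGI the signs flip (`D > 0` is adverse).
`D = 0` is *neutral* and enters neither the numerator nor the denominator of
the positive-effect frequency — the sign rules only define labels for strict
inequalities, and with a deterministic process emulator exact zeros really
occur (e.g. yield is untouched by the CO₂-only tillage multiplier).

A cell is recommended a practice when its positive-effect frequency across
all windows strictly exceeds 0.75. When both practices qualify the
higher-frequency one wins; exact ties go to NT by default (the
emission-reduction default; configurable). Recommendation maps are produced
per index plus a consensus layer (majority across the three indices).

**Reduction statistic.** How much the recommended scheme lowers regional
sensitivity is quantified as: per window, the spatial median R over
recommended cells under the actual and the optimal scheme; the relative
change $100(\tilde R_{act} - \tilde R_{opt})/|\tilde R_{act}|$; averaged
over windows; reported per index with mean and range across indices. This
aggregation (regional median, relative change, window-averaged) is an
explicit reconstruction — no canonical formula exists for this quantity —
and windows whose actual median magnitude falls below 1e-6 are excluded
rather than divided through.

## The synthetic generator

The generator emulates gridded agroecosystem-model output, not any real
geography. Defaults define the study conditions and are not tuned per run:

* **Grid and period:** 20 × 20 cells spanning 30–49° N, calendar years
  1960–2018 (59 years → 40 windows of 20).
* **Daily maximum temperature:** sinusoidal seasonal cycle (amplitude 11 °C,
  peak at day-of-year 196) + latitudinal gradient (−0.25 °C/deg) + warming
  trend (0.25 °C/decade, stepped by calendar year) + a yearly shared anomaly
  (SD 0.6 °C) + iid daily noise (SD 2 °C). The seasonal term is a complete
  cosine period over each calendar year, so it sums to exactly zero within
  every year and annual means carry only the injected trend — which is why
  the trend-recovery test can demand 1e-9 accuracy.
* **Minimum temperature:** maximum minus an absolute-normal diurnal range
  (|N(10, 2²)| °C), so `tmax ≥ tmin` holds by construction and the
  Hargreaves √range term stays defined.
* **Precipitation:** mixed Bernoulli/Gamma — dry-day probability 0.45
  drifting by +0.011/decade (about two extra dry days per decade over the
  214-day window, a mid-latitude drying analogue), wet-day amounts
  Gamma(shape 0.8) scaled so the baseline mean is 2.5 mm/day.
* **Responses:** additive linear model per cell-year — intercept + per-year
  driver ramps + extreme-day couplings + Gaussian noise, yield floored at 0.
  Default couplings (per extreme day): yield −8/−5/−10 kg/ha for
  HC/DC/CDHC; CO₂ flux +0.6/+0.25/+0.4 g C m⁻²; N₂O +0.002 g N m⁻² per dry
  day (0.003 for the spring-wheat preset). Winter wheat starts at 3000
  kg/ha, spring at 2200.
* **Tillage effect regions:** NT benefit (CO₂-coupling multiplier 0.5) in
  the western third, CT benefit in the eastern third, a mild penalty (1.15)
  elsewhere. The multipliers act on the **CO₂-flux couplings only**: scaling
  every gas coupling by one factor would leave a correlation-based
  sensitivity unchanged (Pearson R is scale-invariant), whereas shifting the
  index mix of EGHG — tillage chiefly modulating soil-carbon turnover — is
  both the physically sensible reading and one a correlation can detect.
* **Noise architecture:** one RNG stream per purpose and dataset variant,
  derived from the master seed (fixed multiplier/offset scheme in
  `edh_stream()`), so adding a scenario or variant never perturbs draws used
  elsewhere. Annual response noise is drawn once per cell-year and **shared
  across all scenarios**: the emulated process model is deterministic, so
  scenario runs differ only through their drivers. This makes attribution
  closure exact and tillage differences well defined. Response noise SDs
  (yield 150 kg/ha; CO₂ 6, N₂O 0.02, CH₄ 0.002 flux units) were fixed by a
  pre-build Monte-Carlo over 20 seeds at which the recommendation scheme
  recovers ≥ 97 % of the injected benefit regions with no false positives.

What the generator deliberately does **not** emulate: spatial
autocorrelation beyond the region masks, interannual precipitation regimes
(droughts lasting multiple years), nonlinear or interacting driver effects,
and any real-world geography or management. Passing tests therefore
demonstrate that the *pipeline arithmetic* recovers known structure — they
say nothing about how much structure real data contain.

## Ground-truth recovery checks

Two recovery designs anchor the test suite:

```{r recovery, eval = FALSE}
cfg  <- synthetic_config(seed = 1L)
edh  <- compute_edh_field(generate_daily_climate(cfg))
sens <- lapply(c(actual = "S2", nt = "S12", ct = "S13"), function(s)
  edh_sensitivity(edh, ghg_intensity(generate_scenario_outputs(edh, cfg, s)),
                  response_vars = "ghgi"))
map  <- recommendation_map(sens$actual, sens$nt, sens$ct)
```

* the consensus map must recover ≥ 90 % of the injected NT and CT regions
  with ≤ 10 % false positives outside them;
* on a **linear-response variant** (yield couplings and yield-driver ramps
  zeroed, so GHGI is exactly linear in the indices), the measured reduction
  statistic is compared against a closed form computed by covariance algebra
  from the index series, the injected coefficients and the noise variance —
  never from the generated responses. At zero noise the two agree to
  machine precision; with noise on, the aggregate (mean across indices)
  agrees within 10 %. The linear variant exists because GHGI — a ratio of
  two linear forms — admits no closed-form Pearson correlation in general.

## Problem sizes and runtime choices

The suite exercises structural tests on a 2 × 3 grid over 1998–2018 (two
windows — the smallest legal configuration) and the recovery tests on the
full 20 × 20 × 1960–2018 study scale; the Mann–Kendall calibration uses
5000 white-noise replicates at series length 40. These sizes were chosen so
the complete check runs comfortably on a single CPU while the study-scale
recovery still has 400 cells and 40 windows of spatial/temporal structure.

## Known limitations

* Pearson R as the sensitivity probe sees only monotone-linear coupling;
  Kendall and Spearman variants are built in precisely to bound that
  distortion, and the SE summary quantifies the spread.
* The attribution scheme cannot separate driver interactions from main
  effects (they fold into the S2 − S1 residual).
* The recommendation scheme conditions on GHGI alone by default; yield and
  GHG effect maps are produced as diagnostics, and a joint criterion is a
  one-line change in `recommendation_map(response = )`.
* No economics: switching costs, residue markets and machinery constraints
  are outside the model, so "recommended" means climatically favourable
  only.
* The daily aridity index with a fixed 0.2 threshold is a screening
  definition of dryness; spell duration and consecutive-event dynamics are
  not represented.
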