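---
title: "Modelling greenhouse evapotranspiration with a constrained Priestley-Taylor coefficient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling greenhouse evapotranspiration with a constrained Priestley-Taylor coefficient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iptet)
```

## The model

Evapotranspiration (ET) of a greenhouse crop is the sum of soil
evaporation and canopy transpiration.  The classical Priestley-Taylor
model writes the latent heat flux as a multiple of the equilibrium
(radiation-limited) evaporation,

$$\lambda ET = \alpha\,\frac{\Delta}{\Delta + \gamma}\,(R_n - G),$$

with $\Delta$ the slope of the saturation vapour pressure curve at air
temperature, $\gamma$ the psychrometric constant, $R_n$ net radiation
and $G$ soil heat flux, and a fixed coefficient $\alpha_0 = 1.26$.  In a
semi-closed greenhouse that single constant fails in three predictable
ways: the topsoil dries out early in the season (soil evaporation is
water-limited, not energy-limited), midday air temperature departs from
the crop optimum, and the canopy senesces late in the season.

This package implements the improved form.  Net radiation is split by
Beer-Lambert extinction through the canopy, $\tau = e^{-k\,\mathrm{LAI}}$,
into a soil share $R_{ns} = \tau R_n$ and a canopy share
$R_{nc} = (1-\tau) R_n$.  Each share gets its own coefficient:

$$\lambda E = f_{sw}\,\alpha_{s0}\,\frac{\Delta}{\Delta+\gamma}(R_{ns} - G),
\qquad
\lambda T = (1 - f_s)\,f_t\,\alpha_{c0}\,\frac{\Delta}{\Delta+\gamma}R_{nc},$$

where

* $f_{sw}$ is the soil evaporative water stress coefficient: 1 while the
  effective topsoil saturation $S_e = (\theta-\theta_w)/(\theta_s-\theta_w)$
  is at least 0.75, and $S_e$ itself below that;
* $f_t = \exp(-(T_a/T_{opt} - 1)^2)$ is a Gaussian penalty on relative
  deviation from the optimum temperature (26 °C for tomato);
* $f_s$ is the leaf senescence index, 0 before the configured onset date
  and $0.05(\exp((CDC/0.98)\,t) - 1)$ afterwards, clipped to $[0,1]$,
  with $t$ the days since onset and $CDC$ the canopy decline coefficient;
* $\alpha_{s0}$ and $\alpha_{c0}$ are the energy-limited soil and canopy
  coefficients.  $\alpha_{s0}$ is 1 under a dense canopy
  ($\tau \le \tau_c$) and rises linearly to $\alpha_0$ as the canopy
  opens; $\alpha_{c0} = (\alpha_0 - \alpha_{s0}\tau)/(1-\tau)$ is defined
  so that the energy-weighted mean recovers $\alpha_0$ exactly,
  $\alpha_{s0}\tau + \alpha_{c0}(1-\tau) = \alpha_0$.

With the soil heat flux closure $G = f_G R_{ns}$ the bulk coefficient
has the closed form

$$\alpha_e \;=\; \frac{f_{sw}\,\alpha_{s0}\,(1-f_G)\,\tau \;+\;
 (1-f_s)\,f_t\,\alpha_{c0}\,(1-\tau)}{1 - f_G\,\tau}.$$

We derived this expression by combining the component equations rather
than transcribing it, and the test suite enforces the derivation: on
1,000 random parameter draws the closed form must agree with the
component assembly $(\lambda E + \lambda T)/\lambda ET_{eq}$ to a
relative $10^{-10}$.  Releasing every constraint
($f_{sw} = f_t = 1$, $f_s = 0$, $f_G = 0$) collapses $\alpha_e$ to
$\alpha_0$ for any LAI — the classical model is an exact special case.

ET depth is obtained per hour as
$ET = \lambda ET \cdot 3600 / \lambda_v$ mm (with
$\lambda_v = 2.45\times10^6$ J kg$^{-1}$ and water density
1000 kg m$^{-3}$), and daily ET is the sum of the hourly depths; $\Delta$
is evaluated from the hourly air temperature, never from a daily mean.

## Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `alpha_0` | recommended Priestley-Taylor coefficient | – | 1.26 |
| `k` | canopy extinction coefficient | – | 0.7 |
| `tau_c` | critical transmission at maximum cover | – | 0.55 |
| `CDC` | canopy decline coefficient | d$^{-1}$ | 0.08 |
| `T_opt` | optimum air temperature | °C | 26 |
| `f_G` | soil heat flux fraction of $R_{ns}$ | – | 0.45 |
| `lambda_v` | latent heat of vaporization | J kg$^{-1}$ | 2.45×10⁶ |
| `elevation` | site elevation (sets $\gamma$) | m | 78 |
| `theta_s`, `theta_w` | saturated / wilting topsoil content | cm³ cm$^{-3}$ | 0.32 / 0.09 |

The defaults describe a drip-irrigated tomato crop in a solar greenhouse
on a silt loam.  `k = 0.7` is a typical measured value for a greenhouse
tomato canopy; when paired above/below-canopy PAR readings exist,
`fit_extinction_coefficient()` recovers `k` as the median of the weekly
Beer-Lambert fits, which is how a season constant should be calibrated.
All defaults are overridable in `ipt_params()` or a YAML run
configuration.

## Numerical and design choices

Several published forms of this model family are typographically
ambiguous; the package fixes one reading of each and documents the
alternative:

* **Senescence index.**  We use
  $f_s = 0.05(\exp((CDC/0.98)\,t)-1)$, which vanishes at onset
  ($f_s(0)=0$) and matches the canopy-decline family used by
  crop-growth models of the AquaCrop type.  The alternative literal
  reading $0.05\exp(0.98\,CDC\,t-1)$, which starts at ≈0.018 instead of
  0, is available via `senescence_index(..., literal = TRUE)` for
  sensitivity checks.  Onset is a configured calendar date (default in
  the synthetic presets: the first day of the late stage); automatic
  onset detection is out of scope.
* **Transmission fraction.** $\tau = e^{-k\,\mathrm{LAI}}$ with no
  leading transmissivity scalar; any other scaling puts $\tau$ outside
  $(0,1]$ and breaks the soil/canopy coefficient algebra.
* **MAE.** The standard mean absolute pairwise error
  $\tfrac1n\sum|O_i-P_i|$.  The variant $\tfrac1n\sum|O_i-\bar P|$
  (scatter of observations about the prediction mean) is exposed as
  `mae_literal()` for comparison, never used as MAE.
* **Vapour physics.** $e_s$, $\Delta$ and $\gamma$ follow the FAO-56
  conventions of the reference-ET literature; $\gamma$ is computed once
  per site from elevation.
* **Soil moisture input.** When both 5 cm and 10 cm sensors are present
  their mean drives $S_e$; a single `theta` column is used as is.
  $\theta$ is clipped to $[\theta_w, \theta_s]$ before rescaling.
* **Measured soil heat flux** overrides the $f_G$ closure wherever a `G`
  column is supplied; the closure remains what defines the closed-form
  $\alpha_e$.
* **Nighttime condensation.** Negative hourly ET is clipped to zero by
  default (`clip_negative_et`), matching what weighing lysimeters
  report; the latent-heat columns are left unclipped so energy budgets
  stay inspectable.
* **Daily LAI.** Weekly observations are interpolated with the
  shape-preserving piecewise cubic Hermite interpolant (PCHIP,
  `pracma::pchip`, the same algorithm as MATLAB's), which passes through
  every observation and cannot overshoot between knots; with only two
  observations the interpolant degenerates to the chord.  Extrapolation
  is refused.
* **Path analysis.**  Direct paths are standardized OLS coefficients
  solved from the normal equations on the correlation matrix; indirect
  paths are $r_{ij}P_j$; the decision coefficient is $2P_ir_i - P_i^2$.
  Sample statistics use $n-1$ denominators.  The ventilation window
  9:00–16:00 is inclusive on both ends (8 hourly rows per day).  The
  identity $r_i = P_i + \sum_{j\ne i} r_{ij}P_j$ holds to numerical
  precision whenever $P$ and $r$ come from the same data; published
  tables do not always satisfy it, so the package reports the residual
  per driver instead of forcing agreement.

## What the synthetic generator does and does not emulate

`greenhouse_scenario()` ships two season presets (a 2019-like and a
2020-like tomato season, mid-March to mid-July, four contiguous growth
stages).  `generate_scenario()` then produces:

* **Microclimate** — net radiation as a daytime half-sinusoid peaking at
  13:00, modulated by day-to-day lognormal AR(1) "cloudiness" and small
  hourly noise, rescaled so each stage's 6:00–18:00 mean equals the
  preset target (104–154 W m⁻²); air temperature and VPD track the
  radiation shape with a 1 h lag plus AR(1) noise around stage means;
  wind speed is a light positive series (daily mean ≈ 0.1 m s⁻¹).
* **Phenology** — LAI from ≈0.1 at transplanting to a 3.46 peak in the
  middle stage and a senescent decline, via PCHIP through sparse knots;
  plant height peaks at 145 cm.
* **Soil moisture** — exponential drydown with instantaneous drip
  refills toward $0.95\,\theta_s$; the initial stage receives only the
  transplanting irrigation, so $S_e$ dips well below 0.75 (an
  early-season water deficit), while later stages are kept above it by
  trigger-based irrigation, making $f_{sw}=1$ there.
* **Observations** — lysimeter-like hourly ET as the model series with
  5 % multiplicative Gaussian noise, truncated at zero.

All randomness flows from one explicit seed and the generators restore
the caller's RNG state.  The curves are analytic shapes plus AR(1)
noise: they exercise every code path (radiation partition, all three
constraints, irrigation-driven stress release, senescence) with
realistic magnitudes, but they are not a greenhouse energy-balance
simulation.  Passing tests on synthetic data therefore demonstrate
internal correctness and recoverability (for example, the soil heat
fraction $f_G = 0.45$ is recovered within ±0.05 from a season of 5 %
noisy latent heat flux), not predictive skill on real lysimeter records,
and no attempt is made to reproduce a measured season's ET total beyond
order of magnitude.

## Problem sizes

The test suite mostly runs a two-week early-season slice (336 hourly
steps); the parameter-recovery and pipeline checks use a full synthetic
season (124 days, 2,976 hourly steps), and the closed-form/assembly
equivalence uses 1,000 random draws.  The whole suite completes in a few
seconds.

## Known limitations

* The model is radiation-driven: it has no aerodynamic term, so it
  inherits the Priestley-Taylor weakness for strongly advective or
  ventilated conditions, and wind speed enters only the driver analysis,
  never the flux computation.
* Soil evaporation under drip irrigation is spatially uneven; a single
  topsoil moisture series (or the mean of two depths) cannot represent
  wetted/dry strips, which is a known source of early-season error.
* `k` is a season constant; time-varying canopy structure (clumping,
  leaf-angle changes) is not modelled.
* Senescence onset must be supplied; the senescence index is a
  calendar-driven decline, not a physiological model.

## A worked run

```{r example, eval = FALSE}
sc  <- greenhouse_scenario("2019")
inp <- generate_scenario(sc, seed = 1)
fit <- ipt(inp$met, inp$crop, inp$soil,
           params = ipt_params(senescence_onset = sc$stages$late$start))
fit
plot(fit)

obs <- generate_observed_et(fit$hourly$ET, 0.05, seed = 2)
et_metrics(obs, fit$hourly$ET)

pd <- cbind(fit$hourly[, c("timestamp", "Rn", "Ta", "VPD", "ET")],
            u2 = inp$met$u2)
path_analysis(pd, window = c(9, 16))
```
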