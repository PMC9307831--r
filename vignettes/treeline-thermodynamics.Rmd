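---
title: "Treeline thermodynamics: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treeline thermodynamics: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`treetherm` implements a desk-scale counterfactual experiment on Arctic and
alpine treelines. This vignette is the package's account of the science it
computes: the model and its assumptions, the parameters that matter, what the
synthetic forcing emulates, the numerical choices, and the places where the
design was genuinely open and a choice had to be made.

## 1. The question and the diagnostics

An ecosystem dissipates the radiative energy it absorbs by exporting latent
and sensible heat across its canopy top. We treat that export as *work*
performed against or along the vertical temperature structure. With
`T_surf` the ground (or snow) surface temperature, `T_air` the air above the
canopy and `h_e` the ecosystem height of a site pair, the package computes

* the **resultant temperature gradient** `(T_air - T_surf) / h_e`
  (`temperature_gradient()`); positive values are temperature inversions;
* the **signed work** `(LE + H) * -sign(T_air - T_surf)` (`work_flux()`),
  positive exactly when heat moves from high to low temperature.

Two sign choices partition every half-hour into four regimes
(`classify_work_case()`): (1) daytime export down a negative gradient
(positive work, the common case), (2) heat gain against a negative gradient
(negative, rare), (3) nocturnal heat gain down an inversion gradient
(positive), and (4) export *against* an inversion (negative) — the snowmelt
case. A record with zero gradient or zero net flux belongs to no case and is
reported as neutral (`NA`); by the sign convention its work is exactly zero.

Feasibility is then judged per scenario (`assess_feasibility()`): a scenario
is infeasible when its daily-mean work stays negative for at least
`threshold_days` consecutive days, or when its mean annual net leaf CO2 flux
is negative; a feasible scenario whose positive CO2 gain falls below its
paired existing-vegetation scenario is *disadvantaged*.

"Prolonged" negative work has no canonical definition; the default
`threshold_days = 14` is config-exposed. In the shipped study conditions the
infeasible counterfactuals produce negative-work runs of many weeks while
existing vegetation stays in the single-digit range (see
`scripts/acceptance.R` output), so any threshold between one and four weeks
yields the same verdicts.

## 2. Model structure

Each scenario couples four pieces on a half-hourly step:

1. **Vegetation** (`scenario_set()`, `leaf_area_density_profile()`): plant
   functional groups (evergreen needleleaf trees, suppressed deciduous
   trees, shrubs, grasses/sedges) with a vertical extent and a maximum LAI,
   distributed uniformly over a 20-layer above-ground grid. Non-evergreen
   groups green up over a 30-day cosine ramp starting at the first snow-free
   day of the year (not before day 60) and senesce over days 270–300 —
   tying phenology to snowmelt is what lets an extended snow season shorten
   the carbon-uptake window. Snow burial removes the buried fraction of a
   group's extent; a fully buried group contributes nothing.
2. **Radiation**: Beer–Lambert attenuation with extinction `k = 0.5` times a
   needleleaf clumping index `0.5`; layer absorption is the flux difference
   across the layer times `1 - leaf_reflectance`; the ground receives the
   transmitted flux times `1 - albedo` (snow albedo decays from 0.85 fresh
   to 0.6 with a 10-day e-folding age).
3. **Energy balances**: every occupied (layer, group) cell solves
   `absorbed = H + LE + eps*sigma*(T_leaf^4 - T_air_local^4)` per unit leaf
   area (`leaf_energy_balance()`), with local air temperature interpolated
   between the surface and above-canopy air. The ground/snow surface solves
   the analogous balance including conduction into a 12-layer explicit soil
   column; while snow is present the surface temperature is capped at
   273.15 K and the excess balance becomes melt energy, at most
   `SWE * 0.334 MJ/kg` worth per step, with any surplus returned to the
   ground heat flux.
4. **Carbon** (`leaf_photosynthesis()`, `autotrophic_respiration()`):
   photosynthesis is a rectangular hyperbola in absorbed PAR (45% of
   absorbed shortwave) capped at the group capacity, with a symmetric
   temperature envelope peaking at 20 °C and vanishing at 0/40 °C, and is
   gated by the dormancy switch — open only when the element is unburied,
   the trailing 5-day mean air temperature exceeds +5 °C, and the group is
   in its phenology window. Respiration is Q10 (= 2.0) in leaf temperature,
   scales with leaf area, and never switches off; buried leaf area respires
   at 10% of the unburied rate. This asymmetry — respiration runs while
   photosynthesis is blocked — is what converts a late melt-out into an
   annual carbon deficit.

The per-step energy closure `Rn_abs - LE - H - G - M` is recorded; under the
bulk longwave treatment the identity holds by construction up to solver
residuals, and the tests require it below 1 W/m² at every step (achieved
residuals are below 0.1 W/m²). Snow mass balance is exact: change in SWE
equals snowfall minus melt; sublimation is an energy term only (a stated
simplification).

## 3. Synthetic forcing: what it emulates, what it does not

`generate_forcing()` produces half-hourly drivers with the statistical
skeleton of flux-tower records: a seasonal plus diurnal temperature cycle
with an AR(1) anomaly (3 K stationary spread, ~3-day decorrelation); a
probit-transformed AR(1) cloudiness whose lag-1 autocorrelation is the
archetype's `cloud_persistence`; clear-sky shortwave as top-of-atmosphere
irradiance times a bulk transmissivity of 0.75, reduced by cloud cover, and
exactly zero when the sun is below the horizon; longwave from a Brutsaert
clear-sky emissivity enhanced by cloudiness; a two-state wet/dry day chain
(wet-after-wet probability 0.65, stationary wet fraction per archetype) with
exponential daily amounts spread over the day; phase split at a fixed
threshold (1 °C; exactly at the threshold is rain, a documented tie-break).
Wind is Weibull-marginal over an AR(1) driver; pressure is the barometric
value for the archetype elevation. The model calendar is 365-day years with
clock time equal to local solar time.

The four archetypes are *plausible climatologies*, not site measurements: a
subalpine forest belt (mean 274.7 K, 800 mm), the alpine zone above it
(271.7 K, 950 mm, the snow-rich setting in which the counterfactual fails),
and a colder, drier sub-Arctic/Arctic pair (264–265 K, 250–300 mm) with
strong seasonality. What the generator does **not** emulate: synoptic
weather structure beyond lag-1 persistence, rain-on-snow energetics,
humidity–precipitation coupling, topographic shading, blowing-snow
redistribution (important at real fellfield sites), and observation gaps.
Consequently, passing tests demonstrate that the *mechanisms* — shading →
delayed melt → pinned surface → inversions → negative work and carbon loss —
operate and discriminate between vegetation structures under realistic
boundary conditions; they do not validate the model against any particular
tower record.

One consequence worth naming: the synthetic subalpine winter keeps a
persistent snowpack, so the existing forest scenario also accrues long
*winter* negative-work spells (canopy heat export over cold snow), where
intermittent-snow forest sites show only sporadic ones. The above-treeline
contrast — the discriminating comparison — is unaffected.

## 4. Parameters

All physics tunables live in `physics_params()` and can be overridden
individually. The consequential ones:

| parameter | default | units | role |
|---|---|---|---|
| `k_ext`, `clump` | 0.5, 0.5 | – | effective canopy extinction `k_ext*clump` |
| `ground_albedo` | 0.2 | – | snow-free ground shortwave albedo |
| `snow_albedo_fresh/old`, `snow_albedo_efold` | 0.85 / 0.6, 10 | –, d | snow albedo decay |
| `snow_density` | 250 | kg/m³ | fixed bulk density (depth = SWE/density) |
| `k_snow` | 0.3 | W/m/K | snow insulation of the ground heat flux |
| `r_bl` | 50 | s/m | leaf boundary-layer resistance per unit LAI |
| `r_stom_open/closed` | 200 / 5000 | s/m | two-state stomatal resistance (the dormancy switch is binary by design) |
| `shelter_coef` | 1.0 | per LAI | e-folding of under-canopy turbulent exchange |
| `soil_k`, `soil_C` | 1.0, 2.2e6 | W/m/K, J/m³/K | soil column conduction |
| `par_frac`, `par_half` | 0.45, 100 | –, W/m² | PAR conversion, light half-saturation |
| `t_dorm` | 278.15 | K | 5-day mean temperature to leave dormancy |
| `q10`, `buried_resp_frac` | 2.0, 0.1 | – | respiration temperature response, subnivean reduction |

Vegetation defaults: evergreen tree LAI 4.0 for the temperate forests and
0.5 for the sparse sub-Arctic forest–tundra stand, shrubs 1.0,
grasses/sedges 1.5, suppressed deciduous understory trees 1.0; ecosystem
heights `h_e` of 20/12/8 m for the three pairs. Only the sparse sub-Arctic
tree LAI is anchored in the forest–tundra setting these scenarios emulate;
the rest are field-plausible defaults, all exposed in the scenario config
(`inst/extdata/scenarios_treeline.cfg`).

## 5. Numerical choices

* **Leaf balance**: the exported `leaf_energy_balance()` uses bracketed root
  finding on `[T_air - 40, T_air + 40]` K to a residual below 0.01 W/m²; no
  sign change in the bracket is reported as a solver failure with the
  offending inputs. The simulation loop solves the same residual with a
  vectorized damped Newton iteration (bisection fallback) across all
  occupied cells; the test suite checks both against an exhaustive 0.001 K
  residual scan to within 0.002 K.
* **Surface balance**: damped Newton with a wide bisection fallback; the
  residual is monotone in the surface temperature, so the root is unique.
* **Soil column**: explicit conduction with layer thicknesses 0.05–1.0 m
  (4 m total) and a zero-flux bottom; the stability bound
  `dt <= 0.5 min(dz)^2 C/k` is checked and violated configurations are
  rejected with the required step reported. The scheme conserves energy to
  rounding.
* **Tie-breaks**: precipitation exactly at the phase threshold is rain;
  `sign(0) = 0` makes work exactly zero at a vanishing gradient; records
  with zero net flux are excluded from the four cases; partial days are
  dropped (with a warning) from daily means.
* **Initialization**: soil and canopy start at the archetype mean annual
  temperature with no snow; the first simulated year is discarded as
  spin-up in all study runs.
* **Degenerate inputs**: zero-LAI profiles short-circuit the canopy;
  trace snow (below 0.1 mm SWE) still caps the melting surface so that no
  residual mass lingers unmeltable; buried groups drop out of the leaf
  solver but keep respiring at the reduced rate.

## 6. Design choices that were genuinely open

* **Simplified physics core.** The study design calls for a multi-layer
  canopy model; a full research code (prognostic turbulence, multi-layer
  longwave, soil moisture) is out of scope here. The core keeps every
  mechanism the diagnostics depend on — shading, burial, melt-pinned surface
  temperature, within-canopy temperature structure, dormancy — with
  config-exposed engineering parameterizations. Three ingredients proved
  load-bearing during bring-up and are deliberate: the clumping index
  (without it a closed canopy starves the forest floor and even existing
  forests sit in permanent inversion), ground-view weighting of canopy
  longwave toward the cool lower layers (without it canopy emission cancels
  the shading and snowmelt is not delayed), and strong under-canopy
  sheltering (`exp(-LAI)`; with weak sheltering, sensible heat from warm
  spring air melts forest-floor snow as fast as open snow).
* **Friction velocity is not an input**; aerodynamic resistance comes from
  wind speed through a neutral log profile (roughness `0.1 h`, displacement
  `0.67 h`, wind floored at 0.5 m/s).
* **Within-canopy air temperature** interpolates linearly between the
  (lagged) surface temperature and the above-canopy air — a stand-in for a
  turbulence closure, flagged as a limitation.
* **Counterfactual construction**: the trees-added scenario carries the
  below-treeline group list unchanged under the above-treeline forcing; the
  understory-only scenario removes the evergreen overstory but keeps
  suppressed deciduous trees (they are understory). Both members of a pair
  share `h_e`, the pair's maximum canopy height.
* **LAI–work magnitude property**: evaluated across the study's own
  vegetation structures under one common forcing. An artificial
  evergreen-LAI ladder shows a near-tie in the mid-LAI range (a sparse tall
  canopy trades surface flux for canopy flux almost one-for-one), so the
  monotone growth of work magnitude with leaf area is a statement about the
  study's vegetation structures, not about arbitrary LAI increments.

## 7. Study problem sizes

The shipped studies use half-hourly steps over 365-day years: three years
(one spin-up + two study years) for the alpine mechanism comparison, two
years for the subalpine forest-vs-understory advantage, and two years per
scenario for the full pipeline runs; the acceptance script runs the full
US pair at three years. These sizes give each diagnostic a full snow season
per study year while keeping a complete run in the tens of seconds.

## 8. Known limitations

No turbulence closure; single bulk longwave exchange (no multi-layer
radiative transfer); no soil moisture, root uptake or permafrost latent
heat; snow cold content ignored (zero-heat-capacity snowpack) and
sublimation does not remove snow mass; respiration scales with leaf area
only (no woody tissue term); uniform leaf distribution within each group's
extent; peat soils represented only through bulk conductivity and heat
capacity; 365-day calendar at solar longitude zero. Each of these sharpens
or dampens absolute numbers; none of them creates the qualitative
above/below-treeline asymmetry, which survives parameter variation across
seeds (see the acceptance script).

```{r}
library(treetherm)
cfg <- run_config("US", n_years = 3, spinup_years = 1, seed = 1)
res <- run_site_pair(cfg)
res$comparison
```
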