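---
title: "Methods: paired LAI experiments and the energy-balance decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired LAI experiments and the energy-balance decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenfeedback)
```

## The question and the experimental design

Vegetation greening perturbs near-surface temperature through biophysical
pathways whose strength and even sign differ by season: evapotranspiration
cools most effectively in warm months, canopy darkening warms most where
snow is masked, and energy perturbations can be carried into later seasons
by soil moisture and the circulation. `greenfeedback` isolates these
effects with the paired-experiment logic standard in prescribed-vegetation
modelling: one dynamic-LAI run (SCE) and, per growing season, a control in
which only that season's LAI is fixed to its multi-year monthly
climatology (`make_control_lai()`). Both are run as ensembles whose
members share seeds one-to-one, and ensemble-mean differences
(`delta_field()`) give the induced response — in-season (intra) and in
all later seasons (inter/carry-over, `split_intra_inter()`,
`lagged_sum()`).

Two conventions the design leaves open were fixed as follows:

* **Ensemble averaging precedes spatial averaging and trend fitting.**
* **Members are paired by seed** (same initial conditions and the same
  circulation-noise path in SCE and control). Pairing is a variance
  reduction: shared noise cancels in the difference. A consequence worth
  knowing is that the residual standard error of an induced-trend series
  is almost independent of ensemble size here — member-to-member spread in
  the difference fields comes only from state-dependent nonlinearity, not
  from independent noise draws. The suite therefore checks that member
  trends scatter with strictly positive spread and average to the
  ensemble-mean trend, rather than expecting large-sample SE shrinkage.
* **DJF labelling.** The winter labelled with year *y* aggregates
  December of *y* with January and February of *y + 1* (the winter that
  follows growing-season year *y*), preserving the causal ordering of
  carry-over effects; a 33-year record therefore yields 32 winters.
* **Spin-up.** Each member recycles its first calendar year of LAI once
  and discards it, removing initial-condition transients while keeping
  the output span equal to the input span.

## The toy column model

The simulator (`simulate_run()`) is a deliberately minimal monthly column
model on a regular lat-lon grid; it is **not** a GCM emulator in any
quantitative sense. Each mechanism of interest appears as the simplest
closed form that makes it testable:

* **Albedo:** `α = α_canopy + (α_bg − α_canopy) e^(−k·LAI)` with the
  background `α_bg` equal to bare ground (0.30) or snow (0.70) from a
  prescribed latitude-month snow table; canopy albedo 0.15, extinction
  `k = 0.5`. Snow is prescribed, not prognostic: only the snow-on versus
  snow-off masking contrast matters for the shoulder seasons.
* **Aerodynamic resistance:** `r_a = r_a0/(1 + c·LAI)` (100 s m⁻¹,
  `c = 0.25`): denser canopies are rougher.
* **Evaporative fraction:** `β = β_max (1 − e^(−k·LAI·v)) · min(1, SM/SM_c)
  · s(T)/(s(T)+γ)` plus a small bare-soil term; `v` switches vegetation
  off under snow, `s(T)` is the saturation-vapour-pressure slope, so
  vaporisation is a more efficient cooling pathway at higher temperature.
  The transpiration share of ET is `1 − e^(−k·LAI·v)`.
* **Surface energy balance:** `S_dn(1−α) + ε_s σ(ε_a T_a⁴ − T_s⁴) =
  H + λE` with `G ≡ 0` on these timescales, `λE = β · max(0, S_net +
  L_net)`, `H = ρC_p (T_s − T_a)/r_a`; constants `ε_s = 0.95`,
  `σ = 5.67×10⁻⁸`, `ρ = 1.205`, `C_p = 1013` (SI units). A vectorised
  Newton iteration solves for `T_s` (tolerances 10⁻⁴ W m⁻² and 10⁻⁶ K,
  50-iteration cap, initial guess carried from the previous month); in
  the time stepper, air temperature `T_a = w T_s + (1−w) T_a^bg +
  b·z500` is substituted into the balance so the accepted pair closes the
  budget to machine precision, which the suite asserts at every cell and
  month.
* **Bucket hydrology:** capacity 150 mm, evaporation limited by stored
  water plus precipitation, overflow above capacity and a linear
  baseflow; the monthly budget `P − E − R = ΔSM · capacity` closes
  exactly, so spring ET excess produces a summer moisture deficit — the
  carry-over pathway.
* **Water-vapor feedback:** a humidity index with exponential memory
  (`q ← (1−a) q + a·λE/λE₀`, `a = 0.5`) raises air emissivity
  (`ε_a = 0.72 + 0.10 q`, capped at 0.995) and weakly dims shortwave
  (`c_sw = 0.05` per unit q), a minimal vapor/cloud shading term.
* **Circulation proxy:** `z500 = (z_n + z_c) · pattern(lat, lon)`, with
  `z_n` an AR(1) internal-variability index (φ = 0.7, innovation SD 8 m,
  shared across the grid and identical between paired runs) and `z_c` a
  slow component (φ_c = 0.92) nudged by the domain-mean latent-heat
  anomaly (0.05 m per W m⁻²). The slow component is the design choice
  that lets growing-season energy perturbations persist into winter
  without the contemporaneous circulation response overwhelming local
  summer evaporative cooling; a single fast-coupled index did the
  latter, so the two timescales were separated. Both couplings are toy
  placeholders and must not be read as a fitted atmosphere.

Two forcing regimes are built in (`default_forcing()`): `"wet"`
(precipitation ample year-round, so soil-moisture stress is inactive and
the LAI-ET pathway is unconfounded) and `"moisture_limited"` (dry
summers, so the bucket's spring memory controls summer β). The background
temperature cycle accepts per-month linear trends, used to impose
external warming asymmetries when studying the seasonal amplitude.

## The decomposition

Differencing the energy balance between paired runs and linearising in
the temperature changes gives

ΔT_s = ΣF / f_s + (ρC_p/r_a + 4ε_s σ ε_a T_a³) ΔT_a / (ρC_p/r_a + 4ε_s σ T_s³),

where ΣF collects the five equivalent surface radiative forcings
`−S_dn Δα`, `(1−α) ΔS_dn`, `−ΔλE`, `ρC_p r_a⁻² (T_s−T_a) Δr_a`,
`ε_s σ T_a⁴ Δε_a`, and `f_s = ρC_p/r_a + 4ε_s σ T_s³`
(`redistribution_factor_fs()`) converts W m⁻² to K. The air-side factor
`f_a = ρC_p/r_a + 4ε_s σ ε_a T_s³` converts each component to an
air-temperature contribution, and the unexplained remainder
`ΔT_a^cir = ΔT_a − ΣF/f_a` is attributed to advection/circulation; the
reconstruction is exact by construction and asserted to 10⁻¹² K.

Choices made where the formulation is genuinely open:

* **Coefficient variant.** The ΔT_a coefficient can be written with
  `T_a³` or `T_s³` in its numerator; both variants are implemented
  (`ta_coef = "air"`/`"surface"`) and the `"air"` form is the default
  because it is the exact first-order differential of the balance — the
  closure study (`closure_convergence_study()`) shows the attribution
  error falling ~4× per halving of the LAI perturbation, i.e. a clean
  second-order residual.
* **Baseline state.** Coefficients use the control run's state, either
  time-resolved (`baseline = "monthly"`, the default; required for the
  second-order closure property, since a climatological baseline leaves
  first-order mismatch terms) or its monthly climatology
  (`"climatology"`, used by the trend pipeline where a fixed reference
  state is the conventional choice).
* **Grouping.** Radiative = {α, S_dn, ε_a}, non-radiative = {λE, r_a},
  and `All = R + NR` exactly. Descriptions of this split sometimes list
  `−ΔλE` on both sides; it is treated here as belonging to the
  non-radiative (energy-dissipation) side only, consistent with the
  balance's right-hand side.
* **ΔT_a^cir is first order here.** Because the toy air temperature is
  anchored to an advected background, the circulation residual contains a
  genuine first-order advective term; only the ΔT_s closure is second
  order. This is a property of the toy coupling, not of the
  decomposition algebra.

## Statistics

Trends are ordinary least squares per decade with the two-sided t test at
n−2 degrees of freedom and the conventional star classes (0.01 / 0.05 /
0.1); yearly residuals are treated as independent (no autocorrelation
correction), the simplest defensible reading for 33-point series, and the
type-I error of the test is verified to sit at its nominal level under a
Gaussian null. Figure-caption-style uncertainty is reported as ±1
standard error of the trend. Stippling marks per-cell `p < 0.05` with no
multiple-testing correction (deliberately, matching common practice in
trend maps; the null significant-area fraction is verified ≈ α).
Correlations between seasonal LAI and its induced response are Pearson,
optionally on linearly detrended series — both paths are exposed because
shared trends otherwise masquerade as interannual covariation. Phase-space
summaries bin a cellwise response over two driver maps (20×20 bins,
minimum 5 cells per bin, both configurable) and report binned means plus
partial-dependence marginals; planted linear structure is recovered
within 2 SE in the suite.

## What the generator emulates, and what it does not

The LAI scenario generator reproduces the *structure* of the satellite
record the experiments prescribe: a 33-year monthly record with
season-specific linear trends (defaults 0.019/0.046/0.027 m² m⁻²
decade⁻¹ for spring/summer/autumn — the observed 1982-2014 rates — and a
trendless winter), a smooth July-peaking climatology, and white cell-level
noise (0.15 m² m⁻², chosen once as a realistic interannual variability).
It does not emulate spatial trend heterogeneity beyond an optional
pattern map, snow/cloud gaps (the record is gap-free by construction),
browning regions, or retrieval error structure. Passing tests therefore
demonstrate that the *pipeline* recovers what was planted under the
stated conditions — not that the toy model reproduces observed climate
magnitudes. The paper-scale headline numbers (GCM, 0.5° grid, full
physics) are outside what this desk-scale chain can or should reproduce;
all quantitative statements in the package are computed by its own tests
and acceptance script at the documented sizes.

## Problem sizes and determinism

The mechanism-level checks run at the package's documented study scale —
16×16 northern-land grid (25-90°N), 1982-2014, 30 seed-matched members —
and complete in about a minute each; unit and property tests use 5×4 to
8×8 grids and a few years. Every random element (scenario noise, member
initial conditions, circulation innovations) derives from explicit seeds
drawn up front, so identical configurations are bit-identical end to end,
including byte-identical study tables; this is asserted in the suite.

## Known limitations

Monthly time step with no diurnal cycle; prescribed snow and
precipitation; no prognostic clouds, CO₂ physiology, or ocean; the
ε_a-humidity and z500 couplings are monotone placeholders; trend
inference ignores serial correlation; and the spatial grid is coarse and
regular. The decomposition itself is exact algebra given paired-run
differences and is the portable part of the package: it applies unchanged
to externally produced gridded difference fields read through
`read_field()`.
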