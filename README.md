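# greenfeedback

Quantifying how seasonal vegetation greening feeds back on near-surface
temperature, with paired prescribed-LAI model experiments and a
surface-energy-balance decomposition.

Northern-hemisphere ecosystems have greened for decades, most strongly in
summer. Greening perturbs the land surface energy budget through several
biophysical pathways — stronger evapotranspiration (cooling), darker
canopies over bright ground or snow (warming), rougher canopies with more
efficient turbulent transfer, a moister and hence more emissive atmosphere
(warming), and soil-moisture drawdown that can carry a perturbation into
later seasons. `greenfeedback` packages the full analysis chain used to
separate and attribute these effects at desk scale, for researchers and
students of land-atmosphere coupling:

1. **LAI preparation and scenarios** — composite-to-monthly maxima,
   coarse-grid aggregation, PFT cover weighting, and a seeded generator of
   multi-year LAI records with season-specific trends (defaults: the
   observed 1982-2014 greening rates, JJA 0.046, SON 0.027, MAM 0.019
   m² m⁻² decade⁻¹).
2. **A toy LAI-driven land-atmosphere column model** on a lat-lon grid:
   monthly surface energy balance closed by a Newton solver, bucket soil
   moisture, prescribed snow masking, a humidity index driving air
   emissivity, and an AR(1) circulation proxy with a slow surface-coupled
   component.
3. **The paired seasonal-control design** — a dynamic-LAI run (SCE) against
   controls with one season's LAI fixed to climatology
   (LAI_CTL^MAM/JJA/SON), run as seed-matched initial-condition ensembles
   and differenced intra- and inter-seasonally.
4. **Energy-balance attribution** of the induced temperature change.
   Writing the balance `S_net + L_net = H + λE` with
   `S_net = S_dn(1-α)`, `L_net = ε_s σ (ε_a T_a⁴ - T_s⁴)` and
   `H = ρ C_p (T_s - T_a)/r_a`, the first-order response to paired-run
   differences is

   `ΔT_s = (−S_dn Δα + (1−α) ΔS_dn − ΔλE + ρC_p r_a⁻² (T_s−T_a) Δr_a + ε_s σ T_a⁴ Δε_a) / f_s + …`

   with the energy-redistribution factors
   `f_s = ρC_p/r_a + 4 ε_s σ T_s³` and
   `f_a = ρC_p/r_a + 4 ε_s σ ε_a T_s³`. Each equivalent-forcing term
   converts to an air-temperature contribution through `f_a`; the
   remainder `ΔT_a^cir = ΔT_a − ΣF/f_a` is attributed to
   advection/circulation. Components group into radiative
   (`α`, `S_dn`, `ε_a`) and non-radiative (`λE`, `r_a`) processes.
5. **Seasonal statistics** — OLS trends per decade with significance
   classes, per-cell trend maps with stippling, the seasonal temperature
   amplitude (July minus January), LAI-response correlations, latitudinal
   profiles, and binned phase-space summaries with partial-dependence
   marginals.

## Worked example

Close the surface energy balance at one state and convert a forcing to
temperature:

```r
library(greenfeedback)
p <- sim_params()
sol <- solve_surface_temperature(s_dn = 200, alpha = 0.2, eps_a = 0.8,
                                 t_a = 285, r_a = 60, beta = 0.3, p)
#> T_s = 287.606 K, lambdaE = 22.72, H = 53.02 W m-2, residual = 1.1e-13
redistribution_factor_fs(sol$t_s, 60, p)   # 25.47 W m-2 K-1
redistribution_factor_fa(sol$t_s, 60, 0.8, p)  # 24.45 W m-2 K-1
```

So at this state a sustained +1 W m⁻² surface forcing warms the surface by
1/25.5 ≈ 0.04 K.

Run a smoke-scale paired study (two seasonal controls, 3 members, 8×8
grid) and read off the induced in-season temperature trends:

```r
cfg <- study_config(nlat = 8, nlon = 8, years = 1999:2008, members = 3,
                    seed_base = 70, seasons = c("MAM", "JJA"))
res <- run_study(cfg)
subset(res$tables$intra_inter_trends, type == "intra")
#>  control_season target_season  type slope_decade se_decade p_value stars
#>             MAM           MAM intra     -0.00085   0.00962  0.9317  n.s.
#>             JJA           JJA intra     -0.01716   0.00607  0.0223    **
res$tables$sat_trends
#>       series slope_decade se_decade p_value stars
#>      sat_sce      -2.2730    1.8301  0.2494  n.s.
#>  sat_induced      -0.0416    0.0124  0.0101    **
```

Summer greening drives a significant in-season cooling trend
(−0.017 K decade⁻¹ here), spring greening a weak, non-significant
response — evaporative cooling is counterbalanced by albedo and
water-vapor warming in the cold season — and the LAI-induced component of
the seasonal temperature amplitude (July minus January) declines:
greening makes winters relatively warmer and summers cooler. The same
study can be launched from a shell via
`Rscript inst/cli/greenfeedback-study.R --config inst/extdata/study-smoke.yaml --out out/`.

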