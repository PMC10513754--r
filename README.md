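# maizecast

Maize yield estimation by crop growth simulation and sequential ensemble
Kalman filter (EnKF) assimilation of remotely sensed leaf area index
(LAI), aimed at the weak-growing **inbred lines** used in hybrid seed
production, whose canopy and yield a hybrid-parameterised model badly
overestimates.

The package implements the full chain a regional yield-mapping study
needs, each stage as a tested, reusable function:

1. **Weather & radiation** — daily weather ingestion with FAO-56 solar
   geometry and the Angstrom–Prescott relation
   `R_s = (a_s + b_s n/N) R_a` to derive global radiation from sunshine
   hours (`read_weather()`, `solar_geometry()`,
   `radiation_from_sunshine()`).
2. **Crop simulation** — a reduced-order, daily-step, potential-production
   maize simulator in the WOFOST tradition: thermal-time phenology
   (DVS 0→1→2 over `TSUM1`/`TSUM2`), canopy light interception
   `1 − e^(−k·LAI)`, radiation-use-efficiency growth with a
   piecewise-linear temperature response, DVS-driven partitioning,
   cohort-based leaf senescence, and yield = TWSO/(1 − moisture). The
   eight calibrated variety parameters (`SLATB000`, `SLATB078`, `CVO`,
   `TSUM1`, `TDWI`, `SPAN`, `TBASE`, `TMPFTB200`) plus a single
   growth-weakness factor GWF ∈ [0.3, 0.8] for inbred emulation
   (`simulate_crop()`, `crop_parameters()`, `set_growth_weakness()`).
3. **LAI retrieval** — NDVI, EVI, NDGI and kNDVI = tanh(NDVI²) from band
   reflectances; stage-wise linear VI→LAI models fitted on a seeded 70/30
   split, selected by validation R², and applied per pixel
   (`compute_vi()`, `fit_lai_model()`, `estimate_lai_map()`).
4. **Sensitivity screening** — Sobol variance decomposition (Saltelli
   radial design, Jansen estimators) of LAIMAX and TWSO, screening at
   S > 0.05 (`sobol_analyze()`, `sobol_crop()`, `screen_sensitive()`).
5. **Calibration** — random-walk Metropolis MCMC with truncated-normal
   priors (±30 % hard bounds) and a Gaussian LAI likelihood
   (`mcmc_calibrate()`, posterior p(θ|y) ∝ f(y|θ) g(θ)).
6. **Assimilation** — perturbed-observation EnKF,
   `A^a = A^f + P Hᵀ (H P Hᵀ + R)⁻¹ (D − H A^f)`, applied sequentially at
   the jointing, tasseling and milky stages, in a calibrated
   *parameter-set* mode and a GWF-augmented *single-parameter* mode;
   pixel-wise yield maps and plot-level validation
   (`assimilate_point()`, `assimilate_region()`, `validate_yield()`).
7. **Synthetic scenes** — seeded generators for weather, truth parameter
   fields, LAI/VI grids and measured plot yields, so the whole pipeline is
   testable end to end in twin experiments (`generate_weather()`,
   `generate_scene()`).

See the methods vignette (`vignettes/maizecast-methods.Rmd`) for the model
equations, parameter tables, the assimilation design and known limits.

## Worked example

```r
library(maizecast)

## a temperate-continental season at 38.9 N and the calibrated inbred set
w <- generate_weather(38.9, as.Date("2021-04-20"), 170, seed = 1)
inbred <- crop_parameters(inbred_optimized())
simulate_crop(inbred, w, "2021-04-25")
#> Reduced-order maize simulation
#>   LAIMAX        4.20 m2/m2
#>   TWSO maturity 5983 kg/ha
#>   yield         6957 kg/ha
#>   anthesis      2021-07-14
#>   maturity      2021-10-02

## a synthetic 20x20 study area: truth fields, noisy stage LAI, plots
scene <- generate_scene(20, 20, seed = 1)

## sequential EnKF assimilation of the three stage LAI maps, then
## plot-level validation against the measured plot yields
cfg <- ensemble_config(n_members = 50, mode = "parameter_set", seed = 1)
ymap <- assimilate_region(scene$lai_obs, scene$weather, inbred, cfg,
                          scene$sowing_date, scene$stage_dates)
v <- validate_yield(ymap$yield, scene$plots$yield_measured,
                    plot_id = scene$plot_id)
sprintf("plot-level R2 = %.3f, RMSE = %.0f kg/ha", v$r_squared, v$rmse)
#> [1] "plot-level R2 = 0.095, RMSE = 686 kg/ha"
```

The simulated inbred peaks at LAI ≈ 4.2 and ≈ 7.0 t ha⁻¹ — clearly below
the hybrid defaults (LAIMAX ≈ 7.1, ≈ 7.6 t ha⁻¹) — and the assimilated
map recovers plot yields to within ≈ 690 kg ha⁻¹ on this scene, roughly a
tenth of the mean yield. A pipeline-level entry point with YAML
configuration is available as `run_stage()` (stages `synth`, `simulate`,
`sobol`, `calibrate`, `assimilate-point`, `map-yield`, `validate`), with a
shell wrapper in `inst/scripts/maizecast-pipeline.R`.

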