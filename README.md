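# zmetals

Bayesian analysis of trace-metal dynamics during eelgrass leaf
decomposition.

## The problem

Seagrass beds can act as biogeochemical sinks for trace metals. When
eelgrass (*Zostera marina*) leaves are shed and decompose, the copper,
zinc, cadmium and lead they carry can either concentrate in the decaying
tissue (and end up in the surface sediment) or leach back into the water.
zmetals implements the statistical chain needed to quantify this from
mesocosm measurements, for ecologists and biogeochemists working with
leaf-litter decomposition and sediment contamination data:

1. **Epiphyte weight ratio (`fit_wre`)** — leaf material is a composite of
   leaf tissue and attached epiphytes. The epiphyte mass fraction `r` is
   estimated from elemental tracers (C, δ¹³C, optionally N, δ¹⁵N) with a
   two-source Bayesian mixing model: tracer `t` is normal with mean
   `(1−r)·μ_eel,t + r·μ_epi,t` and variance
   `(1−r)²·σ²_eel,t + r²·σ²_epi,t`, under a uniform(0,1) prior, sampled by
   reflective random-walk MCMC (200,000 sweeps, 50,000 burn-in, thin 15 →
   10,000 draws).
2. **Decomposition model (`fit_decomposition`)** — per metal and
   experiment, `log_e y_j = β₁ + β₂·C_j + ε_j`, `ε_j ~ N(0, σ²)`, where
   `y_j` is concentration (µg/g dry) and `C_j` leaf carbon content
   (% dry weight). Gibbs sampling under a conjugate normal–inverse-gamma
   prior; 3 chains × 50,000 post-burn-in sweeps, thinned to 10,000 pooled
   draws, with split-chain R̂ diagnostics. Below-detection-limit values
   enter by detection-limit substitution.
3. **Predictive integration (`predict_concentration`, `fold_change`)** —
   posterior-predictive concentration at the initial-leaf carbon content
   `C(0) = (1−r)·C_eelgrass + r·C_epiphytes` (integrating over the `r`
   posterior and source variability) and at the lowest observed carbon
   content, and the fold change between them.
4. **Sediment statistics (`steel_dwass_mc`, `kruskal_wallis`,
   `d13c_trend`, `annual_summary`)** — geometric-mean summaries,
   Kruskal-Wallis tests, Monte-Carlo Dwass-Steel-Critchlow-Fligner
   all-pairs comparisons with familywise max-statistic permutation
   control, and log-linear element-vs-δ¹³C trend fits per pool.
5. **Synthetic data (`simulation_config`, `simulate_*`)** — generators
   with known ground truth for every input above, so the whole chain can
   be validated in parameter-recovery mode; `run_pipeline()` orchestrates
   an end-to-end run with one master seed and a reproducibility manifest.

## Worked example

Simulate initial leaves at a known epiphyte fraction (`r_true = 0.192`),
recover it, fit the lead decomposition model, and compute the predicted
fold change from the initial-leaf state to the most decomposed state:

```r
library(zmetals)

cfg <- simulation_config(seed = 42)
il  <- simulate_initial_leaves(cfg)
wre <- fit_wre(il, cfg$source_params, mcmc = wre_mcmc_config(seed = 43))
wre
#> Epiphyte weight ratio posterior (10000 draws, tracers: c_content, d13c)
#>   0.220 +/- 0.035, 95% CI [0.149, 0.287]
#>   acceptance rate 0.36

dec <- simulate_decomposition(simulation_config(seed = 42, n_obs = 100))
fit <- fit_decomposition(dec, "pb", "EX2", mcmc = decomp_mcmc_config(seed = 44))
fit
#> Log-linear decomposition fit: PB EX2 (n = 100, 10000 draws)
#>   parameter    mean      sd   lower  upper  rhat
#> 1 beta1      5.58   0.111    5.36    5.80  1.000
#> 2 beta2     -0.273  0.00478 -0.283  -0.264 1.000
#> 3 sigma2     0.0886 0.0127   0.0671  0.117 1.00

c0     <- draw_initial_carbon(wre, c_eel = c(35, 1.5), c_epi = c(20, 1.5), seed = 45)
p_init <- predict_concentration(fit, c0, seed = 46)
p_low  <- predict_concentration(fit, min(dec$c_content[dec$experiment == "EX2"]), seed = 47)
fold_change(p_low, p_init)
#>   metal experiment fold_change direction ratio_mean ratio_lower ratio_upper
#> 1 pb    EX2               264. increase        331.        94.3        853.
```

Reading the output: the mixing posterior puts the epiphyte mass fraction
at 0.220 ± 0.035 with the generating value 0.192 inside the 95% interval.
The lead fit recovers the generating slope (β₂ = −0.277) as −0.273 with a
credible interval excluding zero — lead concentrates as carbon is lost.
Because the simulated series runs down to ~11% carbon from an
initial-leaf content around 32%, the predicted concentration increase
across that span is large (fold change of the predictive means ≈ 264);
over a narrower, more typical decomposition span the same slope gives
roughly 10-fold accumulation. The draw-wise ratio interval is much wider,
as expected for a ratio of lognormals.

A full run of every stage (simulate → mixing fit → decomposition fits →
predictions → sediment statistics), with per-stage seeds and a YAML
manifest:

```r
report <- run_pipeline(pipeline_config(out_dir = "run1", seed = 99))
```

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "zmetals", load_package = "installed")'
```

The suite checks every sampler against an independent oracle (grid
quadrature for the mixing model, the closed-form normal–inverse-gamma
posterior for the Gibbs sampler, exhaustive permutation enumeration for
the DSCF test) and runs parameter-recovery, coverage and familywise
error-calibration studies on synthetic data.

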