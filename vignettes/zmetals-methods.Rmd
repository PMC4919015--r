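---
title: "Models and methods behind zmetals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind zmetals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

zmetals implements the statistical chain used to study how copper, zinc,
cadmium and lead behave while shed eelgrass (*Zostera marina*) leaves
decompose, and how that behaviour shows up in the surface sediment of a
vegetated pool compared with an unvegetated reference pool. This vignette
describes each model, the assumptions behind it, the tunable parameters and
their defaults, and what the synthetic-data generator does and does not
emulate.

## The epiphyte weight ratio (isotope mixing)

Leaf material entering a decomposition experiment is a composite of eelgrass
leaf tissue and the epiphytes (mainly crustose coralline algae) attached to
it. The mass fraction of epiphytes, `r`, cannot be measured directly on the
experimental material, so it is inferred from elemental tracers: carbon
content, delta-13C, and optionally nitrogen content and delta-15N. Isotope
ratios use the usual per-mil delta notation relative to Pee Dee Belemnite
(carbon) and atmospheric N2 (nitrogen); `delta_from_ratio()` implements the
conversion.

For a candidate fraction `r`, every tracer `t` of an initial-leaf replicate
is modelled as normal with

- mean `m_t = (1 - r) mu_eelgrass,t + r mu_epiphyte,t`, and
- variance `v_t = (1 - r)^2 sd_eelgrass,t^2 + r^2 sd_epiphyte,t^2`.

Mixing is linear in mass fraction for every tracer, with no
concentration-weighting: the same mass-balance identity that defines the
initial-leaf carbon content, `C(0) = (1 - r) C_eelgrass + r C_epiphytes`, is
applied to all tracers, and the source variability propagates with squared
mass-fraction weights (the standard source-variability mixing model).
Replicates are treated as independent and identically distributed given
`r`. The source summaries enter as plug-in constants (means and SDs of the
monthly eelgrass and annually pooled epiphyte samples), not as hierarchical
priors — the source data behind the fit are summaries, not raw replicates.

The prior on `r` is uniform(0, 1). `fit_wre()` samples the posterior with a
single-chain Gaussian random walk, reflecting proposals at the boundaries
(reflection keeps the kernel symmetric, so no Jacobian correction is
needed). The schedule is 200,000 sweeps with 50,000 burn-in, thinned every
15 sweeps, retaining exactly 10,000 draws. The proposal scale starts at
0.05 and is rescaled every 100 burn-in sweeps towards a 35 % acceptance
rate — comfortably inside the 20-50 % band that is efficient for a
one-dimensional random walk — and is frozen when burn-in ends, so the
post-burn-in kernel is a fixed, valid Metropolis kernel. If the two sources
are indistinguishable in every requested tracer, the fit completes and is
flagged non-identifiable; the posterior then reproduces the uniform prior,
which is visible in its near-(0.025, 0.975) credible interval.

## The decomposition model

Within one experiment, the concentration `y_j` (microgram per gram dry
weight) of one metal in decomposing leaf material is related to the leaf
carbon content `C_j` (% dry weight) by

```
log_e y_j = beta1 + beta2 * C_j + eps_j,   eps_j ~ N(0, sigma2) i.i.d.
```

Carbon content is the natural covariate for decomposition stage: it falls
monotonically as the leaf is consumed, so a negative `beta2` means the
metal concentrates as the leaf decomposes and a positive one means it
leaches. The log link keeps predictions positive and makes multiplicative
("fold-change") statements natural. Assays below the detection limit enter
as the substituted limit (`substitute_detection_limits()`), the stated
analysis convention; a censored likelihood is deliberately out of scope.

`fit_decomposition()` samples the posterior by Gibbs under the conjugate
normal-inverse-gamma prior

```
beta | sigma2 ~ N(0, sigma2 * 1e6 * I),   sigma2 ~ IG(1e-3, 1e-3).
```

We chose the fully conjugate form (prior scale of `beta` proportional to
`sigma2`) rather than an independent normal prior because it admits an
exact closed-form posterior — a scaled multivariate t for `beta` and an
inverse gamma for `sigma2` — which the test suite uses as an analytic
oracle for the sampler. With `sigma2` of order 0.01-0.4 on these data the
effective prior variance on `beta` is at least about 1e4, so the posterior
is data-dominated for any sample of twenty or more observations and the
choice is immaterial to the reported quantities.

The schedule is 3 chains of 55,000 sweeps each (burn-in 5,000). Thinning
every 15th sweep of the pooled 150,000 post-burn-in sweeps (chain-major)
retains exactly 10,000 draws with per-chain counts balanced to within one;
thinning within chains instead would retain 9,999 or 10,002, which is why
the pooled convention was adopted. Convergence is monitored with a
split-chain potential-scale-reduction diagnostic per parameter; values
above 1.1 warn and never abort, since a warning plus the draws is more
useful than a refusal.

## Predictive integration and fold changes

The quantity of applied interest is how much a metal's concentration
changes between the start of decomposition and its most decomposed observed
state. `predict_concentration()` integrates the model over everything
uncertain: each Monte-Carlo iteration resamples one *joint* posterior draw
`(beta1, beta2, sigma2)` — joint resampling preserves the strong negative
intercept-slope correlation, which matters for extrapolation — one carbon
content from the target distribution `p(C)`, and then one predictive
`log_e y' ~ N(beta1 + beta2 C, sigma2)`. The default is 100,000 iterations.

Two targets are standard. The initial-leaf target takes `p(C)` from
`draw_initial_carbon()`, which resamples `r` from the weight-ratio
posterior and draws the two source carbon contents from normals, applying
the mass-balance identity above. The lowest-carbon target is a point mass
at the minimum carbon content observed in the experiment, the most
decomposed material actually seen — predictions there interpolate rather
than extrapolate. `fold_change()` reports the ratio of linear-scale
predictive means as the headline number; because the draw-wise ratio of
two heavy-tailed lognormals has a much wider (and differently centred)
distribution, the draw-wise ratio summary is reported alongside rather
than instead.

## Sediment statistics

Annual element summaries are computed on log_e values and back-transformed
(geometric mean with multiplicative spread), appropriate for positive,
right-skewed concentration data. Group comparisons are rank-based and
therefore indifferent to the log transform (a directly tested invariance):

- `kruskal_wallis()` wraps the tie-corrected Kruskal-Wallis test across
  the three sediment groups (surface in each pool, bottom in the eelgrass
  pool as the representative unaffected layer).
- `steel_dwass_mc()` performs all-pairs Dwass-Steel-Critchlow-Fligner
  comparisons. Each pair is summarized by the standardized two-sample
  rank-sum statistic with mid-rank ties and the DSCF tie-corrected
  variance. Familywise control comes from a Monte-Carlo max-statistic
  permutation null: the pooled observations are permuted (10,000 times by
  default), the maximum absolute pairwise statistic is recorded each time,
  and every pairwise p-value is the add-one-corrected exceedance
  proportion of that maximum. This single-step max-T construction is exact
  up to Monte-Carlo error and makes no normality assumption; the reference
  DSCF implementation's null construction is not documented publicly, so
  the max-statistic convention was adopted and is stated here. Fewer than
  100 permutations are refused as numerically unstable.

Trends of log_e element concentration against delta-13C in surface
sediment — delta-13C indexes how much of the sediment derives from marine
organic production — are ordinary least-squares fits with normal-theory
slope p-values (`d13c_trend()`), fitted separately per pool. A companion
fit on the untransformed response is always produced so the effect of the
log transform on the conclusion is visible. Stars follow the conventional
thresholds (0.05, 0.01, 0.001). The perfectly noiseless degenerate case is
defined explicitly: zero residual dispersion with a (near-)zero slope
yields p = 1, with a non-zero slope p = 0.

`experienced_temperature_days()` encodes the leaf-age bookkeeping rule:
thermal history in days is the plastochrone interval times the leaf-rank
factor (2.5 for the third-youngest leaf), rounded to the nearest day —
with the mesocosm plastochrone interval of 14.9 days this gives 37.

## The synthetic-data generator

Every input the pipeline consumes can be generated with known ground truth
by `simulate_sources()`, `simulate_initial_leaves()`,
`simulate_decomposition()` and `simulate_sediment_cores()`, configured
through `simulation_config()`. The generator emulates exactly the
structure the analysis assumes: normal per-tracer source variability,
convex-combination initial leaves at a known `r_true`, log-linear
decomposition series with lognormal noise and substitution censoring, and
sediment pools whose log concentrations trend linearly with delta-13C in
the vegetated pool and stay flat in the reference pool.

Default conditions and their reasoning:

- Source tracers: eelgrass carbon 35 ± 1.5 % (n = 5 monthly replicates),
  epiphytes 20 ± 1.5 % (n = 10 annual pools) — an approximately 15-point
  carbonate-dilution gap; delta-13C of −13.4 ± 2.1 vs −9.7 ± 0.5 per mil.
  Nitrogen and delta-15N defaults (2.0 ± 0.3 vs 0.5 ± 0.1 %, 8.0 ± 0.5 vs
  7.0 ± 0.5 per mil) are plausible temperate-coastal values and carry
  little identifying information, consistent with their observed
  ineffectiveness in the weight-ratio estimate.
- `r_true` defaults to 0.192, a well-constrained late-experiment epiphyte
  load; recovery tests also run at 0.2 / 0.5 / 0.8.
- Decomposition truth: the 12 metal-by-experiment parameter triples of
  `default_decomp_truth()`, spanning slopes from −0.277 to +0.276 per % C
  and log-scale variances from 0.01 to 0.38.
- Carbon contents are drawn uniformly on [11, 35] % — the decomposition
  trajectory of C is not modelled mechanistically, and the uniform draw
  covers the observed initial-to-most-decomposed span; an optional
  exponential day-to-carbon decay curve is available for more realistic
  day structure. 25 observations per experiment (five replicate bags over
  five sampling days) is the default design.
- Detection limits (Cu 0.01, Zn 0.05, Cd 0.001, Pb 0.005 microgram/g) are
  typical ICP-MS procedure limits; under the default truth censoring is
  rare, as in the data the analysis was designed for. Censoring is applied
  by substitution after generation — matching the analysis convention —
  not by truncating the generative distribution.
- Sediment: 3 replicate cores in each of 4 months per pool (12 surface
  samples per pool); metal slopes on delta-13C of 0.15 per per-mil with
  residual SD 0.3 in the eelgrass pool and 0 in the reference pool; carbon
  and nitrogen rise in both pools, more steeply in the vegetated one.
  Surface delta-13C spans −20 to −10 per mil (eelgrass pool) and −22 to
  −17 (reference); bottom sediment sits at −22.2 ± 0.6 around fixed
  baselines.
- Normal draws of elemental contents are clipped to the physical 0-100 %
  range, and clipping is reported via a message and an attribute — never
  silently.

What the generator does *not* emulate: seasonal shoot dynamics, water
temperature, epiphyte growth biology, within-month correlation of cores,
day-level autocorrelation in the mesh-bag series, and any misspecification
of the fitted models themselves. Passing recovery tests therefore
demonstrates that the inference machinery is correct under its own
assumptions, not that those assumptions hold for any particular field
dataset.

## Reproducibility and numerical choices

All randomness flows from explicit integer seeds. The pipeline
(`run_pipeline()`) takes one master seed and derives per-stage seeds
deterministically from the stage name (`stage_seed()`), so each stage is
independently reproducible; the YAML manifest records the master seed,
stage seeds, every ground-truth and schedule parameter, and the analysis
defaults actually used, and rerunning from the same configuration is
bit-identical. The DSCF permutation kernel draws from R's own RNG stream,
so `set.seed()` governs it too.

Posterior summaries are means, SDs, and equal-tailed 95 % intervals from
the 2.5 % and 97.5 % empirical quantiles (default quantile type). Credible
intervals of Monte-Carlo p-values use the add-one correction
`(1 + count) / (n_iter + 1)`, so a zero count reports a resolvable minimum
rather than zero.

Problem sizes used by the test suite were chosen to keep each check
statistically decisive at three Monte-Carlo standard errors: recovery fits
use 100 observations; sampler-versus-oracle comparisons use the full
10,000-draw schedules; repetition-heavy calibration checks (interval
coverage, familywise error, trend power) use 20-1,000 repetitions with
reduced but adequate MCMC schedules, since those checks exercise the
method, not the schedule.

## Known limitations

- The weight-ratio likelihood treats source summaries as known constants;
  uncertainty in the source means beyond the recorded SDs is not
  propagated.
- Censoring by substitution biases low-concentration fits when censoring
  is heavy; the package refuses only the all-censored case.
- The decomposition model conditions on carbon content; day, temperature
  and experiment-level covariates are intentionally outside the model.
- Monthly structure in sediment cores is simulated and analysed as
  independent; no mixed-effects or time-series structure is fitted.
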