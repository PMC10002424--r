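# soilcalib

Kalman-formula-based parameter estimation for soil–crop system models.

Process-based soil–crop simulators can only predict soil water and nitrogen
dynamics usefully after their parameters have been calibrated against field
observations — and a realistic configuration quickly accumulates dozens of
uncertain parameters. `soilcalib` implements, and tests end-to-end, the two
families of Bayesian calibration machinery built on the Kalman update
formula:

* **ensemble smoothers** — the ensemble smoother with multiple data
  assimilation (**ES-MDA**) and the iterative local updating ensemble
  smoother (**ILUES**), which updates each member through a local ensemble
  so that multimodal posteriors survive;
* **adaptive multi-chain MCMC** — **DREAM(ZS)** (parallel-direction and
  snooker moves proposed from an archive of past states) and **DREAMkzs**,
  which adds a Kalman-inspired proposal during burn-in to accelerate
  convergence.

They are exercised on a built-in 45-parameter calibration problem: a fast
daily tipping-bucket soil water balance over an 8-layer, 180 cm profile
with FAO-56-style crop evapotranspiration, standing in for a full soil–crop
simulator. The parameter space covers 32 soil hydraulic parameters
(`Ks`, `SAT`, `FC`, `PWP` for 8 layers), 5 nitrogen transformation
parameters and 8 crop parameters, each with a published uniform prior
interval. Everything — arid-site weather, management schedules, reference
truth, noisy observations — is generated by seeded code; no external data
are needed.

## The update formulas

All four samplers revolve around the Kalman gain

```
K = C_MD (C_DD + C_D)^-1
```

with `C_MD` the parameter–prediction cross-covariance, `C_DD` the
prediction covariance (both estimated from an ensemble or archive) and
`C_D` the measurement-error covariance.

* **ES / ES-MDA** update every member `m_a = m_f + K (d_j - f(m_f))`
  against its own perturbed observation copy `d_j`; ES-MDA repeats the
  assimilation `N` times with the error covariance inflated by factors
  `alpha_i` satisfying `sum(1/alpha_i) = 1`.
* **ILUES** ranks candidates for each member `j` by the combined objective
  `J(m) = a J1(m)/J1max + b J2(m)/J2max` (data misfit plus Mahalanobis
  distance to member `j`), applies the Kalman update within the `NL`
  best-ranked members only, and resamples member `j` from that updated
  local set.
* **DREAMkzs** proposes `theta_p = theta + K r + K eps` during burn-in,
  with `r = d - f(theta)` the current residual and `eps ~ N(0, R)`; the
  gain is estimated from the sampler's archive.

Model fit is scored by mean bias error (ME), RMSE and Willmott's index of
agreement (IA), and calibration quality by `RMSE_MAP`, the RMSE of the
maximum a posteriori member.

## Worked example

Calibrate the synthetic case (reference truth drawn from the prior,
16 depths x 17 days of soil water content, measurement noise
sd 0.005 cm3/cm3) with both ensemble methods at ensemble size 500 and
3 iterations:

```r
library(soilcalib)
res <- run_synthetic_case(seed = 42, ne = 500)
res$comparison
#> # A tibble: 2 x 7
#>   method n_samples n_obs        me    rmse    ia rmse_map
#>   <chr>      <int> <int>     <dbl>   <dbl> <dbl>    <dbl>
#> 1 ILUES        500   272 0.0000559 0.00496 0.998  0.00496
#> 2 ESMDA        500   272 0.0000275 0.00504 0.998  0.00504
```

Both methods drive the MAP member's misfit down to the 0.005 noise floor
(IA near 1, negligible bias). `tidy()` shows the posterior marginals next
to the hidden truth — the storage parameters are recovered tightly:

```r
td <- tidy(res$ilues)
head(dplyr::mutate(td, truth = res$reference[td$parameter]), 4)
#> # A tibble: 4 x 7
#>   parameter   mean      sd  lower  upper    map  truth
#> 1 Ks_1      64.8   1.84    61.4   68.5   66.8   62.7
#> 2 SAT_1      0.351 0.00116  0.348  0.353  0.352  0.355
#> 3 FC_1       0.203 0.00157  0.200  0.206  0.202  0.203
#> 4 PWP_1      0.123 0.00211  0.119  0.127  0.122  0.124
```

Compare the MCMC variants (3 chains, proposal mixture 0.7/0.1/0.2, Kalman
cutoff at 20% of the run):

```r
cmp <- run_mcmc_comparison(seed = 42, n_gen = 500)
dplyr::summarise(dplyr::group_by(cmp$first_passage, variant),
                 median_fp = median(first_passage))
#> # A tibble: 2 x 2
#>   variant median_fp
#> 1 kzs             9
#> 2 zs            384
```

The Kalman-inspired proposal drops chain RMSE below the
`sqrt(2) * noise_sd` threshold within ~10 generations, where the plain
variant needs hundreds — the burn-in acceleration the kzs variant exists
for. `autoplot()` on any result draws the MAP fit with 95% parameter- and
total-uncertainty bands; `plot_rmse_evolution(kzs = cmp$kzs, zs = cmp$zs)`
draws the per-chain RMSE traces.

## Package tour

| area | functions |
|---|---|
| parameter space & design | `param_space()`, `sample_prior()`, `treatment_schedule()`, `observation_layout()` |
| forward model | `simulate_swc()`, `make_forward()`, `water_balance()`, `crop_coefficient()`, `nitrogen_step()` |
| synthetic data | `generate_weather()`, `generate_reference_truth()`, `perturb_observations()`, `make_synthetic_case()` |
| ensemble smoothers | `kalman_gain()`, `es_update()`, `esmda()`, `ilues()`, `ilues_objective()` |
| MCMC | `dream()`, `parallel_direction_proposal()`, `snooker_proposal()`, `kalman_proposal()`, `log_likelihood()`, `gelman_rubin()` |
| evaluation | `fit_stats()`, `rmse_map()`, `uncertainty_bands()`, `summarize_marginals()`, `rmse_evolution()`, `first_passage()` |
| experiments | `run_synthetic_case()`, `run_practical_case()`, `run_mcmc_comparison()` |
| tidy methods | `tidy()`, `glance()`, `autoplot()`, `plot_rmse_evolution()`, `plot_marginals()` |

The methods vignette (`vignettes/calibration-methods.Rmd`) documents the
model assumptions, every tunable default and the numerical choices.
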