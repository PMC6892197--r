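# sacekit

Estimation of the survivor average causal effect (SACE) of a binary
exposure on a binary outcome when outcome data are truncated by death and
further missing because surviving participants do not attend follow-up —
the situation of essentially every cohort study of ageing-related disease.

Restricting an analysis to surviving attenders conditions on survival, a
collider between the exposure and any unmeasured predictor of both survival
and the outcome; the exposure groups then stop being exchangeable no matter
how many measured confounders are adjusted for. The estimand that remains
well defined is the SACE: the exposure effect among *always-survivors*, the
principal stratum of participants who would survive under either exposure
level,

```
SACE_OR = odds[Y(1) = 1 | AS] / odds[Y(0) = 1 | AS].
```

The package provides, for analysts and simulation methodologists:

* **`estimate_msm()`** — a marginal structural model: weighted logistic
  regression with stabilized inverse-probability weights for the observed
  exposure, survival, and attendance among survivors
  (`W_i = SF_A / [(A p + (1-A)(1-p)) q m]`), with covariate-balance
  diagnostics (`standardized_difference()`) and bias-corrected bootstrap
  confidence intervals (`bc_bootstrap_ci()`).
* **`estimate_sensitivity()`** — the closed-form principal-stratification
  sensitivity analysis: arm-specific outcome models and a survival model
  yield the marginal probabilities of surviving (`nu_a`) and of surviving
  with the outcome (`xi_a`); the SACE odds ratio follows in closed form for
  any value of the sensitivity parameter `tau`, the outcome-odds ratio
  between compliant-survivors and always-survivors (`tau = 1` encodes "no
  survival bias").
* **`simulate_cohort()` / `scenario_config()` / `scenario_grid()`** — a
  principal-strata cohort generator with an unmeasured survival–outcome
  confounder `U` and attendance-driven missingness, calibrated per scenario
  (`calibrate_exposure_coefficient()`) so the true SACE odds ratio equals a
  target (0.6 by default).
* **`run_scenario()` / `run_study()`** — a Monte-Carlo harness computing
  bias, empirical SE, MSE, standardized bias and bootstrap coverage over
  the canonical 12-scenario grid
  (`alpha_UZ ∈ {ln 0.5, ln 2}` × `beta_UY ∈ {ln 0.5, 0, ln 2}` ×
  monotonicity valid/violated).

A thin command-line front end ships in `inst/scripts/sacekit`
(`simulate`, `calibrate`, `estimate-msm`, `estimate-sensitivity`,
`run-study`).

## Worked example

Simulate one scenario in which the unmeasured confounder doubles the odds
of survival and halves the odds of the outcome (opposite directions — the
configuration that attenuates naive estimates), calibrate the generator to
a true SACE odds ratio of 0.6, and estimate it both ways:

```r
library(sacekit)

cfg <- scenario_config(alpha_UZ = log(2), beta_UY = log(0.5),
                       monotonicity = "valid")
beta_A <- calibrate_exposure_coefficient(cfg)
#> -0.5151814

truth <- simulate_cohort(cfg, beta_A, seed = 2026)
truth
#> Simulated cohort (truth view): 10000 participants, 8751 survivors
#> stratum
#>   AS   CS   DS   NS
#> 8152 1217    0  631
#>   exposed: 4900; missing outcomes among survivors: 2912

empirical_sace(truth)   # truth-side SACE of this replicate (log OR)
#> -0.5720099
empirical_tau(truth)    # CS/AS outcome-odds ratio; > 1 here, as designed
#> 1.230794

obs <- assemble_observed(truth)     # analyst view: U, strata, potentials hidden
est <- estimate_msm(obs, boot = 1000, seed = 7)
est
#> SACE estimate [msm]: log OR = -0.7265 (OR = 0.4836)
#>   95% BC bootstrap CI (log OR): [-0.9565, -0.5082]
#>   robust SE (diagnostic): 0.1125
#>   converged: TRUE; n used: 5839
est$balance
#>   covariate unweighted     weighted
#> 1        V1 -0.1749195  0.015544666
#> 2        V2 -0.2474437 -0.002888564

sens <- estimate_sensitivity(obs)   # tau grid 0.5, 1, 2
sapply(sens, function(e) e$or)
#> sens@0.5   sens@1   sens@2
#> 0.5198758 0.4845749 0.4292687
```

Reading the output: weighting restores covariate balance (standardized
differences drop from ~0.2 to ~0.01), and on this single replicate both the
MSM (OR 0.48) and the `tau = 1` sensitivity estimate (OR 0.48) land on the
same side of the true 0.6 — with `alpha_UZ` and `beta_UY` of opposite sign
the replicate-level truth happens to sit below its expectation too
(empirical SACE −0.57). Averaged over 300+ replicates the two methods'
systematic biases emerge: estimates at `tau = 0.5 / 1 / 2` are ordered
decreasingly in `tau`, and the MSM tracks the `tau = 1` estimate within
0.03 on the log-OR scale (see the methods vignette,
`vignettes/sace-methods.Rmd`).

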