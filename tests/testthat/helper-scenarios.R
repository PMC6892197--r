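# Shared scenario lists and a calibration cache so that the exposure
# coefficient of each scenario is calibrated at most once per test run.

null_scenarios <- function(...) {
  out <- list()
  for (a in c(log(0.5), log(2)))
    for (m in c("valid", "violated"))
      out[[length(out) + 1L]] <- scenario_config(alpha_UZ = a, beta_UY = 0,
                                                 monotonicity = m, ...)
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

# the four scenarios with a non-null unmeasured outcome effect, valid
# monotonicity only (add_violated = TRUE appends their violated twins)
biased_scenarios <- function(add_violated = FALSE, ...) {
  out <- list()
  monos <- if (add_violated) c("valid", "violated") else "valid"
  for (a in c(log(0.5), log(2)))
    for (b in c(log(0.5), log(2)))
      for (m in monos)
        out[[length(out) + 1L]] <- scenario_config(alpha_UZ = a, beta_UY = b,
                                                   monotonicity = m, ...)
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

.calib_cache <- new.env(parent = emptyenv())

cached_beta_A <- function(config) {
  key <- config$id
  if (is.null(.calib_cache[[key]]))
    .calib_cache[[key]] <- calibrate_exposure_coefficient(config)
  .calib_cache[[key]]
}

# small observed cohort for estimator plumbing tests
quick_cohort <- function(config = scenario_config(), n = 4000, seed = 1,
                         observed = TRUE) {
  truth <- simulate_cohort(config, cached_beta_A(config), seed = seed, n = n)
  if (observed) assemble_observed(truth) else truth
}
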