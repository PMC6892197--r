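#' Scenario configuration for the principal-strata cohort simulator
#'
#' A scenario fixes the data-generating mechanism of a simulated cohort:
#' covariate distributions, the logistic models for exposure, potential
#' survival, potential outcome and attendance, the strength and direction of
#' the unmeasured survival--outcome confounder `U`, whether the monotonicity
#' assumption (exposure never harms survival) holds, and the target marginal
#' SACE odds ratio used to calibrate the conditional exposure effect on the
#' outcome.
#'
#' The default coefficients describe a large ageing cohort: roughly half the
#' participants exposed (exposure depending on sex and mean-centred age),
#' survival to follow-up between about 70% and 95% depending on arm and on
#' `U`, attendance around 70% among survivors, and an outcome prevalence
#' around 10% among unexposed survivors. `U` (e.g. a genotype) affects
#' survival with log odds ratio `alpha_UZ` and the outcome with log odds
#' ratio `beta_UY`; neither is available to the analyst. `D` (e.g. area of
#' residence) affects attendance only and is likewise unmeasured.
#'
#' @param alpha_UZ Log odds ratio of `U` on survival. The canonical
#'   evaluation grid uses `log(0.5)` and `log(2)`.
#' @param beta_UY Log odds ratio of `U` on the outcome. Grid values
#'   `log(0.5)`, `0`, `log(2)`. `beta_UY = 0` means no survival bias.
#' @param monotonicity Either `"valid"` (no defiant-survivors: survival under
#'   low exposure implies survival under high exposure) or `"violated"`
#'   (potential survival statuses drawn independently).
#' @param n_participants Cohort size per simulated dataset.
#' @param n_reps Number of Monte-Carlo replicates for study runs.
#' @param target_sace_or Target marginal SACE odds ratio among
#'   always-survivors; the conditional exposure coefficient of the outcome
#'   model is calibrated per scenario so the simulated cohorts attain it.
#' @param base_seed Base seed from which per-replicate seeds are derived.
#' @param covariates List with elements `p_sex`, `p_genotype`, `p_residence`
#'   (Bernoulli probabilities) and `age_range` (`V2 ~ Uniform(-r, r)` years).
#' @param exposure_coefs Named vector `intercept`, `sex`, `age`. The exposure
#'   model never involves `U` or `D`.
#' @param survival_coefs Named vector `intercept`, `exposure`, `sex`, `age`.
#'   `alpha_UZ` supplies the `U` term. Under `monotonicity = "valid"` the
#'   `exposure` coefficient must be non-negative.
#' @param outcome_coefs Named vector `intercept`, `sex`, `age`. `beta_UY`
#'   supplies the `U` term and the calibrated `beta_A` the exposure term.
#' @param attendance_coefs Named vector `intercept`, `exposure`, `sex`,
#'   `age`, `residence`.
#' @param survival_coupling How `Z(0)` is drawn given `Z(1)` when
#'   monotonicity is valid: `"conditional"` (default) draws `Z(0)` among
#'   survivors under exposure with probability `p0/p1`, which preserves the
#'   marginal law of `Z(0)` while guaranteeing `Z(0) <= Z(1)`;
#'   `"independent"` draws `Z(0) ~ Bernoulli(p0)` and then forces
#'   `Z(0) <= Z(1)`, which distorts the marginal and is provided only for
#'   comparison.
#'
#' @return An object of class `sace_scenario`: a validated list of the above
#'   components plus a human-readable `id`.
#' @seealso [scenario_grid()], [simulate_cohort()],
#'   [calibrate_exposure_coefficient()]
#' @examples
#' cfg <- scenario_config(alpha_UZ = log(2), beta_UY = 0, monotonicity = "valid")
#' cfg$id
#' @export
scenario_config <- function(alpha_UZ = log(2),
                            beta_UY = 0,
                            monotonicity = c("valid", "violated"),
                            n_participants = 10000,
                            n_reps = 1200,
                            target_sace_or = 0.6,
                            base_seed = 20191203,
                            covariates = list(p_sex = 0.5, p_genotype = 0.5,
                                              p_residence = 0.5, age_range = 10),
                            exposure_coefs = c(intercept = -0.23, sex = 0.45, age = 0.045),
                            survival_coefs = c(intercept = 1.1, exposure = 1.2,
                                               sex = 0.2, age = -0.02),
                            outcome_coefs = c(intercept = -2.3, sex = 0.25, age = 0.02),
                            attendance_coefs = c(intercept = 0.9, exposure = 0.2,
                                                 sex = 0.15, age = -0.02,
                                                 residence = log(0.5)),
                            survival_coupling = c("conditional", "independent")) {
  monotonicity <- match.arg(monotonicity)
  survival_coupling <- match.arg(survival_coupling)

  stopifnot(is.numeric(alpha_UZ), length(alpha_UZ) == 1L, is.finite(alpha_UZ),
            is.numeric(beta_UY), length(beta_UY) == 1L, is.finite(beta_UY))
  if (!is.numeric(n_participants) || n_participants < 1)
    stop("'n_participants' must be a positive integer", call. = FALSE)
  if (!is.numeric(n_reps) || n_reps < 1)
    stop("'n_reps' must be a positive integer", call. = FALSE)
  if (!is.numeric(target_sace_or) || target_sace_or <= 0 || !is.finite(target_sace_or))
    stop("'target_sace_or' must be a finite positive odds ratio", call. = FALSE)

  for (p in c("p_sex", "p_genotype", "p_residence")) {
    v <- covariates[[p]]
    if (is.null(v) || !is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("covariate probability '%s' must lie in [0, 1]", p), call. = FALSE)
  }
  if (is.null(covariates$age_range) || covariates$age_range <= 0)
    stop("covariate 'age_range' must be positive", call. = FALSE)

  need <- function(coefs, nms, what) {
    if (!all(nms %in% names(coefs)))
      stop(sprintf("%s coefficients must be named %s", what,
                   paste(nms, collapse = ", ")), call. = FALSE)
    coefs[nms]
  }
  exposure_coefs <- need(exposure_coefs, c("intercept", "sex", "age"), "exposure")
  survival_coefs <- need(survival_coefs, c("intercept", "exposure", "sex", "age"), "survival")
  outcome_coefs <- need(outcome_coefs, c("intercept", "sex", "age"), "outcome")
  attendance_coefs <- need(attendance_coefs,
                           c("intercept", "exposure", "sex", "age", "residence"),
                           "attendance")

  if (monotonicity == "valid" && survival_coefs[["exposure"]] < 0)
    stop("monotonicity = \"valid\" requires a non-negative exposure effect on survival",
         call. = FALSE)

  cfg <- list(
    alpha_UZ = alpha_UZ, beta_UY = beta_UY, monotonicity = monotonicity,
    n_participants = as.integer(n_participants), n_reps = as.integer(n_reps),
    target_sace_or = target_sace_or, base_seed = as.integer(base_seed),
    covariates = covariates, exposure_coefs = exposure_coefs,
    survival_coefs = survival_coefs, outcome_coefs = outcome_coefs,
    attendance_coefs = attendance_coefs, survival_coupling = survival_coupling
  )
  cfg$id <- sprintf("aUZ=%s_bUY=%s_%s", .fmt_lor(alpha_UZ), .fmt_lor(beta_UY),
                    monotonicity)
  class(cfg) <- "sace_scenario"
  cfg
}

.fmt_lor <- function(x) {
  if (abs(x) < 1e-12) return("1")
  or <- exp(x)
  if (abs(or - round(or, 2)) < 1e-9) format(round(or, 2)) else sprintf("%.3g", or)
}

#' @export
print.sace_scenario <- function(x, ...) {
  cat("Cohort simulation scenario:", x$id, "\n")
  cat(sprintf("  U -> survival log OR: % .4f   U -> outcome log OR: % .4f\n",
              x$alpha_UZ, x$beta_UY))
  cat(sprintf("  monotonicity: %s   target SACE OR: %g   N: %d   reps: %d\n",
              x$monotonicity, x$target_sace_or, x$n_participants, x$n_reps))
  invisible(x)
}

#' The canonical 12-scenario evaluation grid
#'
#' Cartesian product of the unmeasured confounder's effect on survival
#' (`alpha_UZ` in `log(0.5)`, `log(2)`), its effect on the outcome (`beta_UY`
#' in `log(0.5)`, `0`, `log(2)`) and the monotonicity setting (`valid`,
#' `violated`), in that nesting order.
#'
#' @param ... Further arguments passed to [scenario_config()] (e.g.
#'   `n_participants`, `base_seed`) applied to every scenario.
#' @return A list of 12 `sace_scenario` objects with deterministic ordering
#'   and unique `id`s.
#' @examples
#' length(scenario_grid())
#' @export
scenario_grid <- function(...) {
  out <- list()
  for (a in c(log(0.5), log(2)))
    for (b in c(log(0.5), 0, log(2)))
      for (m in c("valid", "violated"))
        out[[length(out) + 1L]] <- scenario_config(alpha_UZ = a, beta_UY = b,
                                                   monotonicity = m, ...)
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Derive a child seed from a base seed and integer keys
#'
#' Deterministic mixing of a base seed with stage keys (scenario index,
#' replicate number, ...) so that every stochastic stage of a study run is
#' reproducible and replicate streams are decoupled. The result always lies
#' in `[1, 2^31 - 2]`.
#'
#' @param base Base seed (integer).
#' @param ... Further non-negative integer keys.
#' @return A single integer seed.
#' @examples
#' derive_seed(7, 3, 12)
#' @export
derive_seed <- function(base, ...) {
  m <- 2147483647  # 2^31 - 1, prime; products below stay exact in doubles
  s <- as.numeric(base) %% m
  for (k in c(...)) {
    s <- (s * 69069 + as.numeric(k) + 1) %% m
    s <- (s * 48271) %% m
  }
  as.integer(s %% (m - 1) + 1)
}
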