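#' @keywords internal
expit <- stats::plogis

#' Generate baseline covariates
#'
#' Draws the baseline covariate block: sex `V1`, mean-centred age `V2`
#' (uniform on `(-r, r)` years), the unmeasured survival--outcome confounder
#' `U` (e.g. a genotype) and the unmeasured attendance predictor `D` (e.g.
#' area of residence). `V1`, `U` and `D` are independent Bernoulli draws.
#'
#' @param n Number of participants.
#' @param config A [scenario_config()] object (only its `covariates` block is
#'   used).
#' @return A data frame with columns `V1`, `V2`, `U`, `D`.
#' @export
generate_covariates <- function(n, config) {
  cv <- config$covariates
  data.frame(
    V1 = stats::rbinom(n, 1L, cv$p_sex),
    V2 = stats::runif(n, -cv$age_range, cv$age_range),
    U = stats::rbinom(n, 1L, cv$p_genotype),
    D = stats::rbinom(n, 1L, cv$p_residence)
  )
}

#' Generate the binary exposure
#'
#' Exposure depends on sex and age only (never on `U` or `D`):
#' `A ~ Bernoulli(expit(intercept + c_sex V1 + c_age V2))`.
#'
#' @param covariates Covariate block from [generate_covariates()].
#' @param coefs Named coefficients `intercept`, `sex`, `age`.
#' @return Integer 0/1 vector `A`.
#' @export
generate_exposure <- function(covariates, coefs) {
  lp <- coefs[["intercept"]] + coefs[["sex"]] * covariates$V1 +
    coefs[["age"]] * covariates$V2
  as.integer(stats::runif(nrow(covariates)) < expit(lp))
}

#' Generate potential survival under both exposure levels
#'
#' The survival linear predictor is
#' `s(a) = intercept + c_A a + c_sex V1 + c_age V2 + alpha_UZ U` with
#' `p_a = expit(s(a))`. `Z(1) ~ Bernoulli(p1)`. Under valid monotonicity,
#' `Z(0)` is drawn only among those with `Z(1) = 1`, with probability
#' `p0 / p1`; this is the unique coupling with `P(Z(0) <= Z(1)) = 1` that
#' preserves the marginal law `P(Z(0) = 1) = p0`. Under violated
#' monotonicity, `Z(0) ~ Bernoulli(p0)` independently of `Z(1)`, so
#' defiant-survivors (`Z(0) = 1, Z(1) = 0`) can occur.
#'
#' @param covariates Covariate block.
#' @param coefs Named survival coefficients `intercept`, `exposure`, `sex`,
#'   `age`.
#' @param alpha_UZ Log odds ratio of `U` on survival.
#' @param monotonicity `"valid"` or `"violated"`.
#' @param coupling Coupling used for `Z(0)` when monotonicity is valid; see
#'   [scenario_config()].
#' @return A list with integer vectors `Z0`, `Z1` and the per-participant
#'   probabilities `p0`, `p1`.
#' @export
generate_potential_survival <- function(covariates, coefs, alpha_UZ,
                                        monotonicity = c("valid", "violated"),
                                        coupling = c("conditional", "independent")) {
  monotonicity <- match.arg(monotonicity)
  coupling <- match.arg(coupling)
  base <- coefs[["intercept"]] + coefs[["sex"]] * covariates$V1 +
    coefs[["age"]] * covariates$V2 + alpha_UZ * covariates$U
  p1 <- expit(base + coefs[["exposure"]])
  p0 <- expit(base)
  n <- length(p1)
  Z1 <- as.integer(stats::runif(n) < p1)
  if (monotonicity == "valid") {
    if (any(p0 > p1 + 1e-12))
      stop("monotone design violated: some participants have p0 > p1",
           call. = FALSE)
    u0 <- stats::runif(n)
    Z0 <- if (coupling == "conditional") {
      as.integer(Z1 == 1L & u0 < pmin(1, p0 / p1))
    } else {
      as.integer(Z1 == 1L & u0 < p0)
    }
  } else {
    Z0 <- as.integer(stats::runif(n) < p0)
  }
  list(Z0 = Z0, Z1 = Z1, p0 = p0, p1 = p1)
}

#' Classify participants into principal strata
#'
#' Maps the pair of potential survival statuses to the four principal
#' strata: always-survivors `AS` (1,1), compliant-survivors `CS` (0,1),
#' defiant-survivors `DS` (1,0) and never-survivors `NS` (0,0), where the
#' pair is `(Z(0), Z(1))`.
#'
#' @param Z0,Z1 Integer 0/1 vectors of potential survival under low and high
#'   exposure.
#' @return A factor with levels `AS`, `CS`, `DS`, `NS`.
#' @export
assign_strata <- function(Z0, Z1) {
  if (!all(Z0 %in% c(0L, 1L)) || !all(Z1 %in% c(0L, 1L)))
    stop("potential survival indicators must be 0/1", call. = FALSE)
  code <- 2L * Z0 + Z1  # 3 = AS, 1 = CS, 2 = DS, 0 = NS
  factor(c("NS", "CS", "DS", "AS")[code + 1L], levels = c("AS", "CS", "DS", "NS"))
}

#' Generate potential outcomes under both exposure levels
#'
#' For each exposure level `a`, the outcome probability among participants
#' who would survive that level is
#' `expit(intercept + beta_A a + c_sex V1 + c_age V2 + beta_UY U)`.
#' `Y(a)` is generated only where `Z(a) = 1` and is `NA` (undefined, the
#' outcome of a dead participant) elsewhere. A single shared uniform draw
#' per participant thresholds both potential outcomes, so the two are
#' coupled by common random numbers; this leaves both marginal laws
#' untouched while sharply reducing Monte-Carlo noise in within-cohort
#' contrasts such as the empirical SACE.
#'
#' @param covariates Covariate block.
#' @param Z0,Z1 Potential survival indicators.
#' @param coefs Named outcome coefficients `intercept`, `sex`, `age`.
#' @param beta_UY Log odds ratio of `U` on the outcome.
#' @param beta_A Conditional exposure coefficient, usually the value returned
#'   by [calibrate_exposure_coefficient()].
#' @return A list with integer vectors `Y0`, `Y1` (`NA` where undefined).
#' @export
generate_potential_outcomes <- function(covariates, Z0, Z1, coefs, beta_UY, beta_A) {
  base <- coefs[["intercept"]] + coefs[["sex"]] * covariates$V1 +
    coefs[["age"]] * covariates$V2 + beta_UY * covariates$U
  u <- stats::runif(nrow(covariates))
  Y0 <- ifelse(Z0 == 1L, as.integer(u < expit(base)), NA_integer_)
  Y1 <- ifelse(Z1 == 1L, as.integer(u < expit(base + beta_A)), NA_integer_)
  list(Y0 = Y0, Y1 = Y1)
}

#' Generate attendance at the follow-up wave
#'
#' Attendance is defined for survivors only and depends on exposure, sex,
#' age and the unmeasured residence indicator `D`:
#' `R ~ Bernoulli(expit(intercept + c_A A + c_sex V1 + c_age V2 + c_D D))`.
#'
#' @param covariates Covariate block.
#' @param A Observed exposure.
#' @param Z Observed survival indicator.
#' @param coefs Named attendance coefficients `intercept`, `exposure`,
#'   `sex`, `age`, `residence`.
#' @return Integer vector `R`, `NA` (undefined) where `Z = 0`.
#' @export
generate_attendance <- function(covariates, A, Z, coefs) {
  lp <- coefs[["intercept"]] + coefs[["exposure"]] * A +
    coefs[["sex"]] * covariates$V1 + coefs[["age"]] * covariates$V2 +
    coefs[["residence"]] * covariates$D
  R <- as.integer(stats::runif(nrow(covariates)) < expit(lp))
  R[Z == 0L] <- NA_integer_
  R
}

#' Simulate a complete cohort with known potential outcomes
#'
#' Runs the full generating mechanism of a scenario: covariates, exposure,
#' potential survival and coupling, principal strata, potential outcomes,
#' observed survival `Z = Z(A)`, attendance among survivors, and the
#' observed outcome `Y_obs` (equal to `Y(A)` for attending survivors,
#' missing -- `NA` with `Z = 1, R = 0` -- for non-attending survivors, and
#' undefined -- `NA` with `Z = 0` -- for the dead).
#'
#' @param config A [scenario_config()].
#' @param beta_A Calibrated conditional exposure coefficient for the outcome
#'   model; see [calibrate_exposure_coefficient()].
#' @param seed Optional integer seed set before generation.
#' @param n Cohort size; defaults to `config$n_participants`.
#' @return A data frame of class `sace_cohort` (truth view) with columns
#'   `id, V1, V2, U, D, A, Z0, Z1, stratum, Y0, Y1, Z, R, Y_obs`. In the
#'   truth view the analyst-hidden columns are present; use
#'   [assemble_observed()] for the analyst view. Undefined values (outcomes
#'   or attendance of the dead) are `NA` and are distinguishable from merely
#'   missing outcomes through `Z` and `R`.
#' @export
simulate_cohort <- function(config, beta_A, seed = NULL, n = config$n_participants) {
  if (!inherits(config, "sace_scenario"))
    stop("'config' must be a scenario_config() object", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cov <- generate_covariates(n, config)
  A <- generate_exposure(cov, config$exposure_coefs)
  ps <- generate_potential_survival(cov, config$survival_coefs, config$alpha_UZ,
                                    config$monotonicity, config$survival_coupling)
  stratum <- assign_strata(ps$Z0, ps$Z1)
  po <- generate_potential_outcomes(cov, ps$Z0, ps$Z1, config$outcome_coefs,
                                    config$beta_UY, beta_A)
  Z <- ifelse(A == 1L, ps$Z1, ps$Z0)
  R <- generate_attendance(cov, A, Z, config$attendance_coefs)
  Y_obs <- ifelse(Z == 1L & !is.na(R) & R == 1L,
                  ifelse(A == 1L, po$Y1, po$Y0), NA_integer_)
  out <- data.frame(id = seq_len(n), V1 = cov$V1, V2 = cov$V2, U = cov$U,
                    D = cov$D, A = A, Z0 = ps$Z0, Z1 = ps$Z1,
                    stratum = stratum, Y0 = po$Y0, Y1 = po$Y1, Z = Z, R = R,
                    Y_obs = Y_obs)
  class(out) <- c("sace_cohort", "data.frame")
  attr(out, "view") <- "truth"
  attr(out, "beta_A") <- beta_A
  attr(out, "scenario_id") <- config$id
  out
}

#' Reduce a truth cohort to the analyst-visible view
#'
#' Drops everything an analyst could not observe: the unmeasured covariates
#' `U` and `D`, both potential survival and outcome columns, and the
#' principal stratum. The observed columns (`V1`, `V2`, `A`, `Z`, `R`,
#' `Y_obs`) are untouched.
#'
#' @param cohort A truth-view `sace_cohort`.
#' @return An observed-view `sace_cohort` with columns
#'   `id, V1, V2, A, Z, R, Y_obs`.
#' @export
assemble_observed <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (identical(attr(cohort, "view"), "observed")) return(cohort)
  hidden <- c("U", "D", "Z0", "Z1", "Y0", "Y1", "stratum")
  if (!any(hidden %in% names(cohort))) {
    # already an analyst-level table (e.g. user-supplied): just mark it
    class(cohort) <- unique(c("sace_cohort", class(cohort)))
    attr(cohort, "view") <- "observed"
    return(cohort)
  }
  out <- cohort[, c("id", "V1", "V2", "A", "Z", "R", "Y_obs")]
  class(out) <- c("sace_cohort", "data.frame")
  attr(out, "view") <- "observed"
  attr(out, "scenario_id") <- attr(cohort, "scenario_id")
  out
}

#' @export
print.sace_cohort <- function(x, ...) {
  v <- attr(x, "view")
  cat(sprintf("Simulated cohort (%s view): %d participants, %d survivors\n",
              if (is.null(v)) "?" else v, nrow(x), sum(x$Z == 1L)))
  if (identical(v, "truth"))
    print(table(stratum = x$stratum))
  cat(sprintf("  exposed: %d; missing outcomes among survivors: %d\n",
              sum(x$A == 1L), sum(x$Z == 1L & !is.na(x$R) & x$R == 0L)))
  invisible(x)
}

#' Empirical SACE log odds ratio from a truth cohort
#'
#' The survivor average causal effect on the log odds-ratio scale, computed
#' from the known potential outcomes among always-survivors:
#' `log(odds[Y(1) = 1 | AS] / odds[Y(0) = 1 | AS])`.
#'
#' @param cohort Truth-view `sace_cohort`.
#' @return Log odds ratio (numeric scalar).
#' @export
empirical_sace <- function(cohort) {
  .need_truth(cohort)
  as_ <- cohort$stratum == "AS"
  y1 <- cohort$Y1[as_]; y0 <- cohort$Y0[as_]
  cells <- c(sum(y1 == 1L), sum(y1 == 0L), sum(y0 == 1L), sum(y0 == 0L))
  if (any(cells == 0L))
    stop("degenerate cohort: a zero cell among always-survivors; ",
         "increase the cohort size or the outcome prevalence", call. = FALSE)
  log(cells[1] / cells[2]) - log(cells[3] / cells[4])
}

#' Empirical sensitivity parameter tau from a truth cohort
#'
#' The ratio of the odds of the outcome under exposure among
#' compliant-survivors to that among always-survivors,
#' `odds[Y(1) = 1 | CS] / odds[Y(1) = 1 | AS]`. Defiant- and never-survivors
#' do not enter. `tau = 1` means always- and compliant-survivors share the
#' same outcome distribution under exposure (no survival bias).
#'
#' @param cohort Truth-view `sace_cohort`.
#' @return The odds ratio `tau`, or `NA` with a warning if the CS stratum is
#'   empty or a cell is zero.
#' @export
empirical_tau <- function(cohort) {
  .need_truth(cohort)
  y_cs <- cohort$Y1[cohort$stratum == "CS"]
  y_as <- cohort$Y1[cohort$stratum == "AS"]
  cells <- c(sum(y_cs == 1L), sum(y_cs == 0L), sum(y_as == 1L), sum(y_as == 0L))
  if (length(y_cs) == 0L || any(cells == 0L)) {
    warning("tau undefined: empty compliant-survivor stratum or zero cell",
            call. = FALSE)
    return(NA_real_)
  }
  (cells[1] / cells[2]) / (cells[3] / cells[4])
}

.need_truth <- function(cohort) {
  if (!all(c("stratum", "Y0", "Y1") %in% names(cohort)))
    stop("a truth-view cohort (with strata and potential outcomes) is required",
         call. = FALSE)
  invisible(cohort)
}

#' Calibrate the conditional exposure effect to a target marginal SACE
#'
#' Finds the conditional exposure coefficient `beta_A` of the outcome model
#' such that the marginal SACE odds ratio among always-survivors in cohorts
#' generated under `config` equals `config$target_sace_or`. Because odds
#' ratios are non-collapsible and the always-survivor stratum's composition
#' depends on `alpha_UZ` and `beta_UY`, the calibration is performed per
#' scenario.
#'
#' One large calibration cohort (covariates, potential survival, strata and
#' the shared outcome uniform draw) is generated once and held fixed across
#' iterates (common random numbers). With `smooth = TRUE` (default) the
#' calibration target replaces the binomial outcome draws by their
#' conditional expectations given covariates within the always-survivor
#' stratum, making the target a smooth, strictly increasing function of
#' `beta_A` that is solved by [stats::uniroot()] essentially exactly; the
#' covariate- and stratum-level sampling noise that remains is negligible at
#' the default `n_calib`. With `smooth = FALSE` the drawn outcomes are used
#' and the root found by bisection to within `tol` on the log odds-ratio
#' scale.
#'
#' @param config A [scenario_config()].
#' @param n_calib Calibration cohort size (default `1e6`).
#' @param tol Tolerance on the log odds-ratio scale for the drawn-outcome
#'   mode (default 0.002).
#' @param seed Seed for the calibration cohort; defaults to a child of
#'   `config$base_seed`.
#' @param smooth Use expected outcomes instead of drawn outcomes (default
#'   `TRUE`).
#' @return The calibrated coefficient `beta_A` (numeric scalar).
#' @export
calibrate_exposure_coefficient <- function(config, n_calib = 1e6, tol = 0.002,
                                           seed = NULL, smooth = TRUE) {
  if (!inherits(config, "sace_scenario"))
    stop("'config' must be a scenario_config() object", call. = FALSE)
  if (is.null(seed)) seed <- derive_seed(config$base_seed, 999983L)
  set.seed(seed)
  cov <- generate_covariates(n_calib, config)
  ps <- generate_potential_survival(cov, config$survival_coefs, config$alpha_UZ,
                                    config$monotonicity, config$survival_coupling)
  as_ <- ps$Z0 == 1L & ps$Z1 == 1L
  if (sum(as_) < 100L)
    stop("calibration cohort has too few always-survivors", call. = FALSE)
  oc <- config$outcome_coefs
  base_as <- oc[["intercept"]] + oc[["sex"]] * cov$V1[as_] +
    oc[["age"]] * cov$V2[as_] + config$beta_UY * cov$U[as_]
  u_as <- stats::runif(n_calib)[as_]
  target <- log(config$target_sace_or)

  f <- if (smooth) {
    p0bar <- mean(expit(base_as))
    function(b) stats::qlogis(mean(expit(base_as + b))) - stats::qlogis(p0bar) - target
  } else {
    y0 <- u_as < expit(base_as)
    lodds0 <- log(sum(y0) / sum(!y0))
    function(b) {
      y1 <- u_as < expit(base_as + b)
      s <- sum(y1)
      if (s == 0L || s == length(y1)) return(sign(-0.5 + (s > 0)) * Inf)
      log(s / (length(y1) - s)) - lodds0 - target
    }
  }

  lo <- target - 2; hi <- target + 2; widen <- 0L
  while (f(lo) > 0 || f(hi) < 0) {
    lo <- lo - 2; hi <- hi + 2; widen <- widen + 1L
    if (widen > 2L)
      stop(sprintf(
        "calibration bracket failure for scenario %s: f(%.1f) = %.3f, f(%.1f) = %.3f",
        config$id, lo, f(lo), hi, f(hi)), call. = FALSE)
  }
  if (smooth) {
    stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  } else {
    # bisection on a monotone step function; stop once inside tol
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm) <= tol || (hi - lo) < 1e-8) return(mid)
      if (fm > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
}
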