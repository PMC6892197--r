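#' Fitted propensities for exposure, survival or attendance
#'
#' Fits the three logistic propensity models of the weighting scheme on an
#' observed-view cohort:
#' \describe{
#'   \item{exposure}{`P(A = 1 | V)` on all baseline participants, covariates
#'     the measured exposure--outcome confounders (default `V1`, `V2`).}
#'   \item{survival}{`P(Z = 1 | A, V)` on all baseline participants. The
#'     unmeasured confounder `U` cannot enter, which is precisely the source
#'     of survival bias the simulation study quantifies.}
#'   \item{attendance}{`P(R = 1 | Z = 1, A, V)` on survivors only; the
#'     unmeasured attendance predictor `D` cannot enter.}
#' }
#'
#' @param cohort Observed-view cohort (a data frame with columns `V1`, `V2`,
#'   `A`, `Z`, `R`).
#' @param role One of `"exposure"`, `"survival"`, `"attendance"`.
#' @param covariates Character vector of baseline covariate columns
#'   (default `c("V1", "V2")`).
#' @param start Optional starting coefficients forwarded to
#'   [fit_logistic()] (used to accelerate bootstrap refits).
#' @return Numeric vector of fitted probabilities for the role's population
#'   (all participants for exposure and survival, survivors for attendance),
#'   clipped defensively into `(0, 1)` with a warning if clipping triggers.
#'   The fitted coefficients are attached as attribute `"coefficients"`.
#' @export
fit_propensity <- function(cohort, role = c("exposure", "survival", "attendance"),
                           covariates = c("V1", "V2"), start = NULL) {
  role <- match.arg(role)
  V <- as.matrix(cohort[, covariates, drop = FALSE])
  switch(role,
    exposure = {
      y <- cohort$A
      x <- cbind("(Intercept)" = 1, V)
    },
    survival = {
      y <- cohort$Z
      x <- cbind("(Intercept)" = 1, A = cohort$A, V)
    },
    attendance = {
      keep <- cohort$Z == 1L
      if (!any(keep)) stop("no survivors to fit the attendance model on", call. = FALSE)
      y <- cohort$R[keep]
      x <- cbind("(Intercept)" = 1, A = cohort$A[keep], V[keep, , drop = FALSE])
    }
  )
  if (length(unique(y)) < 2L)
    warning(sprintf("degenerate %s model: outcome shows no variation", role),
            call. = FALSE)
  fit <- fit_logistic(y, x, start = start)
  p <- fit$fitted
  lo <- 1e-12
  if (any(p < lo | p > 1 - lo)) {
    warning(sprintf("clipping %d fitted %s propensities away from {0, 1}",
                    sum(p < lo | p > 1 - lo), role), call. = FALSE)
    p <- pmin(pmax(p, lo), 1 - lo)
  }
  attr(p, "coefficients") <- fit$coefficients
  p
}

#' Stabilizing factors for the exposure weights
#'
#' Constant numerators that stabilize the inverse-probability-of-exposure
#' weights, one per exposure group: the average fitted probability of the
#' *observed* exposure level, `SF1 = mean(p_i | A = 1)` and
#' `SF0 = mean(1 - p_i | A = 0)`. With `literal = TRUE` the `A = 0` factor
#' instead averages `p_i` itself (averaging the high-exposure propensity in
#' both groups); the default reading makes the stabilized numerator an
#' estimate of `P(A = A_i)`, the standard stabilized-weight construction,
#' and is what the balance properties of the weights rely on.
#'
#' @param p Fitted exposure propensities on all baseline participants.
#' @param A Observed exposure.
#' @param literal Use `mean(p_i)` for the `A = 0` group as well.
#' @return Named numeric vector `c(SF0 = , SF1 = )`.
#' @export
stabilizing_factors <- function(p, A, literal = FALSE) {
  if (!any(A == 1L) || !any(A == 0L))
    stop("both exposure groups must be non-empty", call. = FALSE)
  SF1 <- mean(p[A == 1L])
  SF0 <- if (literal) mean(p[A == 0L]) else mean(1 - p[A == 0L])
  c(SF0 = SF0, SF1 = SF1)
}

#' Combined stabilized inverse-probability weights
#'
#' The per-survivor weight
#' `W_i = SF_{A_i} / [ (A_i p_i + (1 - A_i)(1 - p_i)) q_i m_i ]`
#' combining inverse probabilities of the observed exposure (`p`), survival
#' (`q`) and attendance among survivors (`m`) with the group stabilizing
#' factor. Weights are undefined (`NA`) for participants who do not survive:
#' the dead have no outcome to weight.
#'
#' @param p,q Exposure and survival propensities on all baseline
#'   participants.
#' @param m Attendance propensities, a vector aligned with survivors (in
#'   cohort order) or with all participants (`NA` allowed for the dead).
#' @param SF Stabilizing factors from [stabilizing_factors()].
#' @param A,Z Observed exposure and survival.
#' @param cap_quantile Optional upper quantile (e.g. `0.99`) at which
#'   weights are capped; capping is off by default and, when on, the number
#'   of capped weights is reported via a warning.
#' @return Numeric vector of length `N`; `NA` where `Z = 0`, strictly
#'   positive elsewhere.
#' @export
compute_weights <- function(p, q, m, SF, A, Z, cap_quantile = NULL) {
  N <- length(A)
  stopifnot(length(p) == N, length(q) == N)
  p <- as.vector(p); q <- as.vector(q); m <- as.vector(m)
  mm <- rep(NA_real_, N)
  if (length(m) == N) mm <- m else mm[Z == 1L] <- m
  if (any(!is.finite(mm[Z == 1L])))
    stop("attendance propensities must be available for every survivor", call. = FALSE)
  denom <- (A * p + (1 - A) * (1 - p)) * q * mm
  if (any(denom[Z == 1L] <= 0))
    stop("non-positive weight denominator", call. = FALSE)
  W <- ifelse(A == 1L, SF[["SF1"]], SF[["SF0"]]) / denom
  W[Z == 0L] <- NA_real_
  if (!is.null(cap_quantile)) {
    cap <- stats::quantile(W[Z == 1L], cap_quantile, names = FALSE)
    n_cap <- sum(W > cap, na.rm = TRUE)
    if (n_cap > 0L) {
      warning(sprintf("capped %d weights at the %.3g quantile (%.3g)",
                      n_cap, cap_quantile, cap), call. = FALSE)
      W <- pmin(W, cap)
    }
  }
  W
}

#' Standardized difference between exposure groups
#'
#' Model-free covariate balance diagnostic: the difference in means
#' (proportions for binary variables) between the `A = 0` and `A = 1`
#' groups, divided by the pooled standard deviation
#' `sqrt((s0^2 + s1^2) / 2)`. For a binary variable the group variances are
#' `p(1 - p)`. A weighted version substitutes weighted means and variances.
#' Reported on the proportion scale; multiply by 100 for the percentage
#' convention.
#'
#' @param x Covariate vector (binary or continuous).
#' @param group 0/1 exposure indicator.
#' @param weights Optional positive weights.
#' @return The standardized difference `d` (low-exposure minus
#'   high-exposure), or `NA` with a warning when the pooled variance is zero.
#' @examples
#' standardized_difference(c(rep(1, 912), rep(0, 88), rep(1, 806), rep(0, 194)),
#'                         rep(c(0, 1), c(1000, 1000)))
#' @export
standardized_difference <- function(x, group, weights = NULL) {
  if (is.null(weights)) weights <- rep.int(1, length(x))
  stats_for <- function(g) {
    w <- weights[group == g]; v <- x[group == g]
    m <- sum(w * v) / sum(w)
    s2 <- if (all(v %in% c(0, 1))) m * (1 - m)
          else sum(w * (v - m)^2) / (sum(w) - 1)
    c(m, s2)
  }
  s0 <- stats_for(0); s1 <- stats_for(1)
  pooled <- sqrt((s0[2] + s1[2]) / 2)
  if (pooled == 0) {
    warning("zero pooled variance: standardized difference undefined", call. = FALSE)
    return(NA_real_)
  }
  (s0[1] - s1[1]) / pooled
}

#' Covariate balance before and after weighting
#'
#' @param cohort Observed-view cohort.
#' @param W Weights from [compute_weights()].
#' @param covariates Covariate columns to diagnose.
#' @return Data frame with one row per covariate and columns `unweighted`
#'   and `weighted` standardized differences among analysed rows (attending
#'   survivors with observed outcomes).
#' @export
balance_table <- function(cohort, W, covariates = c("V1", "V2")) {
  keep <- cohort$Z == 1L & !is.na(cohort$R) & cohort$R == 1L & !is.na(cohort$Y_obs)
  out <- data.frame(
    covariate = covariates,
    unweighted = vapply(covariates, function(v)
      standardized_difference(cohort[[v]][keep], cohort$A[keep]), 0),
    weighted = vapply(covariates, function(v)
      standardized_difference(cohort[[v]][keep], cohort$A[keep], W[keep]), 0),
    row.names = NULL
  )
  out
}

#' SACE estimation by a weighted marginal structural model
#'
#' The full inverse-probability-weighted pipeline: fit the exposure,
#' survival and attendance propensity models, build stabilized combined
#' weights over survivors, and fit a weighted logistic regression of the
#' observed outcome on exposure and baseline confounders among attending
#' survivors with observed outcomes. The exposure coefficient of that final
#' fit is the SACE estimate on the log odds-ratio scale. An optional
#' bias-corrected bootstrap (resampling baseline participants and refitting
#' every model) supplies the confidence interval; a sandwich (robust)
#' standard error is also reported for diagnostics but plays no role in the
#' interval.
#'
#' @param cohort Observed-view cohort (or a truth cohort, which is reduced
#'   via [assemble_observed()]).
#' @param covariates Baseline confounder columns (default `c("V1", "V2")`).
#' @param boot Number of bootstrap resamples for the BC interval; `0`
#'   (default) skips the interval.
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed for the bootstrap.
#' @param cap_quantile Optional weight cap passed to [compute_weights()].
#' @param literal_sf Use the literal stabilizing-factor reading; see
#'   [stabilizing_factors()].
#' @return An object of class `sace_estimate`: a list with `method = "msm"`,
#'   `log_or`, `or`, `ci` (when bootstrapped), `se_robust`, `converged`,
#'   `n_used`, a `balance` table and a `weight_summary`.
#' @export
estimate_msm <- function(cohort, covariates = c("V1", "V2"), boot = 0,
                         level = 0.95, seed = NULL, cap_quantile = NULL,
                         literal_sf = FALSE) {
  cohort <- assemble_observed(cohort)
  point <- .msm_point(cohort, covariates, cap_quantile, literal_sf, diagnostics = TRUE)
  est <- list(method = "msm", log_or = point$log_or, or = exp(point$log_or),
              ci = c(NA_real_, NA_real_), level = level,
              se_robust = point$se_robust, converged = point$converged,
              n_used = point$n_used, balance = point$balance,
              weight_summary = point$weight_summary)
  if (boot > 0) {
    starts <- point$coefs  # warm-start every refit at the full-sample fit
    bt <- bc_bootstrap_ci(cohort, function(d)
      .msm_point(d, covariates, cap_quantile, literal_sf, starts = starts)$log_or,
      B = boot, level = level, seed = seed, theta_hat = point$log_or)
    est$ci <- bt$ci
    est$boot <- bt[c("z0", "B_used", "n_failed", "degenerate")]
  }
  class(est) <- "sace_estimate"
  est
}

# Point estimate (and optional diagnostics) of the MSM pipeline.
.msm_point <- function(cohort, covariates = c("V1", "V2"), cap_quantile = NULL,
                       literal_sf = FALSE, diagnostics = FALSE, starts = NULL) {
  p <- fit_propensity(cohort, "exposure", covariates, start = starts$p)
  q <- fit_propensity(cohort, "survival", covariates, start = starts$q)
  m <- fit_propensity(cohort, "attendance", covariates, start = starts$m)
  SF <- stabilizing_factors(p, cohort$A, literal = literal_sf)
  W <- compute_weights(p, q, m, SF, cohort$A, cohort$Z, cap_quantile)
  keep <- cohort$Z == 1L & !is.na(cohort$R) & cohort$R == 1L & !is.na(cohort$Y_obs)
  y <- cohort$Y_obs[keep]
  x <- cbind("(Intercept)" = 1, A = cohort$A[keep],
             as.matrix(cohort[keep, covariates, drop = FALSE]))
  w <- W[keep]
  fit <- fit_logistic(y, x, weights = w, start = starts$y)
  out <- list(log_or = unname(fit$coefficients["A"]),
              converged = fit$converged, n_used = sum(keep),
              coefs = list(p = attr(p, "coefficients"),
                           q = attr(q, "coefficients"),
                           m = attr(m, "coefficients"),
                           y = fit$coefficients))
  if (diagnostics) {
    mu <- fit$fitted
    xw <- x * (w * mu * (1 - mu))
    bread <- solve(crossprod(x, xw))
    meat <- crossprod(x * (w * (y - mu)))
    vc <- bread %*% meat %*% bread
    out$se_robust <- sqrt(diag(vc))[["A"]]
    out$balance <- balance_table(cohort, W, covariates)
    ws <- W[cohort$Z == 1L]
    out$weight_summary <- c(min = min(ws), median = stats::median(ws), max = max(ws))
  }
  out
}

#' @export
print.sace_estimate <- function(x, ...) {
  cat(sprintf("SACE estimate [%s]: log OR = %.4f (OR = %.4f)\n",
              x$method, x$log_or, x$or))
  if (!anyNA(x$ci))
    cat(sprintf("  %.0f%% BC bootstrap CI (log OR): [%.4f, %.4f]\n",
                100 * x$level, x$ci[1], x$ci[2]))
  if (!is.null(x$se_robust))
    cat(sprintf("  robust SE (diagnostic): %.4f\n", x$se_robust))
  cat(sprintf("  converged: %s; n used: %d\n", x$converged, x$n_used))
  invisible(x)
}
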