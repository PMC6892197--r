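#' Bias-corrected bootstrap confidence interval
#'
#' Nonparametric bootstrap at the baseline-participant level: rows of
#' `data` are resampled with replacement `B` times and `statistic` is
#' re-evaluated on each resample (for the estimators in this package that
#' means every propensity and outcome model is refitted). The
#' bias-correction constant is `z0 = qnorm(F)` where `F` is the fraction of
#' bootstrap estimates below the point estimate, ties counted half
#' (midrank), and the interval endpoints are the bootstrap-distribution
#' quantiles at `pnorm(2 z0 -/+ z_(1+level)/2)`. When the bootstrap
#' distribution is symmetric about the point estimate, `z0 = 0` and the BC
#' interval reduces to the percentile interval. Failed resamples
#' (errors or non-finite estimates) are dropped and counted; more than 10%
#' failures triggers an unreliable-interval warning.
#'
#' @param data Data frame of baseline participants.
#' @param statistic Function of a resampled data frame returning a scalar
#'   estimate.
#' @param B Number of resamples (>= 200; default 1000).
#' @param level Confidence level.
#' @param seed Optional seed.
#' @param theta_hat Point estimate on the original data; computed from
#'   `data` when omitted.
#' @return A list with `ci` (length-2 vector), `z0`, `B_used`, `n_failed`
#'   and `degenerate` (`TRUE` when all resample estimates coincide, giving a
#'   zero-width interval).
#' @export
bc_bootstrap_ci <- function(data, statistic, B = 1000, level = 0.95,
                            seed = NULL, theta_hat = NULL) {
  if (B < 200) stop("at least 200 bootstrap resamples are required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(theta_hat)) theta_hat <- statistic(data)
  n <- nrow(data)
  cols <- as.list(data)  # plain column vectors: cheap row resampling
  resample <- function(idx) {
    d <- lapply(cols, `[`, idx)
    class(d) <- "data.frame"
    attr(d, "row.names") <- .set_row_names(n)
    d
  }
  th <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    th[b] <- tryCatch(statistic(resample(idx)),
                      error = function(e) NA_real_)
  }
  ok <- is.finite(th)
  n_failed <- sum(!ok)
  if (n_failed > 0.1 * B)
    warning(sprintf("unreliable interval: %d of %d bootstrap resamples failed",
                    n_failed, B), call. = FALSE)
  th <- th[ok]
  if (length(th) == 0L) stop("all bootstrap resamples failed", call. = FALSE)
  degenerate <- max(th) - min(th) == 0
  if (degenerate)
    warning("degenerate bootstrap distribution: zero-width interval", call. = FALSE)
  frac <- (sum(th < theta_hat) + 0.5 * sum(th == theta_hat)) / length(th)
  frac <- min(max(frac, 0.5 / length(th)), 1 - 0.5 / length(th))
  z0 <- stats::qnorm(frac)
  za <- stats::qnorm((1 + level) / 2)
  probs <- stats::pnorm(c(2 * z0 - za, 2 * z0 + za))
  ci <- unname(stats::quantile(th, probs, type = 7))
  list(ci = ci, z0 = z0, B_used = length(th), n_failed = n_failed,
       degenerate = degenerate)
}
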