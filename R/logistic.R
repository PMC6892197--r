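#' Weighted logistic regression core
#'
#' Shared numeric core for every propensity, outcome and weighted outcome
#' model in the package. Maximizes the (optionally weighted) Bernoulli
#' log-likelihood by iteratively reweighted least squares with step-halving,
#' declaring convergence when the largest absolute component of the weighted
#' score `X'w(y - mu)` falls below `1e-8` or the relative deviance change
#' falls below `1e-10`, within at most 100 iterations. The implementation is
#' deliberately minimal (dense normal equations, Cholesky solve) because the
#' designs in this package are small and well conditioned and the fit sits
#' inside Monte-Carlo and bootstrap loops; tests verify agreement with
#' [stats::glm()] and with direct likelihood maximization to high precision.
#'
#' @param y 0/1 response vector.
#' @param x Design matrix including the intercept column.
#' @param weights Optional positive case weights (inverse-probability
#'   weights may be non-integer).
#' @param start Optional starting coefficients (e.g. the full-sample fit
#'   when refitting on bootstrap resamples).
#' @return A list with `coefficients`, `fitted` (probabilities), `converged`,
#'   `deviance` and `iter`.
#' @section Errors:
#' Rank-deficient designs and (quasi-)perfect separation abort with a
#' diagnostic message rather than returning an unusable fit.
#' @examples
#' x <- cbind(1, c(0, 0, 1, 1, 0, 1))
#' y <- c(0, 1, 1, 1, 0, 0)
#' fit_logistic(y, x)$coefficients
#' @export
fit_logistic <- function(y, x, weights = NULL, start = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)))
    colnames(x) <- c("(Intercept)", paste0("x", seq_len(max(ncol(x) - 1L, 0L))))[seq_len(ncol(x))]
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(x) != n) stop("design and response dimensions differ", call. = FALSE)
  if (n == 0L) stop("empty estimation population", call. = FALSE)
  w <- if (is.null(weights)) rep.int(1, n) else as.numeric(weights)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be positive and finite", call. = FALSE)

  p <- ncol(x)
  if (is.null(start)) {
    beta <- numeric(p)
    ybar <- min(max(sum(w * y) / sum(w), 1e-6), 1 - 1e-6)
    beta[1L] <- log(ybar / (1 - ybar))  # intercept start at the weighted mean
  } else {
    stopifnot(length(start) == p)
    beta <- as.numeric(start)
  }
  eps <- 1e-12
  # deviance from the linear predictor, numerically stable in both tails
  dev_of <- function(eta) {
    2 * sum(w * (pmax(eta, 0) - y * eta + log1p(exp(-abs(eta)))))
  }
  eta <- drop(x %*% beta)
  mu <- 1 / (1 + exp(-eta))
  converged <- FALSE
  it <- 0L
  dev <- NA_real_
  while (it < 100L) {
    it <- it + 1L
    score <- drop(crossprod(x, w * (y - mu)))
    if (max(abs(score)) < 1e-8) { converged <- TRUE; break }
    wv <- w * pmax(mu * (1 - mu), eps)
    ch <- tryCatch(chol(crossprod(x, x * wv)), error = function(e) NULL)
    if (is.null(ch))
      stop("singular design in logistic fit (collinear or constant columns)",
           call. = FALSE)
    step <- backsolve(ch, forwardsolve(t(ch), score))
    if (it <= 15L) {
      # plain Newton: quadratic convergence from the mean-response start
      beta <- beta + step
      eta <- drop(x %*% beta)
      mu <- 1 / (1 + exp(-eta))
    } else {
      # slow progress: guard each step by the deviance, halving as needed,
      # and allow the relative-deviance stopping rule
      if (is.na(dev)) dev <- dev_of(eta)
      dev_old <- dev
      lambda <- 1
      repeat {
        beta_new <- beta + lambda * step
        eta <- drop(x %*% beta_new)
        dev <- dev_of(eta)
        if (dev <= dev_old + 1e-8 || lambda < 1e-8) break
        lambda <- lambda / 2
      }
      beta <- beta_new
      mu <- 1 / (1 + exp(-eta))
      if (abs(dev_old - dev) / (abs(dev) + 0.1) < 1e-10) {
        converged <- TRUE
        break
      }
    }
  }
  if (max(abs(beta)) > 30 && length(unique(y)) > 1L)
    stop("perfect or quasi-perfect separation in logistic fit (max |coef| = ",
         format(max(abs(beta)), digits = 3), ")", call. = FALSE)
  list(coefficients = stats::setNames(beta, colnames(x)),
       fitted = mu, converged = converged,
       deviance = if (is.na(dev)) dev_of(eta) else dev, iter = it)
}

# Predicted probabilities from a fit_logistic() result on a new design.
.predict_logistic <- function(fit, x) {
  unname(expit(drop(as.matrix(x) %*% fit$coefficients)))
}
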