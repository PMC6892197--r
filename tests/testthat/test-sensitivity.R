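test_that("arm outcome models predict for every survivor, attender or not", {
  n <- 400
  co <- data.frame(id = 1:n, V1 = rep(0:1, n / 2), V2 = 0,
                   A = rep(c(0L, 1L), each = n / 2), Z = 1L,
                   R = rep(c(1L, 0L), c(n - 40, 40)))
  set.seed(51)
  co$Y_obs <- ifelse(co$R == 1L, rbinom(n, 1, ifelse(co$A == 1, 0.2, 0.1)),
                     NA_integer_)
  h <- fit_arm_outcome_models(co, covariates = character(0))
  expect_length(h$h0, n)
  expect_length(h$h1, n)
  # intercept-only: predictions are the arm-specific attender event rates
  r0 <- mean(co$Y_obs[co$A == 0L & co$R == 1L])
  r1 <- mean(co$Y_obs[co$A == 1L & co$R == 1L])
  expect_equal(unique(round(h$h0, 10)), round(r0, 10))
  expect_equal(unique(round(h$h1, 10)), round(r1, 10))
  # attendance never enters: identical covariates give identical predictions
  expect_equal(h$h1[co$R == 0L][1], h$h1[co$R == 1L][1])

  co$Y_obs[co$A == 0L] <- 0L
  expect_error(fit_arm_outcome_models(co, character(0)), "degenerate")
})

test_that("the survival model yields potential probabilities for all participants", {
  # equal survival in both arms: the exposure coefficient is exactly zero
  co <- data.frame(id = 1:20, V1 = 0L, V2 = 0,
                   A = rep(0:1, each = 10),
                   Z = rep(c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L), 2))
  g <- fit_marginal_survival(co, covariates = character(0))
  expect_equal(g$g0, g$g1, tolerance = 1e-9)
  expect_equal(unique(round(g$g0, 9)), 0.9)
  expect_length(g$g0, 20)
})

test_that("marginal quantities combine survival and outcome predictions correctly", {
  # two survivors with (g, h) = (0.8, 0.2) and (0.6, 0.1) at a = 1
  g <- list(g0 = c(0.7, 0.5), g1 = c(0.8, 0.6))
  h <- list(h0 = c(0.15, 0.05), h1 = c(0.2, 0.1))
  mq <- marginal_quantities(g, h, Z = c(1L, 1L))
  expect_equal(mq$xi1, (0.8 * 0.2 + 0.6 * 0.1) / 2)
  expect_equal(mq$nu1, 0.7)
  # homogeneous cohort: constants propagate
  mq2 <- marginal_quantities(list(g0 = rep(0.9, 4), g1 = rep(0.9, 4)),
                             list(h0 = rep(0.1, 4), h1 = rep(0.1, 4)),
                             Z = rep(1L, 4))
  expect_equal(mq2$nu0, 0.9); expect_equal(mq2$xi0, 0.09)
  # xi increases with h at fixed g
  h_up <- list(h0 = h$h0, h1 = h$h1 + 0.05)
  expect_gt(marginal_quantities(g, h_up, c(1L, 1L))$xi1, mq$xi1)
  # survivors-only averaging switch changes nu when the dead differ
  g3 <- list(g0 = c(0.9, 0.9, 0.3), g1 = c(0.9, 0.9, 0.3))
  h3 <- list(h0 = c(0.1, 0.1), h1 = c(0.1, 0.1))
  zz <- c(1L, 1L, 0L)
  expect_equal(marginal_quantities(g3, h3, zz)$nu0, 0.7)
  expect_equal(marginal_quantities(g3, h3, zz, nu_population = FALSE)$nu0, 0.9)
  # inconsistent inputs abort: survivors carry far higher survival
  # probability than the baseline average, pushing xi above nu
  expect_error(marginal_quantities(list(g0 = c(0.9, 0.05), g1 = c(0.9, 0.05)),
                                   list(h0 = 0.9, h1 = 0.9),
                                   Z = c(1L, 0L)),
               "inconsistent")
})

test_that("the closed-form SACE odds ratio matches independently computed values", {
  # symmetric no-death case
  expect_equal(sace_or(1, 1, 0.5, 0.5, tau = 1), 1)
  # frozen values computed with 30-digit arithmetic
  expect_equal(sace_or(0.9, 0.95, 0.09, 0.06, tau = 1), 0.60674157303371,
               tolerance = 1e-10)
  expect_equal(sace_or(0.9, 0.95, 0.09, 0.06, tau = 2), 0.57796720360146,
               tolerance = 1e-10)
  expect_equal(sace_or(0.9, 0.95, 0.09, 0.06, tau = 0.5), 0.62367382281035,
               tolerance = 1e-10)
  # invalid configurations
  expect_error(sace_or(0.9, 0.95, 0.91, 0.06, tau = 1), "invalid")
  expect_error(sace_or(0.9, 0.95, 0.09, 0.06, tau = -1), "tau > 0")
})

test_that("the general formula agrees with the tau = 1 form in the limit", {
  cases <- list(c(0.9, 0.95, 0.09, 0.06), c(0.8, 0.9, 0.05, 0.04),
                c(0.95, 0.97, 0.2, 0.15))
  for (cs in cases) {
    at1 <- sace_or(cs[1], cs[2], cs[3], cs[4], tau = 1)
    for (eps in c(1e-4, 1e-6)) {
      expect_equal(sace_or(cs[1], cs[2], cs[3], cs[4], tau = 1 + eps), at1,
                   tolerance = 1e-4)
      expect_equal(sace_or(cs[1], cs[2], cs[3], cs[4], tau = 1 - eps), at1,
                   tolerance = 1e-4)
    }
  }
})

test_that("the SACE odds ratio is non-increasing in tau over the valid domain", {
  set.seed(53)
  taus <- c(0.25, 0.5, 1, 2, 4)
  for (k in 1:200) {
    # under monotonicity the compliant-survivor mass nu1 - nu0 is non-negative
    nu0 <- runif(1, 0.3, 0.95); nu1 <- runif(1, nu0, 1)
    xi0 <- runif(1, 0.01, 0.9) * nu0; xi1 <- runif(1, 0.01, 0.9) * nu1
    ors <- vapply(taus, function(t) sace_or(nu0, nu1, xi0, xi1, t), 0)
    expect_true(all(diff(ors) <= 1e-10),
                info = sprintf("nu0=%.3f nu1=%.3f xi0=%.3f xi1=%.3f",
                               nu0, nu1, xi0, xi1))
  }
})

test_that("with intercept-only models and no missingness tau = 1 gives the crude survivor OR", {
  set.seed(54)
  n <- 2000
  co <- data.frame(id = 1:n, V1 = rbinom(n, 1, 0.5), V2 = runif(n, -5, 5),
                   A = rep(0:1, n / 2))
  co$Z <- rbinom(n, 1, ifelse(co$A == 1, 0.9, 0.8))
  co$R <- ifelse(co$Z == 1L, 1L, NA_integer_)  # every survivor attends
  co$Y_obs <- ifelse(co$Z == 1L, rbinom(n, 1, ifelse(co$A == 1, 0.1, 0.15)),
                     NA_integer_)
  est <- estimate_sensitivity(co, tau = 1, covariates = character(0))[["sens@1"]]
  tab <- table(co$A[co$Z == 1L], co$Y_obs[co$Z == 1L])
  crude <- log(tab["1", "1"] * tab["0", "0"] / (tab["1", "0"] * tab["0", "1"]))
  expect_equal(est$log_or, unname(crude), tolerance = 1e-9)
})

test_that("estimate_sensitivity is permutation invariant and ordered in tau", {
  co <- quick_cohort(n = 6000, seed = 55)
  est <- estimate_sensitivity(co)
  expect_named(est, c("sens@0.5", "sens@1", "sens@2"))
  lors <- vapply(est, `[[`, 0, "log_or")
  expect_true(all(diff(lors) < 0))
  expect_true(all(vapply(est, `[[`, TRUE, "converged")))
  # relabelling participants changes nothing
  perm <- co[sample.int(nrow(co)), ]
  est2 <- estimate_sensitivity(perm)
  expect_equal(vapply(est2, `[[`, 0, "log_or"), lors, tolerance = 1e-12)
})
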