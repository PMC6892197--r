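test_that("covariate generation matches the configured distributions and is reproducible", {
  cfg <- scenario_config()
  set.seed(11)
  cov <- generate_covariates(1e6, cfg)
  for (v in c("V1", "U", "D"))
    expect_lt(abs(mean(cov[[v]]) - 0.5), 0.002)
  expect_lt(abs(mean(cov$V2)), 0.02)
  expect_lt(abs(stats::var(cov$V2) - 20^2 / 12), 0.3)
  expect_true(all(cov$V2 > -10 & cov$V2 < 10))

  set.seed(7); a <- generate_covariates(5, cfg)
  set.seed(7); b <- generate_covariates(5, cfg)
  expect_identical(a, b)
})

test_that("covariate configuration errors are caught", {
  expect_error(scenario_config(covariates = list(p_sex = 1.2, p_genotype = 0.5,
                                                 p_residence = 0.5, age_range = 10)),
               "p_sex")
  expect_error(scenario_config(covariates = list(p_sex = 0.5, p_genotype = 0.5,
                                                 p_residence = 0.5, age_range = -1)),
               "age_range")
})

test_that("exposure model follows its logistic law", {
  cov0 <- data.frame(V1 = 0L, V2 = 0, U = 0L, D = 0L)[rep(1, 2e5), ]
  set.seed(3)
  a_null <- generate_exposure(cov0, c(intercept = 0, sex = 0, age = 0))
  expect_lt(abs(mean(a_null) - 0.5), 0.005)
  a_ln2 <- generate_exposure(cov0, c(intercept = log(2), sex = 0, age = 0))
  expect_lt(abs(mean(a_ln2) - 2 / 3), 0.005)

  # marginal prevalence under defaults vs a numeric-integration oracle
  cfg <- scenario_config()
  set.seed(4)
  cov <- generate_covariates(1e6, cfg)
  A <- generate_exposure(cov, cfg$exposure_coefs)
  v2 <- seq(-10, 10, length.out = 2001)
  marg <- mean(vapply(0:1, function(v1)
    mean(plogis(cfg$exposure_coefs[["intercept"]] +
                cfg$exposure_coefs[["sex"]] * v1 +
                cfg$exposure_coefs[["age"]] * v2)), 0))
  expect_lt(abs(mean(A) - marg), 0.002)
})

test_that("potential survival marginals and the monotone coupling are correct", {
  cfg <- scenario_config()
  # identical marginals when the exposure does not affect survival (violated)
  cov <- data.frame(V1 = 0L, V2 = 0, U = 0L, D = 0L)[rep(1, 1e6), ]
  set.seed(5)
  ps <- generate_potential_survival(cov, c(intercept = qlogis(0.85), exposure = 0,
                                           sex = 0, age = 0),
                                    alpha_UZ = 0, monotonicity = "violated")
  expect_lt(abs(mean(ps$Z0) - mean(ps$Z1)), 0.002)

  # homogeneous p1 = 0.9, p0 = 0.81 under the valid coupling:
  # marginal of Z0 preserved and P(Z0 = 1 | Z1 = 1) = p0/p1 = 0.9
  set.seed(6)
  ps <- generate_potential_survival(cov, c(intercept = qlogis(0.81),
                                           exposure = qlogis(0.9) - qlogis(0.81),
                                           sex = 0, age = 0),
                                    alpha_UZ = 0, monotonicity = "valid")
  expect_lt(abs(mean(ps$Z0) - 0.81), 0.002)
  expect_lt(abs(mean(ps$Z0[ps$Z1 == 1L]) - 0.9), 0.002)
  expect_identical(sum(ps$Z0 == 1L & ps$Z1 == 0L), 0L)

  # a harmful exposure cannot be combined with the monotone design
  expect_error(generate_potential_survival(cov[1:10, ],
                                           c(intercept = 1, exposure = -0.5,
                                             sex = 0, age = 0),
                                           alpha_UZ = 0, monotonicity = "valid"),
               "p0 > p1")
  expect_error(scenario_config(survival_coefs = c(intercept = 1.1, exposure = -0.1,
                                                  sex = 0.2, age = -0.02)),
               "non-negative")
})

test_that("principal strata are assigned by the potential survival pair", {
  expect_identical(as.character(assign_strata(1L, 1L)), "AS")
  expect_identical(as.character(assign_strata(0L, 1L)), "CS")
  expect_identical(as.character(assign_strata(1L, 0L)), "DS")
  expect_identical(as.character(assign_strata(0L, 0L)), "NS")
  s <- assign_strata(c(1L, 0L, 1L, 0L), c(1L, 1L, 0L, 0L))
  expect_identical(sum(table(s)), 4L)
  expect_error(assign_strata(2L, 1L), "0/1")
})

test_that("strata composition responds to monotonicity as designed", {
  cfg_v <- scenario_config(monotonicity = "valid")
  cfg_x <- scenario_config(monotonicity = "violated")
  bA <- -0.51
  truth_v <- simulate_cohort(cfg_v, bA, seed = 21, n = 2e4)
  truth_x <- simulate_cohort(cfg_x, bA, seed = 21, n = 2e4)
  expect_identical(sum(truth_v$stratum == "DS"), 0L)
  expect_gt(sum(truth_x$stratum == "DS"), 0L)
  expect_identical(unname(sum(table(truth_v$stratum))), nrow(truth_v))
})

test_that("potential outcomes are undefined exactly where potential survival fails", {
  cov <- data.frame(V1 = rep(0L, 9), V2 = 0, U = 0L, D = 0L)
  Z0 <- c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L, 0L)
  Z1 <- c(1L, 0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L)
  set.seed(8)
  po <- generate_potential_outcomes(cov, Z0, Z1, c(intercept = 0, sex = 0, age = 0),
                                    beta_UY = 0, beta_A = 0)
  expect_identical(is.na(po$Y0), Z0 == 0L)
  expect_identical(is.na(po$Y1), Z1 == 0L)
})

test_that("the unmeasured confounder moves the outcome odds by its design value", {
  n <- 1e6
  cov <- data.frame(V1 = 0L, V2 = 0, U = rep(0:1, each = n / 2), D = 0L)
  set.seed(9)
  po <- generate_potential_outcomes(cov, Z0 = rep(1L, n), Z1 = rep(1L, n),
                                    c(intercept = -2.3, sex = 0, age = 0),
                                    beta_UY = log(2), beta_A = 0)
  odds <- function(y) mean(y) / (1 - mean(y))
  lor <- log(odds(po$Y1[cov$U == 1]) / odds(po$Y1[cov$U == 0]))
  expect_lt(abs(lor - log(2)), 0.03)
  # null effect: always-survivor arms coincide in distribution
  expect_lt(abs(mean(po$Y1) - mean(po$Y0)), 0.002)
})

test_that("attendance follows its logistic law and is undefined for the dead", {
  n <- 1e6
  cov <- data.frame(V1 = 0L, V2 = 0, U = 0L, D = rep(0:1, each = n / 2))
  A <- rep(0L, n); Z <- rep(1L, n); Z[1:100] <- 0L
  set.seed(10)
  R <- generate_attendance(cov, A, Z, c(intercept = 0, exposure = 0, sex = 0,
                                        age = 0, residence = log(0.5)))
  expect_true(all(is.na(R[Z == 0L])))
  odds <- function(r) mean(r) / (1 - mean(r))
  ok <- Z == 1L
  lor <- log(odds(R[ok & cov$D == 1]) / odds(R[ok & cov$D == 0]))
  expect_lt(abs(lor - log(0.5)), 0.03)
  expect_lt(abs(mean(R[ok & cov$D == 0]) - 0.5), 0.005)
})

test_that("the observed view hides the truth columns and encodes missingness correctly", {
  cfg <- scenario_config()
  truth <- simulate_cohort(cfg, -0.51, seed = 12, n = 5000)
  obs <- assemble_observed(truth)
  expect_named(obs, c("id", "V1", "V2", "A", "Z", "R", "Y_obs"))
  expect_false(any(c("U", "D", "Z0", "Z1", "Y0", "Y1", "stratum") %in% names(obs)))
  # Y_obs = Y(A) for attending survivors
  att <- truth$Z == 1L & truth$R == 1L
  expect_identical(obs$Y_obs[att],
                   ifelse(truth$A[att] == 1L, truth$Y1[att], truth$Y0[att]))
  # undefined for the dead, missing for non-attending survivors
  expect_true(all(is.na(obs$Y_obs[truth$Z == 0L])))
  expect_identical(sum(is.na(obs$Y_obs) & obs$Z == 1L),
                   sum(truth$Z == 1L & truth$R == 0L))
})

test_that("cohort simulation is deterministic under a fixed seed", {
  cfg <- scenario_config()
  a <- simulate_cohort(cfg, -0.51, seed = 33, n = 2000)
  b <- simulate_cohort(cfg, -0.51, seed = 33, n = 2000)
  expect_identical(a, b)
})

test_that("the empirical SACE reproduces hand-computed odds ratios", {
  # AS cells: Y1 positive 20/120, Y0 positive 30/120 -> ln(0.6)
  n <- 120
  df <- data.frame(id = 1:n, V1 = 0L, V2 = 0, U = 0L, D = 0L, A = 1L,
                   Z0 = 1L, Z1 = 1L,
                   stratum = factor(rep("AS", n), levels = c("AS", "CS", "DS", "NS")),
                   Y0 = rep(c(1L, 0L), c(30, 90)), Y1 = rep(c(1L, 0L), c(20, 100)),
                   Z = 1L, R = 1L, Y_obs = NA_integer_)
  expect_equal(empirical_sace(df), log(0.6), tolerance = 1e-12)
  # identical odds -> zero
  df$Y0 <- rep(c(1L, 0L), c(60, 60)); df$Y1 <- rep(c(1L, 0L), c(60, 60))
  expect_equal(empirical_sace(df), 0)
  # zero cell -> degenerate-cohort error
  df$Y1 <- rep(1L, n)
  expect_error(empirical_sace(df), "zero cell")
})

test_that("the empirical tau reproduces hand-enumerated odds and flags degeneracy", {
  fix <- make_fixture("tau-3")
  expect_equal(empirical_tau(fix), 3, tolerance = 1e-12)
  no_cs <- fix[fix$stratum != "CS", ]
  expect_warning(tau <- empirical_tau(no_cs), "undefined")
  expect_true(is.na(tau))
})
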