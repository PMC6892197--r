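---
title: "Estimating the survivor average causal effect with outcomes truncated by death and missing by non-attendance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the survivor average causal effect with outcomes truncated by death and missing by non-attendance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacekit)
```

## The estimand

Cohort studies of ageing-related disease lose outcome information in two
qualitatively different ways. Participants who die before the outcome wave
have no outcome at all — for them the outcome is *undefined*, not missing —
while surviving participants who fail to attend the follow-up visit have an
outcome that exists but is *missing*. Conditioning an analysis on survival
opens a backdoor path whenever some unmeasured characteristic (frailty, a
genotype) predicts both survival and the outcome: survival is a collider
between the exposure and that characteristic, so even an analysis that
adjusts for every measured exposure–outcome confounder can be biased.

The estimand that stays well defined under truncation by death is the
survivor average causal effect (SACE): the effect of the exposure within the
principal stratum of *always-survivors*, the participants who would survive
under either exposure level. Writing $Z_i(a) \in \{0,1\}$ for potential
survival and $Y_i(a)$ for the potential outcome (defined only when
$Z_i(a) = 1$), the principal strata are determined by the pair
$(Z_i(0), Z_i(1))$: always-survivors AS $(1,1)$, compliant-survivors CS
$(0,1)$, defiant-survivors DS $(1,0)$ and never-survivors NS $(0,0)$. On the
odds-ratio scale,

$$\mathrm{SACE}_{OR} =
  \frac{\mathrm{odds}[Y(1) = 1 \mid AS]}{\mathrm{odds}[Y(0) = 1 \mid AS]}.$$

Under the *monotonicity* assumption the exposure never harms survival
($Z_i(0) \le Z_i(1)$), there are no defiant-survivors, and survivors under
low exposure are identifiable as always-survivors; survivors under high
exposure remain a mixture of AS and CS.

## The two estimators

### Weighted marginal structural model

`estimate_msm()` fits three logistic propensity models on the analyst-visible
data: exposure given baseline confounders $\mathbf V$, survival given
exposure and $\mathbf V$, and attendance among survivors given exposure and
$\mathbf V$. Each attending survivor receives the stabilized weight

$$W_i = \frac{SF_{A_i}}
  {\left(A_i p_i + (1 - A_i)(1 - p_i)\right) q_i m_i},$$

where $p_i$, $q_i$, $m_i$ are the fitted exposure, survival and attendance
propensities and $SF_a$ is the average fitted probability of the observed
exposure level within group $a$ (the standard stabilized numerator
$\widehat P(A = A_i)$). Weights are undefined for the dead — they have no
outcome to weight. The final weighted logistic regression of the observed
outcome on exposure and $\mathbf V$ among complete cases yields the exposure
coefficient as the SACE estimate on the log odds-ratio scale. Weighting by
$1/q_i$ lets survivors stand in for comparable participants who died;
weighting by $1/m_i$ does the same for non-attenders. The method is
unbiased when survival is correctly modelled and no *unmeasured*
survival–outcome confounder exists; the simulation harness quantifies what
happens when one does.

Interval estimation uses a bias-corrected nonparametric bootstrap that
resamples baseline participants and refits every model
(`bc_bootstrap_ci()`); a sandwich standard error is reported as a
diagnostic only. Covariate balance before and after weighting is reported as
standardized differences (`standardized_difference()`), the model-free
diagnostic conventionally used for propensity weighting.

### Closed-form sensitivity analysis

The sensitivity estimator (`estimate_sensitivity()`) does not weight.
It models, within each observed exposure arm, the outcome probability of
survivors given covariates (fitted on attenders, valid when missingness is
at random given those covariates) and predicts $h_i(a)$ for *every*
survivor under both exposure levels; a survival model yields each baseline
participant's potential survival probabilities $g_i(a)$. These combine into
the marginal quantities

$$\nu_a = \frac{1}{N}\sum_{i=1}^{N} g_i(a), \qquad
  \xi_a = \frac{1}{n_{Z=1}}\sum_{i \in \text{survivors}} g_i(a)\,h_i(a),$$

the marginal probabilities of surviving, and of surviving with the outcome,
under exposure level $a$. The sensitivity parameter
$\tau = \mathrm{odds}[Y(1)=1 \mid CS] \,/\, \mathrm{odds}[Y(1)=1 \mid AS]$
indexes how much compliant-survivors differ from always-survivors; it is
not identifiable from data, so the estimator is evaluated over a grid
(default $\tau \in \{0.5, 1, 2\}$). For $\tau \ne 1$ the SACE odds ratio has
the closed form implemented in `sace_or()` (a quadratic-root expression in
$\nu_a$, $\xi_a$, $\tau$); at $\tau = 1$ it reduces to
$\xi_1(\nu_0 - \xi_0) / \{\xi_0(\nu_1 - \xi_1)\}$. Values of $\tau$ within
$10^{-8}$ of one are routed to the reduced form to avoid a $0/0$
evaluation; tests verify the two forms agree to $10^{-4}$ at
$\tau = 1 \pm 10^{-4}$ and that the estimate is non-increasing in $\tau$
over the valid domain ($0 < \xi_a < \nu_a \le 1$, $\nu_0 \le \nu_1$).

Two modelling choices here were genuinely open and are worth recording.
First, the averaging population for $\nu_a$: the survival model predicts
$g_i(a)$ for *every* baseline participant, while the composite estimating
equation for $\xi_a$ averages over survivors. A marginal survival
probability refers to the baseline population, so `marginal_quantities()`
averages $g$ over all $N$ by default; a survivors-only switch
(`nu_population = FALSE`) implements the strictly literal composite reading.
The difference is small whenever survival is high. Second, the outcome
models can only be *estimated* on attenders (the only participants with
observed outcomes) even though predictions extend to all survivors; this is
the only feasible choice under missingness-at-random and is stated in the
documentation rather than hidden.

## The cohort simulator

`simulate_cohort()` generates cohorts with full principal-stratum truth so
that estimators can be judged against a known SACE:

1. Covariates: sex $V_1 \sim \mathrm{Bernoulli}(0.5)$, mean-centred age
   $V_2 \sim \mathrm{Uniform}(-10, 10)$ years, an unmeasured
   survival–outcome confounder $U \sim \mathrm{Bernoulli}(0.5)$ (a genotype,
   say) and an unmeasured attendance predictor $D \sim
   \mathrm{Bernoulli}(0.5)$ (area of residence).
2. Exposure $A$ depends on sex and age only (never $U$ or $D$); the default
   coefficients give about half the cohort exposed, with sex and age
   imbalance between exposure groups large enough that unweighted analyses
   are visibly confounded (standardized differences of roughly 0.2).
3. Potential survival uses the linear predictor
   $\mathrm{intercept} + c_A a + c_{sex} V_1 + c_{age} V_2 + \alpha_{UZ} U$.
   With the defaults, survival is about 82% under low exposure and 94%
   under high exposure, so death removes a substantial but not extreme
   slice of the cohort and the compliant-survivor stratum holds roughly
   12–16% of participants. Under `monotonicity = "valid"`, $Z(1)$ is drawn
   first and $Z(0)$ among its survivors with probability $p_0/p_1$ — the
   unique coupling that both guarantees $Z(0) \le Z(1)$ and preserves the
   marginal law $P(Z(0) = 1) = p_0$. Under `"violated"`, $Z(0)$ is drawn
   independently, so defiant-survivors appear.
4. Potential outcomes under each level are generated for the participants
   who would survive that level, from
   $\mathrm{intercept} + \beta_A a + c_{sex} V_1 + c_{age} V_2 + \beta_{UY} U$,
   about 10% prevalence among unexposed survivors (rarer outcomes make the
   arm-level logistic fits fragile at $N = 10{,}000$). One shared uniform
   draw per participant thresholds both potential outcomes: common random
   numbers leave each marginal law untouched while sharply reducing the
   Monte-Carlo variance of within-cohort contrasts such as the empirical
   SACE (the two potential events are nested, so most of the binomial noise
   cancels).
5. Attendance among survivors depends on exposure, sex, age and $D$
   (odds ratio 0.5), about 67% attendance.

The unmeasured confounder's effects $\alpha_{UZ}$ (on survival) and
$\beta_{UY}$ (on the outcome) form the evaluation grid
$\{\ln 0.5, \ln 2\} \times \{\ln 0.5, 0, \ln 2\} \times
\{\text{valid}, \text{violated}\}$ — twelve scenarios
(`scenario_grid()`). When $\beta_{UY} = 0$ there is no survival bias and
$\tau = 1$ in expectation; opposite signs of $\alpha_{UZ}$ and
$\beta_{UY}$ push $\tau$ above one, equal signs below.

The default covariate coefficients were fixed by numerical integration over
the covariate distribution before any estimator was run: they were chosen
so that, in the no-survival-bias scenarios, the population value of $\tau$
is 1.00 (the age effect, acting in opposite directions on survival and
outcome, skews compliant-survivors old; the sex effect, acting in the same
direction in both models, almost exactly offsets it). All coefficients are
ordinary configuration fields and can be overridden.

### Calibration of the true SACE

Because odds ratios are non-collapsible, the conditional exposure
coefficient $\beta_A$ that yields a *marginal* SACE odds ratio of 0.6 among
always-survivors differs between scenarios (the stratum's covariate and $U$
composition depends on $\alpha_{UZ}$, $\beta_{UY}$ and monotonicity).
`calibrate_exposure_coefficient()` therefore solves for $\beta_A$ per
scenario on one large calibration cohort ($10^6$ participants by default)
with all sources of randomness held fixed across iterates. By default the
calibration target replaces the drawn outcomes with their conditional
expectations given covariates inside the always-survivor stratum, which
makes the target a smooth, strictly increasing function of $\beta_A$ solved
by `uniroot()` essentially exactly; the residual error from covariate and
stratum sampling is of order $10^{-4}$ on the log odds-ratio scale. The
drawn-outcome bisection (`smooth = FALSE`, tolerance 0.002) is retained and
tested for agreement. A freshly seeded cohort of $10^6$ participants then
reproduces the target log odds ratio $\ln 0.6 = -0.511$ to within about
one Monte-Carlo standard error (±0.003 with the common-random-number
coupling).

## The Monte-Carlo harness

`run_replicate()` simulates one cohort, records the MSM estimate, the
sensitivity estimates at $\tau \in \{0.5, 1, 2\}$, and the truth-side
empirical SACE and empirical $\tau$ from the known strata and potential
outcomes. `run_scenario()` aggregates replicates into bias (mean estimate
minus $\ln 0.6$), empirical SE (SD of estimates), MSE
($\mathrm{bias}^2 + \mathrm{SE}^2$), standardized bias
($100 \cdot \mathrm{bias}/\mathrm{SE}$) and, when requested, the coverage
of the MSM's bias-corrected bootstrap interval. Replicate seeds derive
deterministically from the scenario's base seed and the replicate index, so
results are reproducible and independent of execution order; failed
replicates are dropped per method and counted, and a scenario with more
than 5% failures is flagged. Coverage is computed for the MSM only by
default, which is how such comparisons are conventionally reported;
`run_scenario(coverage = TRUE)` with the sensitivity estimator's bootstrap
is available but expensive.

Two presets size the study: `"full"` (1200 replicates per scenario,
1000-resample coverage bootstrap) matches the full evaluation; `"desk"`
(300 replicates, no coverage) reproduces the directional findings — the
ordering of sensitivity estimates in $\tau$, under- versus over-estimation
by sign combination of $(\alpha_{UZ}, \beta_{UY})$, and the near-agreement
of the MSM with the $\tau = 1$ sensitivity estimate — in about ten minutes
on one core.

The package's own test suite runs the evaluation at these sizes: the
truth-calibration check over all twelve scenarios at $10^6$ participants,
the null-scenario bias checks at 1200 replicates of $N = 10{,}000$, the
directional properties at 300 replicates, and a reduced coverage study
(200 replicates × 200 resamples) whose coverage is required to sit within
binomial Monte-Carlo error of the nominal 95%.

## What the simulator does and does not emulate

The generator reproduces the structural features that drive survival bias
in ageing cohorts — a roughly balanced binary exposure, high but
exposure-dependent survival, substantial non-attendance among survivors
driven partly by an unmeasured factor, a rare-to-moderate binary outcome,
and an unmeasured shared predictor of survival and outcome. It does not
emulate continuous or time-to-event outcomes, multi-wave attrition,
measurement error in the exposure, effect modification of the exposure by
covariates, or misspecified link functions; passing tests therefore says
nothing about those complications. The logistic survival model fitted by
the estimators is itself mildly misspecified relative to the generator
(marginalizing over the unmeasured $U$ does not preserve the logistic
form), which is deliberate — it is exactly the position an analyst is in.

## Numerical choices

* Logistic fits use the package's own IRLS-with-step-halving Newton core
  (`fit_logistic()`): score convergence at $10^{-8}$, relative deviance
  change at $10^{-10}$, at most 100 iterations, Cholesky solves of the
  dense normal equations. The fit sits inside bootstrap-within-replicate
  loops, so bootstrap refits warm-start at the full-sample coefficients.
  Rank-deficient designs and (quasi-)separation abort with diagnostics
  rather than returning unusable fits. Tests pin the core to `glm` and to
  direct Nelder-Mead likelihood maximization on small fixtures.
* Fitted propensities are defensively clipped to
  $[10^{-12}, 1 - 10^{-12}]$ with a warning if clipping ever triggers;
  weights are never truncated silently (percentile capping is an opt-in
  flag that warns).
* The bias-correction constant of the bootstrap uses midrank tie counting,
  so a degenerate bootstrap distribution yields $z_0 = 0$ rather than
  $\Phi^{-1}(0)$.
* Undefinedness is enforced, not encoded: potential outcomes are `NA`
  exactly where potential survival fails, attendance is `NA` for the dead,
  and the cohort CSV format distinguishes undefined (empty field) from
  missing (literal `NA` token).

## Limitations

Both estimators assume missingness at random given measured covariates and
share the positivity assumption; neither can rescue an analysis in which
attendance depends on the outcome itself. The sensitivity analysis assumes
$\tau$ constant across covariate patterns and, at $\tau = 1$, monotonicity;
eliciting plausible $\tau$ ranges from subject-matter experts is outside
the package's scope. The MSM requires that living participants be adequate
stand-ins for the deceased — a conceptual, not statistical, assumption that
the sensitivity parameter is designed to probe.
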