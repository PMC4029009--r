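---
title: "Modeling longitudinal multirater MTMM data with lscom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling longitudinal multirater MTMM data with lscom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lscom)
```

## The measurement problem

Many multirater studies mix two kinds of measurement methods.  *Structurally
different* methods — a self-report, a parent report — exist once per target
and cannot be swapped for one another.  *Interchangeable* methods are drawn
from a target-specific pool of equivalent raters (several peers rating the
same student), which makes raters a random factor nested in targets and the
data two-level.  When such a design is followed over several occasions, an
adequate measurement model has to combine confirmatory factor analysis,
multilevel modeling, and longitudinal multitrait-multimethod (MTMM) ideas in
one place.  `lscom` implements such a latent-state combination-of-methods
measurement model, together with everything needed to study its statistical
behavior by simulation.

## The model

One structurally different method is declared the *reference method*; its
indicators define occasion-specific latent state factors $S_{jl}$ (construct
$j$, occasion $l$).  All other methods are contrasted against it through
latent residuals:

* indicators of the reference method ($k = 1$) measure only the state
  factor:
  $Y_{tij1l} = \alpha_{ij1l} + \lambda_{Sij1l} S_{tj1l} + \epsilon_{tij1l}$;
* indicators of a structurally different non-reference method add a
  target-level method factor $M$:
  $Y_{tij2l} = \alpha_{ij2l} + \lambda_{Sij2l} S_{tj1l} +
  \lambda_{Mij2l} M_{tj2l} + \epsilon_{tij2l}$;
* indicators of the interchangeable rater set add a target-level *common*
  method factor $CM$ (the shared deviation of the rater pool from the
  reference) and a rater-level *unique* method factor $UM$ (an individual
  rater's deviation from the pool's expectation):
  $Y_{rtij3l} = \alpha_{ij3l} + \lambda_{Sij3l} S_{tj1l} +
  \lambda_{CMij3l} CM_{tj3l} + \lambda_{UMij3l} UM_{rtj3l} +
  \epsilon_{rtij3l}$.

Because the method variables are defined as regression residuals, they have
mean zero and are uncorrelated with the state factors; unique method factors
live at the rater level and are uncorrelated with everything at the target
level; measurement errors are mutually uncorrelated.  These zeros are
*structural*: `correlation_policy()` can restrict the remaining free
covariances (states with states, target-level method factors among
themselves, rater-level method factors among themselves) but can never free
a structural zero.

Each indicator's variance decomposes additively into state, method, and
error components, which yields the familiar coefficients of consistency,
(common/unique) method specificity, and reliability.
`compute_coefficients()` reports them on two scales, because both are useful
and they are easy to confuse: `*_true` coefficients are shares of true
(error-free) variance and obey `con + ms = 1` (structural methods) and
`con + cms + ums = 1` (interchangeable methods), with the rater-consistency
coefficient `rc = con + cms` interpretable as the intraclass correlation of
error-free rater scores; `*_observed` coefficients are shares of total
observed variance, so systematic shares and the error share sum to one and
`consistency + method specificity = reliability`.  Simulation populations
are specified on the observed scale.

## Identification and invariance

Every latent factor is scaled by fixing the loading of its first indicator
to one (for state factors, the reference method's first indicator); factor
variances stay free.  Measurement invariance across occasions is a nested
ladder: `configural` imposes only the factor structure, `weak` equates
loadings over occasions, `strong` additionally equates intercepts, and
`strict` equates residual variances too.  Latent state means are fixed to
zero except under strong/strict invariance, where the first occasion's mean
is fixed to zero and later means are free — they are then the true mean
change relative to occasion one, which is why `latent_state_means()` refuses
configural and weak fits.  Equality constraints are represented as groups
(one estimated parameter per group), not by eliminating parameters, so the
Monte-Carlo type classification can address constrained parameters
uniformly.

## Estimation

`fit_ml()` maximizes the two-level Gaussian likelihood with all information
in the data.  Per target, the between vector (between-only observations
stacked with rater means) contributes through
$V_t = \Sigma_B + \Sigma_W / n_t$, and the rater deviations from their
cluster mean contribute through $\Sigma_W$ with $n_t - 1$ effective degrees
of freedom, including the Jacobian of the mean/deviation transformation so
the value equals the dense per-target multivariate-normal log-likelihood
exactly (the test suite checks this identity to $10^{-8}$ relative on small
instances, including unbalanced rater counts).  Between-only variables are
variables with no within-level existence — they are never padded into
$\Sigma_W$, which keeps the within matrix well conditioned.

The optimizer works on an unconstrained reparameterization: loadings,
intercepts, and latent means enter directly, residual variances on the log
scale, and every free latent covariance block through its log-Cholesky
factor.  Fixed zeros are enforced structurally.  Start values come from a
method-of-moments pass: unit loadings, residuals at half the sample
variances, state variances from the between covariance of the first two
reference indicators (an error-free cross moment), and zero latent
correlations; on non-convergence up to three jittered restarts are tried.
The likelihood and its finite-difference gradient/Hessian are evaluated in
compiled code (one evaluation of the 58-parameter model used below costs
about 40 microseconds), so a full fit takes well under a second.
Convergence is declared when the scaled gradient
$\max_i |g_i| \max(|\theta_i|, 1) / \max(|f|, 1)$ falls below `gtol`
(default $10^{-6}$), or when the optimizer reports success with a
near-stationary gradient; the iteration cap defaults to 1000.  A fit that
starts at a stationary point returns immediately.  Standard errors invert
the numerically differentiated observed information — chosen over expected
information because method variances sit near the boundary in
high-consistency conditions — and are mapped to the natural scale by the
delta method.

The saturated model needed for the $\chi^2$ statistic has a closed-form
maximum under balanced cluster sizes (pooled within scatter over its
degrees of freedom; between scatter over the number of targets).  The
implied unrestricted between matrix $\hat V - \hat\Sigma_W/n$ may be
slightly indefinite in finite samples; the likelihood involves it only
through $\hat V$, so the closed form is still the unrestricted maximum.
With unbalanced clusters the saturated likelihood is maximized numerically
over a log-Cholesky (positive semi-definite) parameterization.  Model fit
is judged by $\chi^2 = 2(\log L_{sat} - \log L)$ against the central
$\chi^2$ with `moment count - free parameters` degrees of freedom; no
level-specific decomposition is attempted.

### Improper solutions

Inadmissible estimates (negative variances, latent correlations beyond one,
non-positive-definite latent covariance matrices) are classical signs of an
underinformative design.  Under the log-Cholesky parameterization a fitted
solution can only reach that region in the limit, so `detect_heywood()`
distinguishes two uses: on raw parameter sets (`boundary = 0`) it flags
literal violations; on fitted models it additionally flags solutions within
a margin of the boundary (default: a latent correlation above $1 - 10^{-3}$
or a relative eigenvalue below $10^{-3}$), which is the operational
analogue of the warnings SEM engines print for such solutions.  These
boundary rates are directional diagnostics — they fall with more raters and
more targets — not calibrated reproductions of any engine's warning counts.

## The simulation populations

`derive_population_params()` turns target variance shares into a population:
all latent variances are one, every indicator's total variance is one,
loadings are square roots of the assigned shares, residual variances absorb
the unreliability.  The two canonical conditions put, per interchangeable
indicator, (consistency, common MS, unique MS, error) at
(.30, .25, .25, .20) for low consistency and (.60, .10, .10, .20) for high
consistency, with structural-method specificity .50/.20 and reliability .80
everywhere.  Indicator heterogeneity comes from equally spaced offsets
($-.025, 0, +.025$ for three indicators) applied to the consistency share
with the error share compensating; the offsets average to zero exactly, so
every across-indicator mean share is preserved and indicator reliabilities
span .775–.825.  The printed spread of the *combined* method-specificity
share cannot be made larger while the shares still sum to one within this
scheme, so means are prioritized over spreads.

Values the study conditions do not pin down were chosen once as package
defaults and are configurable: latent correlations (.5 between states of the
same construct, .3 across constructs and between same-kind method factors
across occasions, .2 for other method-factor pairs — all acceptance
quantities are insensitive to them), intercepts of .5, and a latent state
mean change of .5 at occasions after the first.  Nonzero intercepts and
means matter for the bias harness: a parameter whose true value is zero has
an undefined relative bias and would silently drop its parameter type from
the aggregation.

`simulate_dataset()` draws target-level factors from
$N(\mu, \Phi_B)$, per-rater unique method factors from $N(0, \Phi_W)$, and
independent Gaussian errors at each level — multivariate normal, complete
data, bit-reproducible from the seed.  What the generator does *not*
emulate: non-normal indicators, missingness or rater attrition, unequal
populations across occasions beyond the mean shift, and real raters' serial
dependence.  Tests passing under this generator therefore certify the
estimator and the harness under the model's own assumptions, not robustness
to their violation.

## The Monte-Carlo harness

`run_condition()` simulates and fits one grid cell with per-replication
seeds derived deterministically from `(base seed, condition id, replication
index)`, so runs are a pure function of those inputs, archives are
resumable, and concurrent execution cannot change results.  Replications
that fail to converge are excluded from the bias statistics but counted in
the convergence rate (all conditions exercised in the tests converge in
every replication, so the rule has no numerical effect there).  Free
parameters are classified into twelve types — eight in the between part
(state/common-method/method loadings, Level-2 covariances, latent means,
intercepts, Level-2 variances and residuals) and four in the within part
(unique-method loadings, Level-1 variances, covariances, residuals).  Two
aggregates are reported per type: the mean absolute relative deviation of
the mean estimate from the truth (parameter bias), and the mean absolute
relative deviation of the mean reported standard error from the empirical
standard deviation of the estimates (standard-error bias; SD uses the
$n-1$ denominator).  The conventional acceptability cutoff for both is
10%.

`chisq_calibration()` summarizes test calibration: for each probability on
a grid, the share of replications whose $\chi^2$ falls below the reference
quantile.  Points above the diagonal mean the simulated statistic runs
below its reference distribution, i.e. the test is too liberal — the
direction the model shows in well-specified conditions.

### Problem sizes used in the shipped checks

The package's own evaluation scales the study down to what a single CPU
core handles in minutes; the sizes were fixed when the checks were written.
Parameter bias uses the one-construct, three-method, two-occasion,
three-indicator, low-consistency cell with 500 targets and 10 raters, 100
replications (58 free parameters, so about 86 targets per parameter times
10 raters).  Standard-error bias uses 250 targets and 5 raters with 200
replications — the regime where reported standard errors are claimed to be
accurate with more than two raters per target.  The calibration curve uses
a two-occasion reference+interchangeable model (200 targets, 3 raters, 60
replications), and the improper-solution comparison contrasts the
high-consistency cell at 100 targets / 2 raters against 500 targets / 20
raters.  With two raters and small method variances the information about
the rater-level covariance structure is thin, which is exactly why that
cell shows boundary solutions and the large cell essentially none.

## Numerical choices, degenerate inputs, limitations

* A design with only the reference method degenerates to an ordinary
  latent state model (no method factors, single-level likelihood); the
  template builder and estimator handle it as such.
* Choosing the interchangeable set as the reference method is a different
  model (the state factors would live at the rater level) and is rejected
  with an explicit error rather than approximated.
* Singular implied covariances during optimization return a large penalized
  objective instead of raising, so line searches retreat; `loglikelihood()`
  returns `-Inf` with a `singular` attribute.
* Fewer targets than free parameters triggers a warning (and
  `run_condition()` refuses such cells, reporting the count); the
  enumeration of the full factorial marks them infeasible.  Exactly which
  cells a given engine would drop depends on its counting of free
  covariances, which published exclusion totals do not fully determine;
  the package documents its own counting rule and treats published totals
  as approximate calibration.
* Equality groups combined with the block-Cholesky covariance
  parameterization cannot express fixed *nonzero* covariances or partially
  free blocks; both are rejected with clear errors.
* Robust (sandwich) standard errors, missing-data handling, Bayesian
  estimation, fit indices beyond $\chi^2$, and level-specific difference
  tests are out of scope.

## A worked example

```{r example, eval = FALSE}
design <- design_spec(
  n_indicators = 3, n_constructs = 1,
  methods = c("reference_structural", "nonreference_structural",
              "interchangeable_set"),
  n_occasions = 2, n_targets = 500, n_raters = 10)

pop <- derive_population_params(population_targets("low"), design)
round(colMeans(compute_coefficients(pop)[
  compute_coefficients(pop)$role == "interchangeable_set",
  c("con_observed", "cms_observed", "ums_observed", "rel")]), 3)

dat <- simulate_dataset(pop, design, seed = 42)
fit <- fit_ml(build_template(design, mi = "strong"), data = dat)
fit
latent_state_means(fit)
```

The `README` shows this example with the numbers it prints; the acceptance
script under `scripts/` recomputes the population shares and the two bias
aggregates from scratch.
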