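---
title: "Growth models, predictions and monitoring intervals: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth models, predictions and monitoring intervals: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aaamonitor)
```

This vignette is the package's account of its statistical machinery: the
hierarchical growth models and their samplers, the individual-level
prediction semantics, the planning and validation procedures, the design
of the synthetic cohort generator, and the numerical conventions and
their rationale.  It states no empirical results beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## 1. The models

Repeated aneurysm diameters `y_ij` (mm) for subject `i` at times `t_ij`
(years since that subject's first screen) follow a mixed-effects growth
curve.  The base linear model is

    y_ij = (beta0 + b0_i) + (beta1 + b1_i) t_ij + w_ij' gamma + eps_ij

with `eps_ij ~ N(0, sigma_w^2)` and `b_i = (b0_i, b1_i)' ~ N(0, Sigma)`,
where `Sigma` has SDs `sigma0`, `sigma1` and correlation `rho01`.  The
covariate row `w_ij = (z_i, t_ij z_i)` lets each baseline covariate
shift both the intercept and the slope.  Variants:

* **quadratic trend** — adds `(beta2 + b2_i) t_ij^2`; `Sigma` becomes
  3x3 and covariates may also act on the curvature;
* **Student-t errors** — `eps_ij = sigma_w T_nu` with `nu` estimated;
  appropriate when residuals are heavier-tailed than Gaussian, as
  repeated ultrasound measurements typically are;
* **independent intercepts** — each subject's intercept `alpha_i` is a
  free parameter with a `U(0, 1000)` prior (no shrinkage, no
  distributional assumption on the skewed baseline diameters), and
  slopes are Gaussian *conditionally on* the intercepts:
  `b1_i | alpha_i ~ N(lambda (alpha_i - mean(alpha)), sigma_c^2)` with
  `lambda ~ U(-5, 5)`.  Centring at the running empirical mean of the
  intercepts keeps `E[b1_i] = 0`; the mean is treated as fixed within
  each conditional update, an `O(1/n)` approximation.
* **left-censoring** — screening records known only to satisfy
  `y < 30` mm contribute `log Phi((30 - mu_ij)/sigma_w)` to the
  likelihood, which moves inference from "men with a detected aneurysm"
  to the general screened population.

Assumptions worth keeping in view: measurement errors are independent
across visits given the curve; random effects are Gaussian (except where
the independent-intercept or censored variants relax this); dropout
depends only on *observed* diameters (surgery referral, loss after
sub-30 readings), which is ignorable under likelihood-based inference.

### Priors

Fixed effects get independent `N(0, 1000^2)` priors; `sigma_w^2` an
`IG(0.001, 0.001)`; `Sigma` an inverse Wishart with `1 + dim(Sigma)`
degrees of freedom — the choice that makes each implied correlation
marginally uniform — and, by default, an identity scale matrix.  The
scale matrix is configurable (`prior_spec(wishart_scale = ...)`) because
no canonical value exists at this vagueness level; at the cohort sizes
the package targets (hundreds to a thousand subjects) its influence is
negligible, and the identity keeps the prior proper without favouring
any correlation sign.  `nu` has a `U(2, 1000)` prior (below 2 the error
variance is infinite; 1000 is indistinguishable from Gaussian).

## 2. The sampler

`fit_growth()` runs a bespoke blocked Gibbs sampler rather than a
generic probabilistic-programming backend, so that every conditional is
a closed form that can be unit-tested in isolation:

1. fixed effects `(beta, gamma)` jointly from their conjugate
   multivariate normal;
2. each `b_i` from its conjugate normal — vectorised across subjects via
   closed-form 2x2/3x3 inversions and Cholesky factors, so no R-level
   loop over subjects occurs;
3. `sigma_w^2` from its inverse gamma;
4. `Sigma` from its inverse Wishart (via `stats::rWishart` on the
   precision);
5. a **translation move**: because the likelihood depends on `beta` and
   `b` only through `beta + b_i`, the shift `delta` with
   `beta <- beta + delta`, `b_i <- b_i - delta` has a conjugate normal
   conditional (precision `n Sigma^{-1} + I/tau^2`).  Sampling it each
   sweep removes the slow random walk between the fixed-effect and
   random-effect blocks that otherwise dominates the autocorrelation
   time of `beta` in centred parameterisations;
6. for t errors, per-observation gamma scale-mixture weights, with `nu`
   updated by a gridded Gibbs step: the conditional is evaluated on a
   400-point log-spaced grid over (2, 1000) from the sufficient
   statistics `(sum log w, sum w)`, a cell is sampled, and the draw is
   jittered uniformly within the cell to keep `nu` continuous.  The grid
   spacing near `nu = 4` is about 0.06, an order of magnitude below the
   posterior SD at the cohort sizes used;
7. for censoring, each censored record's latent diameter is imputed from
   its upper-truncated normal conditional (inverse-CDF in log space, so
   the far tail stays finite);
8. the independent-intercept model updates `alpha_i` (truncated normal),
   `b1_i`, `beta1`, `lambda` (truncated normal), `sigma_c^2` and
   `sigma_w^2`, plus the analogous slope translation move.

Defaults are 2 chains of 2,000 iterations with 500 burn-in; the
protocol the models were originally developed under used 2 x 10,000,
and both are one argument away.  Every stochastic step descends from the
single `seed`, so fits are bit-reproducible.

### Diagnostics

`rhat()` implements the split-chain Gelman–Rubin statistic: each chain
is halved and `sqrt(((N-1)/N W + B/N)/W)` computed across the halves,
which also detects within-chain drift.  The package's working threshold
is 1.05.  Note that any between/within estimator returns
`sqrt((N-1)/N)`, not exactly 1, for literally identical chains.

`dic()` uses the *conditional* focus: the deviance is
`-2 log p(y | theta, b)`, `p_D = Dbar - D(posterior means of theta and
b)`, and `DIC = Dbar + p_D`.  With subject-level prediction as the goal
the random effects are part of the focus, and `p_D` is accordingly of
the order of the number of subjects.  Censored records contribute their
CDF terms to the deviance on both sides of the subtraction.

## 3. Individual prediction under cut semantics

Predictions for a (possibly new) individual condition on that
individual's measurements without letting them update the population
posterior: for each stored population draw `theta_k`, one draw of `b_i`
is taken from `p(b_i | y_i, t_i, theta_k)`.  Under Gaussian errors this
conditional is exactly multivariate normal, so the cut is realised
without approximation; under t errors a 5-step inner Gibbs run on the
scale-mixture weights is used per population draw, keeping the final
state (the conditional is low-dimensional and mixes essentially
immediately; the inner length is configurable).  For the
independent-intercept model the new individual's intercept has a flat
prior and the slope its conditional-Gaussian model, which again yields a
closed-form bivariate normal.  In-sample subjects can instead reuse
their stored random-effect draws (`subject_id =` argument).

All prediction quantities derive from the per-draw curve coefficients
`(A, B, C)` (level `A + B u + C u^2` at time `u`):

* **growth rate** `G = B + 2 C t`;
* **time to threshold** `W`, on the extended non-negative line:
  `W = 0` when the underlying level at `t` already meets the threshold
  `alpha`; for a linear draw `W = (alpha - level(t))/B` if `B > 0`, else
  infinity; for a quadratic draw the smallest root of
  `level(u) = alpha` exceeding `t`, or infinity if no real root exceeds
  `t`.  Roots use the cancellation-stable quadratic formula
  (`q = -(B + sign(B) sqrt(disc))/2`), draws with `|C| < 1e-12` fall
  back to the linear rule (curvature draws near zero are common), and
  the `B = 0` branch is handled explicitly.  Summaries on the extended
  line use inverse-ECDF (type-1) quantiles with infinity ordered above
  all reals — so the reported median is a draw, never an interpolation
  between a finite value and infinity — alongside the probability
  masses at 0 and at infinity.  The mean is deliberately not reported:
  it is undefined whenever `P(W = Inf) > 0`;
* **posterior predictive measurement** at `t + s`: the underlying level
  plus a fresh error draw from the fitted family (or the error-free
  level, on request);
* **exceedance probability** `P{Y(t+s) >= alpha}`: Rao–Blackwellised,
  i.e. the closed-form tail probability of the error family around the
  underlying level, averaged over draws.  This has strictly smaller
  Monte Carlo variance than averaging indicator draws and makes the
  planner's objective a smooth, deterministic function of the stored
  draws.

## 4. Planning and validation

`recommend_interval()` finds the largest wait on a grid over
`[0, max_horizon]` (default step 0.25 years) whose exceedance
probability is within the risk limit, then bisects to a tolerance of a
tenth of the grid step.  Because the Rao–Blackwellised probability is
deterministic given the draw set, the bisection is exact, and the
returned interval's probability (also returned) never exceeds the limit.
When even `s = 0` breaches the limit — large baselines, where
measurement error alone can push an observed value over the threshold —
the recommendation is 0 with an `already_exceeded` flag.  The criterion
uses the *observed* (error-inclusive) predictive by default, since
programmes act on measured diameters; an underlying-level variant is a
flag.

`validate_predictions()` checks calibration the way a programme would
use the model: cut posteriors from each subject's first `k` scans give
predicted probabilities of exceeding the threshold at years 1–5, and
their mean over subjects is compared with a multiply-imputed comparator
— the observed scan nearest each year when one lies within half a year
(ties to the earlier scan), otherwise a draw from the subject's
all-data posterior predictive.  Imputation is what makes the comparison
fair: subjects whose diameters grow are removed by surgery, so late
observed samples alone are biased downward.  The number of imputations
defaults to 100 (subsampled from the retained draws; the original
analyses used every draw).

## 5. The synthetic cohort generator

The generator emulates the structure of a national screening cohort:

* baseline diameters on 30–54 mm, either from the model's Gaussian
  random intercept or from a right-skewed shifted-gamma law (shape 0.56,
  scale 35.8, truncated to [30, 55); mean 37.5 mm, SD 7.0 mm) mirroring
  the skewed histogram seen at first screen;
* rescan intervals by diameter band — 1 year below 45 mm, 3 months at
  45–54 mm — with Gaussian appointment jitter (SD 0.08 yr, ~1 month)
  and 82% attendance; a missed appointment is skipped, not rescheduled;
* termination by the first of: surgery referral (observed value at or
  over 55 mm, or an observed increase of 10 mm or more between scans at
  most 1.25 years apart), death, loss to follow-up, or an 11-year
  administrative horizon.  A referral leads to surgery with probability
  0.7; otherwise the patient is permanently "unsuitable" and
  surveillance continues, as happens in practice.  Death and loss are
  independent exponential hazards (0.045 and 0.065 per year).

The hazard, attendance and referral values are calibrated defaults,
chosen once so that the default configuration reproduces the reported
descriptive statistics of the emulated study (about 8.5 scans per
person, follow-up near 5 years, and termination shares of roughly
36% surgery / 21% death / 26% loss / 17% administrative); the study
reports these proportions but not the underlying mechanisms, so the
mechanisms here are the package's own.  The test suite checks the
calibration bands, not the exact values.

**Entry filtering.**  Three modes are provided.  `"observed"` (default)
redraws any subject whose observed first scan falls outside [30, 55),
reproducing the cohort's inclusion rule — note this truncates the
realised random-intercept distribution, so a model refitted to such a
cohort will *correctly* estimate a smaller `sigma0` than the generating
value.  `"none"` keeps every subject: this is the mode for
parameter-recovery experiments, where the point is to simulate exactly
from the model being fitted.  `"censor"` emits sub-30 mm first screens
as left-censored records (and can add a whole sub-threshold screening
population via `censor_population_n`), feeding the censored-likelihood
model.  Per-subject RNG substreams make cohorts reproducible and
prefix-stable in `n_subjects`.

What the generator does **not** emulate: calendar-time effects and
staggered entry; scan-quality or reader variation beyond i.i.d. error;
informative dropout beyond the observed-value mechanisms above;
mortality related to diameter.  Passing recovery tests on these cohorts
therefore demonstrates the correctness of the samplers and prediction
machinery under the stated model, not robustness to real-data
violations of it.

## 6. Numerical choices and degenerate inputs

* Truncated-normal draws use inverse-CDF sampling in log space, stable
  for bounds many SDs from the mean.
* Batched 2x2/3x3 precision inversions guard Cholesky pivots with a
  floor of `1e-300`; the inverse-Wishart keeps `Sigma` draws positive
  definite by construction, and degenerate (zero-variance) truths are
  accepted by the generator for noise-free tests.
* Subjects with a single measurement are admitted everywhere —
  predicting from one baseline scan is a core use case; their slope
  effects are identified by the population prior (shrinkage does the
  work).  Subjects whose measurements share a single time point are
  likewise allowed.
* Diameter values are floored at 0.5 mm in the generator (a diameter
  cannot be negative; the event is vanishingly rare under realistic
  truths).
* Comparator scans tied in distance to a validation year resolve to the
  earlier scan.
* The time-to-threshold quantile convention (type-1, infinity ordered
  last) is the only place the package must take a stand on how infinite
  mass enters point summaries; medians are finite exactly when
  `P(W < Inf) > 1/2`.

## 7. Problem sizes

The acceptance computations simulate 1,000-subject cohorts (about
7,500–8,500 measurements) and fit 2 chains of 2,000 iterations — sizes
chosen so that posterior uncertainty, not Monte Carlo error, dominates
the recovery comparisons, while a full recovery study (three models,
plus planning, validation and oracle suites) completes in a few minutes
on a single CPU.  The reduced simulation-based-calibration check uses
100 replicate fits of 30-subject cohorts.  Validation calibration uses a
500-subject self-consistent cohort.

## 8. Known limitations

* The censored-population model is implemented for Gaussian errors and
  the linear trend; the original analyses additionally explored
  t-distributed intercepts under censoring and found inference highly
  sensitive to that choice — a caution that carries over here.
* The independent-intercept model supports no covariates (matching how
  it was originally specified) and its `alpha`-centring approximation,
  while negligible at hundreds of subjects, is not exact.
* DIC is reported under the conditional focus only; marginal-focus DIC
  would require integrating over `b_i` and answers a different
  (population-level) question.
* The planner treats the fitted model as true; no allowance is made for
  model uncertainty across the linear/quadratic/t variants beyond
  comparing their policies.
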