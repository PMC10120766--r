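---
title: "Sigmoidal and random-changepoint mixed models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sigmoidal and random-changepoint mixed models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(trajmix)
```

## The models

trajmix fits nonlinear mixed-effects models of the form

$$ y_{ij} = f(t_{ij}, \psi_i) + \varepsilon_{ij}, \qquad
   \varepsilon_{ij} \sim N(0, \sigma_\varepsilon^2), $$

for a continuous longitudinal outcome $y_{ij}$ of subject $i$ at time
$t_{ij}$, where $\psi_i$ is a vector of four interpretable structural
parameters built from population means $\alpha_k$, covariate effects
$\beta_k$ and Gaussian subject-level random effects $\eta_{ki}$:

$$ \psi_{ki} = \alpha_k + \beta_k^\top X_{ki} + \eta_{ki}. $$

The motivating application is terminal decline: cognition measured on a
retrospective timescale with death at time zero and negative times before it.
Three structural functions are available.

**Model 1 — sigmoidal mixed model (SMM).** A four-parameter logistic on the
positive time-before-zero scale $s = \text{shift} - t$ (for purely negative
times, $s = -t$; with mixed-sign times the shift that makes $\min s = 0$ is
applied and reported):

$$ f(s, \psi_i) = \psi_{2i} + \frac{\psi_{1i} - \psi_{2i}}{1 + (s/\psi_3)^{\psi_4}}, $$

with $\psi_1$ the *last level* (value at $s = 0$, e.g. at death), $\psi_2$
the *first level* (asymptote long before), $\psi_3 > 0$ the *midpoint* (time
before zero at which half the decline has occurred — always reported
positive) and $\psi_4$ the *Hill slope* governing the steepness of the
transition. Random effects act on the two levels only; midpoint and Hill
slope are kept marginal for convergence, so the random-effect covariance $B$
is an unstructured $2 \times 2$ matrix.

**Model 2 — piecewise mixed model with abrupt changepoint (PMM-abrupt).**
Two straight lines joined at a subject-specific changepoint $\psi_{4i}$:

$$ f(t, \psi_i) = \begin{cases}
 \psi_{1i} + \psi_{3i} t, & t \ge \psi_{4i}, \\
 \psi_{1i} + \psi_{3i}\psi_{4i} + \psi_{2i}(t - \psi_{4i}), & t < \psi_{4i},
\end{cases} $$

with $\psi_1$ the level at time zero (the intercept/last level), $\psi_2$
(*slope1*) the slope of the phase away from time zero (pre-changepoint when
times are negative), $\psi_3$ (*slope2*) the slope of the phase adjacent to
time zero (terminal decline), and $\psi_4$ the changepoint. All four
parameters carry random effects; $B$ is diagonal apart from the
slope1–slope2 covariance. A note on naming: in the literature on this model
the symbols attached to the two slopes are not used consistently between the
defining equations and the descriptive text, so this package names them by
what they do — slope1 is always the slope *before* the changepoint, slope2
the slope *between the changepoint and time zero* — and all tables, `start`
vectors and simulation truths follow that convention.

**Model 3 — smooth piecewise model (PMM-smooth).** The abrupt kink is
replaced by a cubic polynomial on the window
$[\psi_{4i}, \psi_{4i} + v]$, so $\psi_4$ is the *onset* of the transition.
The cubic is the unique solution of four linear constraints: it matches the
value and slope of the entering line at the start of the window and of the
exiting line at its end. So that the intercept stays directly interpretable,
the exiting phase passes through $(0, \psi_{1i})$, and the entering line is
positioned by the constraint
$\lambda_i = \psi_{1i} + (\psi_{3i} - \psi_{2i})(\psi_{4i} + v/2)$, which
makes the two extended lines intersect at the middle of the window. Setting
$v = 0$ recovers the abrupt model exactly; the resulting trajectory is
globally $C^1$. One identity worth recording: the *lines* cross at
$\psi_4 + v/2$, but the cubic itself passes
$v(\psi_3 - \psi_2)/8$ away from that crossing — the two coincide only when
the slopes are equal.

`transition_cubic()` exposes the coefficients by solving the explicit
$4 \times 4$ linear system in the monomial basis; the vectorised evaluator
used inside the estimation loop uses the algebraically identical Hermite
form, and the test suite pins the two against each other (and against an
independent solve) to $10^{-8}$ or better.

The default window length is $v = 2$ in the units of the time variable
(two years on an annual decedent timescale), user-settable; it is a
modelling choice, not an estimated quantity.

## Estimation: SAEM

The marginal likelihood integrates over the random effects and has no closed
form, so estimation uses a Stochastic Approximation EM algorithm:

1. **Simulation step.** For each subject, the random-effect vector
   $\eta_i$ is updated by Metropolis–Hastings targeting
   $p(\eta_i \mid y_i; \theta)$, with three kernels per sweep: an
   independent draw from the prior $N(0, B)$, a componentwise random walk,
   and a joint random walk along the prior Cholesky factor. Random-walk
   scales adapt toward an acceptance rate of 0.35 during burn-in only, so
   the transition kernel is fixed during the averaging phase. Two sweeps per
   iteration are used by default; with fewer than 50 subjects the chain is
   replicated (`ceiling(50/N)` chains) and the statistics averaged.
2. **Stochastic approximation.** Complete-data sufficient statistics
   (per-subject first moments of the simulated parameters, their second
   moments, and the residual sum of squares) are averaged with step
   $\gamma_k = 1$ for the first $K_1$ iterations and
   $\gamma_k = (k - K_1)^{-a}$, $a = 1$, for the $K_2$ averaging iterations.
3. **Maximisation step.** Fixed effects of parameters with random effects
   have a closed-form generalised-least-squares update; $B$ is a moment
   update restricted to the model's sparsity mask (with covariances clamped
   to $|\rho| \le 0.99$ and variances floored at $10^{-12}$); $\sigma^2$ is
   the averaged residual mean square (floored at $10^{-10}$). Parameters
   without random effects (SMM midpoint and Hill slope, and covariate
   effects on them) are updated by a damped Nelder–Mead step on the
   complete-data criterion at the current draws.

For the piecewise models the population changepoint is additionally kept
inside the observed time range during the M-step. This implements the
structural requirement that the changepoint be interior to the data and, in
practice, prevents a known degeneracy of random-changepoint likelihoods:
when the changepoint variance is large there is a flat ridge in which all
subject changepoints are pushed outside the observation window and one slope
becomes unidentified.

**Iteration defaults ($K_1 = 600$, $K_2 = 800$, 2 sweeps).** These were
chosen by comparing the attained marginal log-likelihood against long
reference runs (thousands of iterations) on simulated sigmoid and
broken-stick scenarios, including a deliberately hard one with a changepoint
random-effect SD near 7 years. Short burn-ins freeze the averaging before
the slowly mixing changepoint components reach the neighbourhood of the
maximum; the defaults bring the remaining gap to a level that does not move
the fixed-effect estimates by more than a fraction of their sampling error,
at a few seconds per fit for a few hundred subjects. The averaging phase is long enough that the terminal Robbins-Monro step keeps per-iteration parameter fluctuations an order below the convergence tolerance even for weakly informed variance components. An optional
simulated-annealing floor on variance shrinkage during burn-in
(`saem_control(anneal = )`) is provided but off by default: on these
scenarios it measurably worsened the attained likelihood.

**Convergence diagnostic.** A fit is flagged converged when the largest
per-iteration parameter change over the trailing 50 averaging iterations is
below `tol = 1e-3` on a parameter-aware, dimensionally matched relative
scale: outcome-dimension mean parameters against
$\max(|\hat\theta_j|, 0.1\,\mathrm{sd}(y))$; time-dimension mean parameters
(the changepoint and its covariate effects) against
$\max(|\hat\theta_j|, 0.1\,T)$ with $T$ the observed time span; and
variance-type parameters (variances, masked covariances, $\sigma^2$) against
$\max(|\hat\theta_j|, (0.1\,\mathrm{sd}(y))^2)$ — one rule per dimension. The floors make the diagnostic measure stability *at the scale of
the data*: a variance component estimated at $10^{-4}$ on an outcome with
variance 2 may fluctuate by a relative $10^{-3}$ of itself without any
scientific consequence, while genuine non-convergence (drifting means,
wandering changepoint) is still caught. Both the tolerance and the window
are user-settable.

## Standard errors, tests and likelihood

Standard errors use a Louis-type decomposition of the observed information:
$I(\hat\theta) = -\mathbb{E}[H_c \mid y] - \mathbb{E}[s_c s_c^\top \mid y]
+ \sum_i \mathbb{E}[s_i \mid y]\,\mathbb{E}[s_i \mid y]^\top$, with
conditional expectations accumulated by the same stochastic averaging over
the SA phase. The complete-data log-likelihood separates into a Gaussian
random-effect block (exactly quadratic in the simulated effects, so its
expected Hessian is an explicit function of the accumulated moments) and a
residual block (whose Hessian with respect to the marginal SMM parameters is
taken at the accumulated conditional means — a plug-in step that matters
only for the midpoint/Hill-slope SEs). Wald p-values
$2\{1 - \Phi(|\hat\theta|/\mathrm{SE})\}$ are reported for *all* fixed
effects — the four main parameters as well as every covariate effect — and
CV% $= 100\,\mathrm{SE}/|\hat\theta|$ accompanies each variance-table entry.
On a linear mixed model special case (random intercept and slope), the SAEM
estimates and SEs agree with closed-form maximum likelihood to well within
the tolerances asserted in the test suite.

The marginal log-likelihood is estimated by importance sampling with a
per-subject Gaussian proposal centred at the conditional mode with the
curvature at the mode (prior fallback when the curvature is degenerate);
AIC uses $-2\ell + 2p$ and BIC $-2\ell + p\log N$ with $p$ counting all
fixed effects, the free entries of $B$, and $\sigma^2$, and $N$ the number
of subjects. The estimator returns its Monte Carlo standard error; when all
random-effect variances are numerically zero the closed-form residual
likelihood is returned instead.

## Automated initial values

With user `start` values absent, the four starting values are derived from
the data. For the SMM, the last- and first-level starts are mean outcomes
over the observations whose time percentile rank lies within ±2.5 points of
the 95th and 5th percentiles (a band is needed — a point percentile has
measure zero; the half-width is a package convention). The midpoint start is
300 when the pooled trajectory is nearly linear and 2 otherwise; "nearly
linear" means pooled OLS $R^2 \ge 0.99$ *or* the mid-band mean within 5% of
the outcome range from the linear interpolation of the extreme band means
(the published heuristic names the rule but no threshold; both are
documented and overridable). The Hill-slope start is whichever of the
candidate pair {0.5, 1.05} gives the lower pooled residual sum of squares,
1.05 on ties.

For the piecewise models, the intercept start is the 95th-percentile band
mean; the time axis is cut at its 20/40/60/80th percentiles, a within-subject-centered
least-squares trend (the fixed-effects slope: time and outcome demeaned
within subject before pooling) is fitted in each band, and the changepoint
start is the lower bound of the band with the steepest absolute slope.
Within-subject centering matters: with realistic between-subject level
heterogeneity, raw pooled band slopes are dominated by who happens to be
observed in the band rather than by how individuals change, and can hand
the changepoint start to an arbitrary band. When several bands tie for the
steepest slope the *earliest* tied band wins: the changepoint is the onset
of the fast phase, and for exactly two-phase data the later of the tied
bands would sit entirely inside the fast phase. For fully linear data (all
bands tied) the start is clamped to 5% above the earliest observed time so
it stays strictly interior. The two slope starts are within-subject-centered
slopes on either side of the approximate changepoint. This estimator is
used instead of per-band random-effects fits deliberately: it extracts the
same slope information a random-intercept model would, without five
auxiliary mixed-model fits.

Variance starts are method-of-moments flavoured: with $V$ the variance of
the residuals from the structural curve at the starting values, level-type
random effects start at $0.5V$, slope-type at $0.1V/(\text{half
range})^2$, the changepoint variance at $(0.25 \times \text{time range})^2$,
and $\sigma^2$ at $0.25V$. These only need the right order of magnitude;
the changepoint start is intentionally generous because underestimating it
freezes the changepoint chains early.

## The simulator

`sim_scenario()`/`simulate_longdata()` generate decedent-style data:
follow-up spans drawn $N(10, 5^2)$ years truncated to $[4, 24]$ by
regeneration (regeneration rather than clipping keeps the span distribution
smooth), annual visits from minus the span to zero jittered uniformly by up
to ±2 months, at least 4 visits per subject, and outcomes from the sigmoid
or broken-stick structure with Gaussian random effects and residual noise.
The default truths are: sigmoid — last level −1.03, first level 0.37,
midpoint 4.0 (positive scale), Hill slope 1.69, level SDs 1.46 and 0.51
(uncorrelated), σ = 0.28; broken-stick — last level −1.21, slope1 −0.03,
slope2 −0.32, changepoint −3, random-effect SDs 1.70, 0.01, 0.05 and 6.91
with slope1–slope2 correlation −0.07, σ = 0.28. Where a variance and an SD
are both conventional for a quantity the SDs are taken as defining, since
they enter the covariance directly. Optional covariates are standard normal,
subject-constant, with effect 0.1 on every parameter — a documented free
choice. `example_dataset()` builds the package's 1200-subject demonstration
cohort (mean follow-up 7, SD 5, minimum 4 visits, age at death
$N(90, 6^2)$ truncated to [65, 108] with small negative effects on the last
level and the changepoint); it is synthetic and labelled as such.

What the simulator emulates — and what it does not: visit schedules and
trajectory shapes of a decedent cohort with Gaussian heterogeneity and
homoscedastic Gaussian noise. Real cognitive data add features the
generator omits: informative dropout and mortality selection, floor/ceiling
effects and skewed measurement error, retest (practice) effects, and
time-varying covariates. Passing the package's recovery tests therefore
demonstrates correctness of the estimator under the stated model, not
robustness to those violations.

## Problem sizes used in validation

The bundled validation (test suite and `scripts/acceptance.R`) replicates
the simulation design at 20 datasets per model with n = 100 subjects for
the convergence-rate and trajectory-MSE checks, and 20 replicates at
n = 200 for parameter recovery; simulator moment checks use n = 5000.
These sizes give Monte Carlo error small enough for three-standard-error
comparisons while keeping a full run in the tens of minutes on one core.

## Known limitations

* Parameters enter linearly in covariates; no transformations or
  interactions are generated internally.
* Residuals are homoscedastic Gaussian without autocorrelation; no
  alternative residual models.
* The smooth window length $v$ is fixed, not estimated.
* The marginal log-likelihood is a Monte Carlo estimate; comparisons of
  models whose AIC differs by less than a few Monte Carlo SEs are not
  meaningful.
* Wald inference for variance components near zero is unreliable (as in any
  mixed model); the CV% column flags such entries with large values.
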