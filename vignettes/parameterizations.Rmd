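---
title: "Identification parameterizations for ordinal panel SEMs"
author: "ordalt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identification parameterizations for ordinal panel SEMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordalt)
```

## The model

An observed ordinal response $y_{it}$ with categories $0,\dots,C-1$ at
occasion $t$ is treated as a discretized normal latent response
$y^*_{it}$: $y_{it} = c$ exactly when
$\tau_{c,t} < y^*_{it} \le \tau_{c+1,t}$, with $\tau_0 = -\infty$ and
$\tau_C = +\infty$.  Because only ordinal information is observed, the
mean and variance of $y^*_t$ are not identified jointly with the
thresholds; some scaling constraint must be chosen, and with repeated
measures the choice matters.  `ordalt` implements the three families of
constraints used in practice:

* **standard** — $\mu^*_t = 0$, $\mathrm{sd}(y^*_t) = 1$ at every
  occasion; thresholds free and time-specific.  `placement` decides
  whether the unit-variance constraint sits on the latent responses
  ("delta") or on the structural errors ("theta").
* **alternative 1** (occasion-one anchoring) — $\mu^*_1 = 0$,
  $\mathrm{sd}(y^*_1) = 1$; later means and variances free; at least two
  thresholds time-invariant, or all of them under the `_inv` variants.
* **alternative 2** (threshold anchoring) — $\tau_{1,t} = 0$,
  $\tau_{2,t} = 1$ at every occasion; all latent means and variances
  free.  Needs $C \ge 3$; binary variables instead use the
  fixed-zero-threshold binary row.

Binary variables pair with the alternative-1 family through either the
means-free row (`binary_alt1 = "myt"`, variances all one) or the
variances-free row (`"mm"`, means all zero).

On top of the measurement layer sit four structural families for the
latent responses: the linear growth model
($y^*_t = \alpha + (t-1)\beta + \varepsilon_t$), the first-order
autoregressive model ($y^*_t = \nu_t + \rho_t y^*_{t-1} +
\varepsilon_t$ with $y^*_1$ predetermined), their combination the
autoregressive latent trajectory (ALT) model
($y^*_t = \rho_t y^*_{t-1} + \alpha + (t-1)\beta + \varepsilon_t$,
$t \ge 2$), and a multivariate ALT with lag-one cross-lagged paths and
same-occasion (concomitant) error covariances.  The first latent
response is always treated as predetermined: it enters through a free
mean, variance and covariances with the growth factors rather than
through an outcome equation (the endogenous-initial-condition variant is
covariance-equivalent and is not implemented separately).

## Estimation

Estimation is the usual two-stage WLSMV scheme.  Stage 1 estimates
thresholds as standard-normal percentiles of the cumulative margins and
each polychoric correlation by maximizing the Olsson likelihood of the
bivariate table with thresholds held fixed (a pseudo maximum likelihood
step; 1-D search on the Fisher-z scale, tolerance `1e-8`, cell
probabilities floored at `1e-12` inside the log-likelihood only, no cell
smoothing — degenerate tables are flagged, never patched).  Stage 2
minimizes the diagonally weighted least squares discrepancy
$F(\theta) = (s - \sigma(\theta))' W^{-1} (s - \sigma(\theta))$, with
$W = \mathrm{diag}(\Gamma)$ and $\Gamma$ the asymptotic covariance of
the stacked statistics.  Standard errors use the full sandwich
$(\Delta'W^{-1}\Delta)^{-1}\Delta'W^{-1}\Gamma W^{-1}\Delta(\Delta'W^{-1}\Delta)^{-1}$,
and the test statistic is the second-order (mean-and-variance,
Satterthwaite-type) adjustment: with
$U = W^{-1} - W^{-1}\Delta(\Delta'W^{-1}\Delta)^{-1}\Delta'W^{-1}$ and
$M = U\Gamma$, the statistic $F\,\mathrm{tr}(M)/\mathrm{tr}(M^2)$ is
referred to a chi-square with
$\mathrm{tr}(M)^2/\mathrm{tr}(M^2)$ degrees of freedom.  Mplus versions
differ in whether they adjust one or two moments; we implement the
two-moment version and report both the integer model df and the
fractional effective df.

A design point worth spelling out: whatever the parameterization, the
fitted statistics vector is always expressed in the *standard metric* —
standardized thresholds $(\tau_{c,t} - \mu^*_t)/\mathrm{sd}(y^*_t)$
followed by latent-response correlations.  Every specification implies
this same vector through its own parameters.  This keeps chi-squares of
different parameterizations fitted to one panel exactly comparable, and
it is what makes the equivalence results below sharp rather than
approximate.

### The asymptotic covariance $\Gamma$

$\Gamma$ defaults to an estimating-equation (influence-function) form:
a threshold's influence is $(\mathbf{1}\{y \le c\} - P_c)/\phi(\tau_c)$,
and each polychoric correlation is an M-estimator whose influence
combines its own score with the propagated threshold influences,
$\mathrm{IF}_\rho = -A_\rho^{-1}(s_i + A_\tau' \mathrm{IF}_\tau)$.
$\Gamma$ is then the empirical covariance of the stacked influences
divided by $n$.  A subject-level nonparametric bootstrap
(`method = "bootstrap"`, seeded) is provided as a cross-check and agrees
with the analytic form within Monte-Carlo error; the analytic form is
the default because the package's own calibration studies (hundreds of
replications, each needing a fresh $\Gamma$) would be impractical with
a nested bootstrap, and because it is exactly testable against the
delta-method variance of a single threshold,
$p(1-p)/(n\,\phi(\tau)^2)$.

### Optimization

The DWLS objective is a smooth weighted least-squares criterion, so the
fitter uses damped Gauss–Newton (Levenberg-style trust damping on the
normal equations, numerical Jacobians by central differences) from
several starts — a moment-informed start constructed by mapping the
stage-1 estimates into the specification's own metric, plus
deterministic perturbations — iterating until the relative decrease of
$F$ falls below `1e-12`, with a quasi-Newton (`nlminb`) fallback if the
least-squares path fails outright.  The tight stopping rule matters:
the equivalence checks below compare
chi-squares of independently fitted specifications at a `1e-4`
tolerance, which requires optima resolved far beyond ordinary
convergence tolerances.  When two specifications are linked by a
registered transformation map, each fit also receives the other's
mapped solution as an additional start; both optima remain genuine
minimizers of their own problems.  Equality constraints are implemented
by parameter elimination (shared table rows), never by penalties, so
degree-of-freedom accounting is exact.

## Equivalence and non-equivalence

Two specifications are equivalent when a parameter transformation maps
one onto the other while preserving the implied moments; equivalent
models fit any dataset with identical chi-square and degrees of
freedom.  The package ships closed-form maps for the pairs where such a
transformation exists:

* growth model, occasion-one anchoring vs threshold anchoring (all
  parameters scale through the distance between the first two
  thresholds, or back through the occasion-one latent variance);
* growth model, delta vs theta variance placement (all parameters
  divide by the occasion-one latent variance);
* autoregressive model, the two anchorings (a global affine change of
  the latent scale, with intercepts absorbing $a(1-\rho_t)$);
* the four binary autoregressive rows (per-occasion affine
  reparameterizations of one Markov correlation structure).

Because the extracted source tables for these maps were not readable,
each transcription is validated in the test suite by the
moment-preservation oracle (mapped parameters must reproduce the
implied statistics entrywise below `1e-10` and round-trip to the
identity); the oracle, not the transcription, is authoritative.  Two of
the binary maps are *generic* rather than global: the variances-free
binary row divides by standardized thresholds, so its map is undefined
where a threshold is zero or changes sign over time.

Non-equivalence is just as important: the standard delta and theta
growth models share degrees of freedom but impose different constraints
on the covariance structure (both have $T(T+1)/2 - 3 = 7$ constraints
at $T = 4$, but different ones — `omega_constraint_report()` counts
them and `omega_distinct()` exhibits covariance matrices one family
cannot reproduce).  And the two anchored ALT specifications are not
equivalent: ALT means are driven by the growth factors rather than by
free occasion intercepts, so the location shift of the affine map
leaves a residue $a(1-\rho_t)$ that cannot be absorbed when the
autoregressive coefficients vary over time.  ALT specifications
therefore default to time-varying $\rho_t$ (matching the kind of
application the model is built for); `check_equivalence()` finds
chi-square differences orders of magnitude above solver tolerance on
probe panels.

Probe panels are generated from processes deliberately misspecified for
both candidates — an ALT-type recursion followed by per-occasion affine
distortions of the latent scale — because equivalence must hold off the
truth, not only at it.

```{r equivalence-demo, eval = FALSE}
E <- model_spec("ar1", "alt1", n_occasions = 4, n_cat = 4, invariant = TRUE)
F <- model_spec("ar1", "alt2", n_occasions = 4, n_cat = 4, invariant = TRUE)
check_equivalence(E, F, n_probes = 5, seed = 1)
# equivalence check: EQUIVALENT (df 6 vs 6)
#   max |delta chi2| = 1.1e-14 over 5 probe panels (tol 0.0001)
#   closed-form map preserves implied statistics: TRUE
```

A subtle but important convention follows from the equivalence
requirement: free error variances are *unbounded below* during
optimization.  Several pairs relate a free error variance in one
specification to an unconstrained remainder in the other; bounding the
free one at zero would break exact equivalence precisely on badly
misfitting data, where the common optimum can be a Heywood solution.
Such solutions are reported as inadmissible, never silently prevented.

## Identification

`check_identification()` evaluates the Jacobian of the implied-statistics
map at random admissible parameter vectors (10 draws by default) and
declares local identification when the smallest singular value exceeds
`1e-8` times the largest at every draw; global identification is not
claimed.  The counting rule
`df = sum_v T(C_v - 1) + p(p-1)/2 - #free` matches the free-parameter
tables.  Numerically, the growth and autoregressive families are
identified with four waves under every implemented constraint set,
while the ALT family needs five: at four waves its Jacobian loses
exactly one rank, and the reported null direction shows the trade-off
among the autoregressive, growth-covariance and initial-condition
parameters.

## The simulator and what it does (not) show

`simulate_panel()` draws latent trajectories by running the structural
recursion — never by factorizing the implied covariance — so the
simulator is an independent oracle for the implied-moment algebra (the
acceptance suite checks agreement within four Monte-Carlo standard
errors at $10^6$ draws).  Randomness flows from one seed through R's
Mersenne-Twister stream; derived child seeds keep replications
independent and below $2^{31}$.

`nlsy_like_scenario()` packages a trivariate panel emulating a youth
cohort followed over six biennial waves: a binary illegal-drug-use
indicator and two 4-category ordinal series (depressive symptoms,
general health), generated from a stationary multivariate ALT with
cross-lagged paths, concomitant error covariances, time-invariant
thresholds and declining propensity means.  The true values (autoregressions
0.30–0.40, cross-lags of magnitude 0.05–0.10, slope means −0.03 to
−0.07, thresholds placed to give realistic margins such as a ~20%
drug-use rate) were chosen once as plausible for such cohort data and
are documented in the scenario object itself.  The generator emulates
threshold discretization of a Gaussian process with listwise-complete
data; it does not emulate informative missingness, survey weights,
measurement non-invariance across subgroups, or non-Gaussian latent
distributions — so passing tests support the estimator's internal
consistency and calibration under the stated model, not robustness to
those violations.

## Numerical choices and problem sizes

* Bivariate normal rectangle probabilities: Gauss–Legendre scheme
  (Drezner–Wesolowsky/Genz) in C++, oracled against 1-D quadrature to
  `1e-12`; infinite limits handled exactly.
* Polychoric search interval $(-1+10^{-6},\, 1-10^{-6})$; estimates
  within $10^{-4}$ of $\pm 1$ are flagged as boundary solutions.
* Free variances are bounded below at `1e-4` during optimization;
  negative *remainder* variances (possible under delta-style
  constraints) are reported as inadmissible-solution warnings, not
  errors, so misspecified fits still return diagnostics.
* Thresholds tied across occasions share one parameter-table row;
  ordering of free thresholds is checked at admissibility, not enforced
  during the search.
* Empty extreme categories push thresholds to $\pm\infty$ and block
  stage 2 with a clear error; interior empty categories are flagged
  degenerate and the polychoric layer refuses them.  A variable's
  effective category count is never silently collapsed.
* Study sizes used by the bundled acceptance computations: 10–20 probe
  panels of $n = 2000$ for the equivalence suite, a 200-replication
  recovery study at $n = 5000$, and a 500-replication size study at
  $n = 2000$.  These sizes give Monte-Carlo error comfortably inside
  the tolerances being checked.

## Known limitations

Pairwise-present estimation, multiple imputation and survey weights are
out of scope (listwise deletion only, so stage-1 and stage-2 samples
coincide).  Growth curves are linear with loadings $t-1$ (configurable
centering is not yet exposed).  The threshold-anchored parameterization
requires at least three categories; with binary data its role is taken
by the fixed-zero-threshold row.  Equivalence verdicts are empirical —
equal fit on the probe set plus a validated map — not symbolic proofs.
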