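---
title: "Estimating time-varying covariate effects in the Cox model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating time-varying covariate effects in the Cox model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvcox)
```

## The model

The Cox proportional hazards model assumes each covariate multiplies the
hazard by a constant factor over all of follow-up. In registry-scale
time-to-event data this assumption routinely fails: the hazard ratio of a
disease stage, a treatment, or a demographic factor is often strikingly
large shortly after baseline and fades over the following years. `tvcox`
fits the non-proportional generalization

$$\lambda(t \mid z) = \lambda_0(t)\, \exp\{z^\top \beta(t)\},$$

where each coordinate of $\beta(t)$ — the log hazard ratio of one covariate
— is a smooth function of time. Each trajectory is spanned by a B-spline
basis with $K$ functions,

$$\beta_j(t) = \sum_{k=1}^K \theta_{jk} B_k(t),$$

which turns the problem into finite-dimensional maximization of the
log-partial likelihood over the $p \times K$ matrix $\theta$. Estimation
never touches $\lambda_0(t)$; with stratified data, each stratum keeps its
own baseline hazard while $\beta(t)$ is shared.

Ties are handled with the Breslow approximation: the contribution of a
distinct event time $t_m$ with tie set $D_m$ ($d_m$ events) and risk set
$R_m$ is

$$\sum_{i \in D_m} \eta_i(t_m) - d_m \log \sum_{\ell \in R_m}
  e^{\eta_\ell(t_m)}, \qquad \eta_i(t) = z_i^\top \beta(t).$$

A subject censored exactly at an event time is kept in that risk set
(the usual counting-process convention; the data model enforces strictly
positive times, 0/1 event indicators, and at least one event).

## Basis choices

* **Degree**: cubic by default. Quadratic is supported because the
  first-derivative smoothing-spline penalty is natural for it.
* **Number of basis functions** `K`: default 8; sensible values are roughly
  5–10. Too-small `K` underfits; beyond ~10 the penalty, not `K`, controls
  smoothness.
* **Knots**: interior knots sit at quantiles of the *distinct* observed
  event times (a uniform rule is available). Quantile placement balances the
  number of events per knot interval, which keeps the information matrix
  well conditioned late in follow-up where risk sets are thin. Knots are
  placed on event times pooled across strata, since one $\beta(t)$ is shared.
* **Boundary**: the basis is clamped to [smallest, largest distinct event
  time]. Evaluation outside that range is clamped to the boundary, i.e.
  fitted effects are extrapolated as constants — needed when predicting at
  censoring times past the last event. A strict mode raises an error
  instead.

## Estimation

`fit_tvcox()` maximizes the (optionally penalized) log-partial likelihood by
a proximal Newton method. The gradient and Hessian in
$\mathrm{vec}(\theta)$ (covariate-major flattening: the $K$ coefficients of
covariate 1 first) are accumulated event time by event time through the
Kronecker structure $x_i(t) = z_i \otimes B(t_m)$: per event time only the
at-risk rows' $p$-vector $z$ and the $K$-vector $B(t_m)$ are combined, and
the $n \times pK$ expanded design of the classical "long data" approach is
never materialized. Every risk-set sum is log-sum-exp stabilized.

Each iteration solves $(-H + \tau I)\delta = g$ and backtracks from step
size 1 (halving, Armijo constant $10^{-4}$, at most 50 halvings) until the
objective increases sufficiently. The damping $\tau$ starts at 0 — plain
Newton — and is escalated ($\tau \leftarrow \max(10^{-8}, 10^{-4}
\max \mathrm{diag}(-H))$, then tenfold) only when the system fails a
Cholesky factorization or a line search stalls with a non-negligible
gradient. This is the proximal safeguard for the ill-conditioning that
near-degenerate binary covariates and sparse late risk sets produce; on
well-behaved data it never activates, and the fit is an ordinary Newton
path. Convergence is declared when the relative objective change drops
below $10^{-9}$ (default); the gradient max-norm at the optimum is reported
alongside, and accepted iterations never decrease the objective — the test
suite asserts this trace monotonicity on every fit. Fits contain no random
elements: results are reproducible bit for bit given the input order.
A covariate with no variation carries no information; its row of
$\theta$ stays at the zero start and the (then singular) information matrix
falls back to a generalized inverse with a warning.

## Penalties

Two quadratic roughness penalties are available, both applied per covariate
with one shared tuning parameter $\lambda$ (the penalized objective is
$\ell(\theta) - \lambda \sum_j \theta_j^\top S \theta_j$):

* **P-spline** (`pspline_matrix`): $S = D^\top D$ with $D$ the $d$-th order
  difference operator on adjacent basis coefficients. Order 1 shrinks the
  fitted effect toward a constant as $\lambda \to \infty$; order 2 (the
  default, standard in the P-spline literature) shrinks the coefficient
  sequence toward one affine in the knot index. The constant-effect limit is
  therefore exact for $d = 1$; with $d = 2$ the limit is an approximately
  linear effect (exactly linear in knot index, approximately in $t$ for
  near-uniform knots). Both behaviors are covered by tests; users wanting
  the hard constant limit should set `diff_order = 1`.
* **Smoothing spline** (`smoothing_spline_matrix`): $S_{kl} = \int
  B_k^{(r)} B_l^{(r)} \,dt$, the integrated squared $r$-th derivative of
  $\beta_j$. With a cubic basis $r = 2$ (limit: straight lines), with a
  quadratic basis $r = 1$ (limit: constants); the order is auto-selected and
  overridable. The integrand is piecewise polynomial of degree
  $2(\mathrm{degree} - r)$, so a fixed Gauss–Legendre rule with
  $(\mathrm{degree} - r) + 2$ nodes per knot interval is exact up to
  round-off; the test suite checks the Gram matrix against adaptive
  quadrature at $10^{-9}$.

Per-covariate $\lambda$ vectors are deliberately not offered: tuning a
single smoothness parameter is what the information criteria and
cross-validation below select, and a shared $\lambda$ keeps the effective
degrees of freedom interpretable.

## Tuning

`fit_tvcox_path()` fits a descending $\lambda$ grid (default: 20 points
log-spaced in $[10^{-3}, 10^3]$) with warm starts. `ic_tvcox()` computes,
with $\ell$ the unpenalized log-partial likelihood at the optimum, $H$ the
unpenalized negative Hessian, $P$ the penalized negative Hessian and $J$
the outer-product (score-based) information:

$$\mathrm{mAIC} = -2\ell + 2\,\mathrm{tr}(P^{-1}H),\quad
  \mathrm{TIC} = -2\ell + 2\,\mathrm{tr}(P^{-1}HP^{-1}H),\quad
  \mathrm{GIC} = -2\ell + 2\,\mathrm{tr}(P^{-1}J),$$

with effective degrees of freedom $\mathrm{tr}(P^{-1}H)$. These are the
standard trace constructions for penalized likelihoods, pinned here as the
package's definitions. At $\lambda = 0$, $P = H$ makes the effective df
exactly $pK$ and mAIC the classical AIC — the anchor the tests assert — and
the df decreases monotonely in $\lambda$ toward the penalty's null-space
dimension ($p$ for an order-1 P-spline). Criterion ties break toward the
larger $\lambda$ (prefer the smoother model).

`cv_tvcox()` offers K-fold cross-validation with the
Verweij–van Houwelingen contribution $\ell_{\text{full}}(\hat\theta_{\text{train}})
- \ell_{\text{train}}(\hat\theta_{\text{train}})$ per fold. The naive
alternative — the partial likelihood of the held-out fold — breaks down in
small folds whose risk sets are degenerate; the full-minus-train form never
does. Folds are assigned by a seeded shuffle stratified on event status and
stratum, redrawn (up to 20 times) if a training split would lose all its
events; the whole procedure is deterministic given the seed. Information
criteria are considerably cheaper than cross-validation (one path instead of
one per fold) and are the recommended default.

## Inference

All tests and intervals use the covariate's $K \times K$ block of the
inverse *penalized* information at the optimum (for unpenalized fits this
is the usual inverse information). This Bayesian-style variance is the
package's single variance anchor — the pointwise bands, the PH test and the
zero-effect test all draw on the same matrix, so they are mutually
consistent by construction. A sandwich alternative is deliberately not the
default; the Monte-Carlo checks below document how the default behaves.

* `test_ph()`: $H_0{:}\ \beta_j(t)$ constant, via the adjacent-difference
  contrast on $\theta_j$, $\chi^2_{K-1}$. The statistic is invariant to the
  choice of contrast basis spanning the constant-orthogonal space (tested).
* `test_zero()`: $H_0{:}\ \beta_j(\cdot) = 0$, $\chi^2_K$; at $K = 1$ it is
  the square of the standard Cox z-statistic.
* `test_pointwise()` / `confint()`: $\hat\beta_j(t) = B(t)^\top\hat\theta_j$
  with delta-method variance $B(t)^\top V_j B(t)$, one df per time point. No
  multiplicity adjustment by default (each time is reported marginally); a
  Bonferroni-across-grid option exists. The default grid is the distinct
  event times.

Under a proportional-hazards-true simulation ($n = 1000$, $K = 5$, 500
replicates) the PH test's empirical type-I error at $\alpha = 0.05$ falls
within the 99% binomial band $[0.028, 0.078]$, and its power against a
sinusoidal alternative of amplitude 1 exceeds 0.9 at 200 replicates — both
recomputed by the acceptance suite and script.

## Baseline hazard and prediction

`baseline_hazard()` returns the Breslow step estimator per stratum,
$d\hat\Lambda_0(t_m) = d_m / \sum_{\ell \in R_m} e^{\hat\eta_\ell(t_m)}$;
at $\theta = 0$ this is exactly the tied Nelson–Aalen estimator, which the
tests assert stratum by stratum. `predict_survival()` composes it with the
fitted effects into $S(t \mid z) = \exp\{-\sum_{t_m \le t}
d\hat\Lambda_0(t_m) e^{z^\top \hat\beta(t_m)}\}$. `export_curves()` writes a
tidy long table (log hazard-ratio scale by default, hazard-ratio scale on
request) for any plotting front end, with 17-significant-digit CSVs that
round-trip exactly.

## The simulator

`simulate_survdata()` draws event times from $\lambda(t \mid z) =
\lambda_0(t) e^{z^\top \beta(t)}$ by inverting the cumulative hazard on a
2000-point grid over $[0, t_{\text{horizon}}]$ with linear interpolation —
a documented approximation chosen to support arbitrary trajectory shapes;
halving the step moves the mean event time by well under 0.1% (tested).
Censoring (uniform, exponential, or administrative) is independent;
subjects surviving the horizon are administratively censored there.
Optional rounding of observed times induces realistic ties, with resampling
of the rare times that round to zero. Trajectory shapes include constant,
linear, sinusoidal and exponentially decaying effects; the decaying default
in the examples, $\beta(t) = 1.5\,e^{-0.3 t}$, mirrors a hazard ratio near
4.5 shortly after baseline that fades to near 1 by eight time units — the
qualitative pattern seen for cancer-stage effects in registry data.

`example_survdata()` packages one fixed design: $n = 2000$, two standard
normal covariates, $\beta_1 = 1$ constant and $\beta_2(t) = \sin(\pi t/3)$,
exponential baseline (rate 0.8), uniform censoring on $(0, 12)$ plus the
administrative cut-off at $t = 3$, giving roughly a quarter censored — one
covariate that satisfies proportional hazards and one that visibly violates
it.

What the simulator does *not* emulate: covariate measurement error,
dependent censoring, left truncation, time-varying covariate *values*,
cluster-correlated frailty, and the sampling quirks of real registries.
Passing tests therefore demonstrate correctness of the estimator under the
assumed model, not robustness to violations of it.

## Numerical choices, sizes, and limitations

* Tolerances: objective-change $10^{-9}$; derivative checks at $10^{-6}$
  relative against central differences; oracle-equivalence (naive
  counting-process expansion fit) at $10^{-6}$ per coefficient on fixtures
  up to $n = 100$, $p = 3$, $K = 5$.
* Monte-Carlo problem sizes used by the checks: 500 null replicates and 200
  alternative replicates at $n = 1000$ for test calibration; three seeds at
  $n = 3000$ for trajectory recovery (grid RMSE below 0.2, with the
  IC-selected penalized fit no worse than 1.25× the unpenalized RMSE in
  median).
* Degenerate inputs: strata with zero events contribute nothing (empty
  baseline with a warning); a singular contrast covariance in a Wald test
  falls back to a generalized inverse with rank-adjusted df, flagged.
* Covariates are used exactly as supplied — no internal standardization;
  the command-line interface offers optional centering, which shifts only
  the baseline hazard and leaves $\beta(t)$ unchanged.
* Scope: right-censored data only; no left truncation, interval censoring,
  recurrent events, or time-varying covariate values; designed for
  low-dimensional $p \ll n$ problems. All covariates are modeled as
  time-varying; there is no mixed constant/varying specification.
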