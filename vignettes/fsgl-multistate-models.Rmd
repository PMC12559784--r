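---
title: "Fused sparse-group lasso penalized multi-state models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fused sparse-group lasso penalized multi-state models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusedmsm)
```

## The model

A multi-state model describes a patient's event history as a continuous-time
Markov process over a finite set of disease states; each directed transition
$q = 1,\dots,Q$ between states carries its own proportional-hazards model

$$h_q(t \mid x) = h_{0,q}(t)\, \exp\{\beta_q^\top x\},$$

with a shared set of $P$ time-fixed covariates $x$ and transition-specific
coefficients $\beta_q \in \mathbb{R}^P$. Working on *long-format* data — one
row per subject and transition at risk during a sojourn, with entry time,
exit time and an event indicator — the partial likelihood factorizes over
transitions into stratified Cox partial likelihoods. Stacking the
coefficients covariate-major,
$\beta = (\beta_{1,1},\dots,\beta_{1,Q},\beta_{2,1},\dots,\beta_{P,Q})^\top$,
and expanding each row's covariates into the columns of its own transition
gives a single stratified Cox model with $PQ$ parameters, negative log
partial likelihood $L(\beta)$, score $U(\beta) = X^\top(\delta - \hat\mu)$
and Hessian $J(\beta) = -X^\top W X$. Risk sets respect left truncation
(a row is at risk at $t$ iff $T_{\text{start}} < t \le T_{\text{stop}}$)
and ties are handled by Breslow's method throughout, consistent with the
Breslow baseline estimator used for $\hat\Lambda_{0,q}$.

With many transitions, even a handful of biomarkers produces a large
parameter vector, and three kinds of prior structure are worth exploiting:
most effects are zero (*sparsity*), clinically similar transitions — e.g.
remission-to-relapse at first and second remission — tend to carry effects
of similar size (*similarity*), and a covariate that matters for one
transition often matters for that transition as a whole block
(*transition-wise grouping*). The fused sparse-group lasso (FSGL) penalty
encodes all three:

$$p_{\lambda}(\beta) = \lambda \Big[\, \alpha\gamma \sum_{p,q}
|\beta_{p,q}| \;+\; (1-\gamma) \sum_{(q,q') \in S} \sum_p
|\beta_{p,q} - \beta_{p,q'}| \;+\; (1-\alpha)\gamma \sum_q w_q
\lVert \beta_q \rVert_2 \Big],$$

where $S$ is the declared set of similar transition pairs. $\lambda > 0$
sets the overall regularization level; $\alpha \in [0,1]$ balances the
coefficient-wise lasso against the transition-group penalty;
$\gamma \in [0,1]$ balances both sparse terms against the fusion penalty.
The corners reduce to classical penalties (`reduction_mode()`): global
lasso at $(1,1)$, group penalty at $(0,1)$, pure fusion at $\gamma = 0$.

## The solver

The penalty is non-separable (fusion couples coordinates across
transitions), so coordinate descent is unsuitable; we use ADMM. All penalty
arguments are collected in a penalty structure matrix $K$ with three row
blocks — $PQ$ unit rows, one $\pm 1$ contrast row per (similar pair,
penalized covariate), and $Q$ group selector blocks — and the problem is
split as $\min_\beta L(\beta) + g(\theta)$ subject to $\theta = K\beta$.
Each iteration then alternates:

* a smooth **beta-update** minimizing
  $L(\beta) + \tfrac{\rho}{2}\lVert K\beta - \theta + u \rVert^2$ by
  Newton's method with step halving (warm-started from the previous
  iterate; a single gradient step with $\varepsilon_{GD} = 0.01$ precedes
  Newton on the first outer iteration, following the hybrid scheme used for
  penalized Cox likelihoods);
* a closed-form **theta-update**: scalar soft-thresholding of the lasso and
  fusion rows, vector soft-thresholding of each group block, at levels
  $\lambda_m w_m / \rho$ assembled term-by-term from the penalty
  ($\lambda\alpha\gamma\zeta_m$, $\lambda(1-\gamma)$,
  $\lambda(1-\alpha)\gamma w_q$);
* a **dual update** $u \leftarrow u + K\beta - \theta$, and adaptive
  residual balancing of $\rho$ ($\tau = 2$, $\eta = 10$, $\rho_0 = 1$).

Iterations stop when the primal residual
$\lVert\theta - K\beta\rVert_2$ and dual residual
$\lVert\rho K^\top \Delta\theta\rVert_2$ fall below tolerances built from
$\varepsilon_{abs} = 10^{-4}$ and $\varepsilon_{rel} = 10^{-2}$, or after
`maxiter = 500` iterations (a warning, not an error; the last iterate is
returned flagged as non-converged). The raw $\beta$ iterate never contains
exact zeros; the thresholded auxiliary variable $\hat\theta$ does, so the
reported coefficient vector and the selection mask are read off the lasso
block of $\hat\theta$ (with transitions zeroed as whole blocks when the
group penalty removed them).

Numerical choices worth recording:

* **Stopping-rule dimensions.** The absolute tolerance is scaled by
  $\sqrt{M}$ for the primal residual ($\theta - K\beta \in \mathbb{R}^M$)
  and $\sqrt{PQ}$ for the dual ($K^\top\nu \in \mathbb{R}^{PQ}$), the
  standard square-root-of-dimension rule; `admm_control(stop_mode =
  "literal")` scales linearly instead.
* **Dual rescaling.** When $\rho$ changes, the scaled dual $u$ is rescaled
  by $\rho_{old}/\rho_{new}$ so the unscaled multiplier $\phi = \rho u$ is
  preserved; without this the scaled-dual iteration is inconsistent across
  step-size changes.
* **Rho adaptation.** $\rho$ grows when the primal residual exceeds
  $\eta$ times the dual residual and shrinks when the dual exceeds $\eta$
  times the primal — the usual residual-balancing form, which leaves
  $\rho$ unchanged when the residuals are of comparable size.
* **Group weights.** $w_q = \sqrt{P_{pen}}$ by default (the standard
  group-lasso size weighting); `penalty_structure(group_weight = "size")`
  uses the literal group size instead.
* **Unpenalized covariates.** Established predictors can be exempted via
  per-coefficient scaling factors $\zeta_m = 0$; such covariates are
  excluded from the fusion contrasts and group blocks as well, so no
  penalty term ever touches them.
* **Standardization.** Continuous covariates should be scaled by their
  empirical standard deviation per stacked column before penalization
  (`standardize_design()`; no centering, which would destroy the stacked
  sparsity pattern); fitted coefficients map back via the recorded scale
  factors. Binary covariates are left on their natural scale.
* **Selection convention.** When $\alpha\gamma = 0$ there are no active
  lasso rows and exact zeros can only arise blockwise; selection then falls
  back to $|\hat\beta| > 10^{-8}$.

## Tuning

$\lambda$ is selected at fixed $(\alpha, \gamma)$ by generalized
cross-validation,
$\mathrm{GCV}(\lambda) = \bar L(\hat\beta) / \{N [1 - e(\lambda)/N]^2\}$,
with $e(\lambda) = \mathrm{tr}[(H + \Sigma_\lambda)^{-1} H]$ the
effective number of parameters: $H$ is the Hessian of $L$ at $\hat\beta$
restricted to the active set, and $\Sigma_\lambda$ the curvature of the
locally quadratic approximated penalty,
$\sum_m \lambda_m w_m \lVert K_m\hat\beta\rVert^{-1} K_m^\top K_m$ over
rows with nonzero argument — which reduces to the familiar diagonal
$\lambda/|\hat\beta_j|$ form in the pure-lasso case. Exact zeros are
excluded before the trace (the quadratic approximation is undefined at 0,
and a removed coefficient contributes no degrees of freedom).

Two open choices were settled empirically and are worth stating plainly:

* **The sample size $N$ in GCV.** The stacked likelihood's natural sample
  size is the number of long-format rows, not the number of subjects, and
  the statistic is computed from the per-row averaged likelihood with
  $N = $ rows by default (`N_mode = "rows"`). This calibration makes the
  degrees-of-freedom correction commensurate with the likelihood scale; on
  the benchmark scenario below it yields GCV values of order
  $5 \times 10^{-4}$ with tuned penalty levels around $\lambda \approx 10$
  for the global lasso (the quantities `scripts/acceptance.R` reports),
  whereas dividing by the subject count weakens the correction's leverage,
  pushing the selected $\lambda$ several grid points higher and changing
  the statistic's magnitude by orders. The subject-count convention
  remains available as `N_mode = "subjects"`.
* **The default grid** is 20 values of $\lambda$ from 0.01 to 500, equally
  spaced on the log scale, with $\alpha, \gamma$ on
  $\{0, 0.25, 0.5, 0.75, 1\}$; grids are user-overridable and recorded
  verbatim in run manifests. Tuning walks the grid from its largest (most
  sparse) value with warm starts; ties in GCV break toward the smaller
  $\lambda$. `refine = TRUE` adds Brent minimization of GCV over the
  bracketing grid interval; it is off by default because the GCV surface
  is shallow near its minimum, so the refinement buys little relative to
  the extra fits it costs.

## The simulator and the benchmark scenario

`simulate_paths()` generates event histories as a nested series of
competing-risks experiments: within each transient state the sojourn is
exponential with the summed outgoing hazards
$h_q(x) = h_{0,q} \exp(\beta_q^\top x)$ (constant baselines), and the
destination is a categorical draw with probabilities $h_q(x)/\sum h$ —
equivalent to racing per-transition exponential clocks. Covariates are
drawn before any event times, so a subject's covariates do not depend on
the length of their path. By default there is no censoring: every path
runs to an absorbing state, which the nine-state benchmark chart
guarantees. An administrative horizon (`max_time`) is available for
robustness experiments.

The packaged benchmark (`aml_dgp()`) is an acute myeloid leukemia disease
pathway: nine states, eight transitions, $N = 1000$ subjects, all
$h_{0,q} = 0.05$, two independent Bernoulli(0.5) biomarkers, and truth
$\beta_{1,1} = 1.5$, $\beta_{1,3} = \beta_{1,7} = 1.2$,
$\beta_{1,4} = \beta_{1,8} = -0.8$, all else zero ($d = 5$ nonzero
coefficients). Transitions (3,7) and (4,8) — remission to relapse, and
remission to death, at first and second remission — are the declared
similar pairs. The simulator emulates constant-hazard Markov dynamics with
time-fixed covariates; it does not emulate time-varying effects,
non-exponential sojourns, frailty, or dependent censoring, so passing
selection benchmarks here demonstrates correctness of the machinery under
the stated model, not robustness to violations of it.

Replicate counts follow the Monte Carlo error budget for selection rates:
`required_nsim(0.9, 0.02)` gives the 225 repetitions a full study uses.
The packaged tests and the acceptance script run a scaled-down study of 50
replicates over the global-lasso corner $(1,1)$ and the mixed combination
$(1,0.25)$, which keeps the whole suite in the tens of minutes on one core
while leaving the Monte Carlo error of a median FDR around 0.07; the full
$5 \times 5 \times 225$ study is an overnight job driven by `cmd_study()`
with the default configuration.

## A worked example

```{r example, eval = FALSE}
chart <- aml_state_chart()
dat <- simulate_paths(aml_dgp(N = 1000), seed = 1)
design <- expand_design(dat, chart)
ps <- penalty_structure(chart, P = 2)

tuned <- fsgl_tune(design, ps, alphas = 1, gammas = 0.25)
tuned$argmin
fit <- tuned$fits[["1/0.25"]]
fit_table(fit, design)
```

On data like these the tuned fused fit recovers the two fused pairs as
near-equal effects and zeroes most of the eleven null coefficients, while
a pure-lasso fit at its own tuned $\lambda$ tends to drop the weak late
effect $\beta_{1,8}$; the test suite and `scripts/acceptance.R` recompute
these patterns from scratch.

## Known limitations

* Time-dependent covariates or effects, transition-specific covariate
  sets, and non-constant simulated baselines are out of scope.
* Breslow tie handling only (consistent with the baseline estimator);
  Efron or exact methods are not provided.
* The GCV surface near its minimum is shallow on the benchmark, so the
  selected $\lambda$ can move by a grid step between replicates;
  conclusions should rest on aggregates over replicates, as in
  `run_study()`.
* No post-selection inference: selection masks come with no error
  guarantees beyond the empirical TPR/FDR reported by the study tools.
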