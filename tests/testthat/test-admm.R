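test_that("soft-thresholding matches its closed form", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_equal(soft_threshold(0.3, 0.5), 0)
  expect_equal(soft_threshold(0, 7), 0)
  expect_equal(soft_threshold(c(3, 4), 1), c(2.4, 3.2))  # norm 5, factor 0.8
  expect_equal(soft_threshold(c(0.3, 0.4), 1), c(0, 0))
})

test_that("theta update thresholds blockwise and passes zeta = 0 through", {
  ps <- penalty_structure(aml_state_chart(), P = 2)
  a <- seq(-1, 1, length.out = ps$M)
  lev <- fusedmsm:::penalty_row_levels(ps, lambda = 1, alpha = 1, gamma = 1)
  th <- fusedmsm:::admm_theta_update(a, ps, lev, rho = 2)
  # lasso rows: scalar threshold at 1/2; fusion/group multipliers vanish
  expect_equal(th[1:16], sign(a[1:16]) * pmax(abs(a[1:16]) - 0.5, 0))
  expect_equal(th[17:36], a[17:36])
  # group corner: blocks thresholded jointly as vectors
  lev0 <- fusedmsm:::penalty_row_levels(ps, 1, 0, 1)
  th0 <- fusedmsm:::admm_theta_update(a, ps, lev0, rho = 1)
  expect_equal(th0[1:20], a[1:20])
  gr <- ps$group_rows[[1]]
  expect_equal(th0[gr], soft_threshold(a[gr], sqrt(2)))
})

test_that("adaptive step size follows residual balancing", {
  ctl <- admm_control()
  expect_equal(fusedmsm:::admm_adapt_rho(1, 10.1, 1, ctl), 2)
  expect_equal(fusedmsm:::admm_adapt_rho(1, 1, 20, ctl), 0.5)
  expect_equal(fusedmsm:::admm_adapt_rho(3, 1, 1, ctl), 3)
})

test_that("stopping thresholds are monotone in the tolerances", {
  ctl <- admm_control()
  st <- fusedmsm:::admm_check_stopping(primal = 0, dual = 0, Kb_norm = 1,
                                       theta_norm = 1, Ktnu_norm = 1,
                                       PQ = 16, M = 36, ctl)
  expect_true(st$stop)
  st1 <- fusedmsm:::admm_check_stopping(0.05, 0.02, 1, 1, 1, 16, 36, ctl)
  ctl2 <- admm_control(eps_rel = 2e-2)
  st2 <- fusedmsm:::admm_check_stopping(0.05, 0.02, 1, 1, 1, 16, 36, ctl2)
  if (st1$stop) expect_true(st2$stop)
  expect_gte(st2$eps1, st1$eps1)
  expect_gte(st2$eps2, st1$eps2)
})

test_that("beta update minimizes the augmented Lagrangian", {
  rd <- random_design(n = 60, P = 2, Q = 2, seed = 21)
  d <- rd$design
  ps <- penalty_structure(rd$chart, P = 2)
  pre <- fusedmsm:::cox_precompute(d)
  set.seed(22)
  theta <- rnorm(ps$M); u <- rnorm(ps$M, sd = 0.2); rho <- 1.7
  ctl <- admm_control()
  up <- fusedmsm:::admm_beta_update(rep(0, 4), theta, u, rho, d, pre, ps,
                                    ctl, first_outer = TRUE)
  aug <- function(b) msm_nll(d, b) +
    rho / 2 * sum((drop(ps$K %*% b) - theta + u)^2)
  # gradient of the augmented objective vanishes at the inner optimum
  g <- fd_gradient(aug, up$beta)
  expect_lt(max(abs(g)), 1e-3)
  expect_lt(aug(up$beta), aug(rep(0, 4)))
  # analytic augmented gradient matches finite differences at a random point
  b0 <- rnorm(4, sd = 0.3)
  ga <- -msm_score(d, b0) +
    rho * drop(ps$KtK %*% b0 - crossprod(ps$K, theta - u))
  expect_equal(ga, fd_gradient(aug, b0), tolerance = 1e-5)
})

test_that("unpenalized ADMM fit reproduces the stratified Cox estimate", {
  d <- aml_test_design(N = 250, seed = 42)
  ps <- penalty_structure(aml_state_chart(), P = 2)
  fit <- fsgl_fit(d, ps, 0, 1, 1)
  expect_true(fit$converged)
  cp <- survival::coxph(
    survival::Surv(d$tstart, d$tstop, d$delta) ~ d$X +
      survival::strata(d$strata),
    ties = "breslow")
  expect_lt(max(abs(fit$beta_hat - unname(coef(cp)))), 1e-3)
})

test_that("theta is exactly sparse while the raw beta iterate is not", {
  d <- aml_test_design(N = 250, seed = 42)
  ps <- penalty_structure(aml_state_chart(), P = 2)
  fit <- fsgl_fit(d, ps, 15, 1, 1)
  expect_gt(sum(fit$theta[1:16] == 0), 0)
  expect_equal(sum(fit$beta_admm == 0), 0)
  expect_equal(fit$selected, fit$beta_hat != 0, ignore_attr = TRUE)
})

test_that("a large enough lambda zeroes every penalized coefficient", {
  d <- aml_test_design(N = 150, seed = 8)
  ps <- penalty_structure(aml_state_chart(), P = 2)
  fit <- fsgl_fit(d, ps, 5000, 1, 1)
  expect_equal(fit$beta_hat, rep(0, 16))
  expect_false(any(fit$selected))
})

test_that("pure fusion with large lambda forces fused pairs equal", {
  d <- aml_test_design(N = 250, seed = 42)
  ps <- penalty_structure(aml_state_chart(), P = 2)
  # tight tolerances: the pair differences approach 0 up to solver accuracy
  fit <- fsgl_fit(d, ps, 400, 1, 0,
                  control = admm_control(eps_abs = 1e-6, eps_rel = 1e-4,
                                         maxiter = 3000))
  b <- fit$beta_hat
  for (p in 1:2) {
    expect_lt(abs(b[stack_index(p, 3, 8)] - b[stack_index(p, 7, 8)]), 1e-2)
    expect_lt(abs(b[stack_index(p, 4, 8)] - b[stack_index(p, 8, 8)]), 1e-2)
  }
  # non-fused coefficients stay near their unpenalized values
  f0 <- fsgl_fit(d, ps, 0, 1, 1)
  expect_lt(abs(b[stack_index(1, 1, 8)] - f0$beta_hat[stack_index(1, 1, 8)]),
            0.1)
})

test_that("group corner selects whole transitions jointly", {
  d <- aml_test_design(N = 250, seed = 42)
  ps <- penalty_structure(aml_state_chart(), P = 2)
  fit <- fsgl_fit(d, ps, 40, 0, 1)
  b <- matrix(fit$beta_hat, nrow = 2, byrow = TRUE)  # P x Q
  per_q <- colSums(b != 0)
  expect_true(all(per_q %in% c(0, 2)))
  expect_true(any(per_q == 0))
})

test_that("fits are deterministic and exportable", {
  d <- aml_test_design(N = 120, seed = 13)
  ps <- penalty_structure(aml_state_chart(), P = 2)
  f1 <- fsgl_fit(d, ps, 10, 1, 0.5)
  f2 <- fsgl_fit(d, ps, 10, 1, 0.5)
  expect_identical(f1$beta_hat, f2$beta_hat)
  tab <- fit_table(f1, d)
  expect_equal(nrow(tab), 16)
  expect_equal(tab$coefficient[tab$covariate == "X1" & tab$trans == 1],
               f1$beta_hat[stack_index(1, 1, 8)])
})
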