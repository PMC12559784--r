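test_that("toy two-subject instance matches hand-derived values", {
  d <- toy_design()
  # at beta = 0: risk sets of sizes 2 then 1
  expect_equal(msm_nll(d, 0), log(2))
  expect_equal(msm_score(d, 0), 0.5, ignore_attr = TRUE)
  expect_equal(drop(msm_hessian(d, 0)), -0.25)
  bl <- breslow_baseline(d, 0)
  expect_equal(bl$cumhaz, c(1 / 2, 3 / 2))
})

test_that("nll at zero equals the sum of log risk-set sizes", {
  rd <- random_design(n = 50, P = 2, Q = 3, seed = 2)
  d <- rd$design
  sizes <- vapply(which(d$delta == 1), function(i) {
    sum(d$strata == d$strata[i] & d$tstart < d$tstop[i] &
          d$tstop >= d$tstop[i])
  }, numeric(1))
  expect_equal(msm_nll(d, rep(0, 6)), sum(log(sizes)))
})

test_that("likelihood matches direct risk-set enumeration at random beta", {
  for (seed in 1:3) {
    rd <- random_design(n = 45, P = 2, Q = 3, seed = seed)
    beta <- rnorm(6, sd = 0.7)
    expect_equal(msm_nll(rd$design, beta), naive_nll(rd$design, beta),
                 tolerance = 1e-10)
  }
})

test_that("score and Hessian agree with finite differences", {
  for (seed in 4:6) {
    rd <- random_design(n = 40, P = 2, Q = 2, seed = seed)
    d <- rd$design
    beta <- rnorm(4, sd = 0.5)
    g <- msm_score(d, beta)
    gfd <- fd_gradient(function(b) -msm_nll(d, b), beta)
    expect_equal(g, gfd, tolerance = 1e-5)
    H <- msm_hessian(d, beta)
    for (j in seq_along(beta)) {
      e <- numeric(length(beta)); e[j] <- 1e-5
      expect_equal(H[, j],
                   (msm_score(d, beta + e) - msm_score(d, beta - e)) / 2e-5,
                   tolerance = 1e-4)
    }
  }
})

test_that("the two score forms agree and the Hessian is block NSD", {
  rd <- random_design(n = 60, P = 2, Q = 3, seed = 9)
  d <- rd$design
  beta <- rnorm(6, sd = 0.5)
  expect_equal(msm_score(d, beta), msm_score(d, beta, form = "breslow"),
               tolerance = 1e-10)
  H <- msm_hessian(d, beta)
  expect_true(isSymmetric(H, tol = 1e-10))
  expect_lte(max(eigen(H, only.values = TRUE)$values), 1e-8)
  # coefficients of different transitions never couple
  for (q1 in 1:3) for (q2 in 1:3) {
    if (q1 == q2) next
    i <- stack_index(1:2, q1, 3); j <- stack_index(1:2, q2, 3)
    expect_equal(H[i, j], matrix(0, 2, 2), ignore_attr = TRUE)
  }
})

test_that("stacked likelihood equals the sum of per-transition Cox fits", {
  rd <- random_design(n = 80, P = 2, Q = 3, seed = 12)
  d <- rd$design
  dat <- rd$data
  beta <- rnorm(6, sd = 0.4)
  per_q <- 0
  for (q in 1:3) {
    sub <- dat[dat$trans == q, ]
    bq <- beta[stack_index(1:2, q, 3)]
    fit <- survival::coxph(
      survival::Surv(Tstart, Tstop, status) ~ x1 + x2, data = sub,
      ties = "breslow", init = bq,
      control = survival::coxph.control(iter.max = 0))
    per_q <- per_q - fit$loglik[2]
  }
  expect_equal(msm_nll(d, beta), per_q, tolerance = 1e-8)
})

test_that("Poisson-approximation Hessian equals -X' diag(mu) X", {
  rd <- random_design(n = 50, P = 2, Q = 2, seed = 15)
  d <- rd$design
  beta <- rnorm(4, sd = 0.5)
  Hp <- msm_hessian(d, beta, mode = "poisson")
  # reconstruct mu from the Breslow baseline
  bl <- breslow_baseline(d, beta)
  eta <- drop(d$X %*% beta)
  mu <- vapply(seq_along(eta), function(i) {
    b <- bl[bl$trans == d$strata[i], ]
    exp(eta[i]) * sum(b$increment[b$time > d$tstart[i] &
                                    b$time <= d$tstop[i]])
  }, numeric(1))
  expect_equal(Hp, -crossprod(d$X * sqrt(mu)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("transitions without events contribute nothing", {
  ch <- state_chart(c("a", "b", "c"), rbind(c(1L, 2L), c(1L, 3L)))
  dat <- data.frame(id = 1:4, trans = c(1L, 1L, 2L, 2L), Tstart = 0,
                    Tstop = c(1, 2, 1, 2), status = c(1L, 1L, 0L, 0L),
                    x = c(1, 0, 1, 0))
  d <- expand_design(dat, ch)
  bl <- breslow_baseline(d, c(0.3, 0.1))
  expect_true(all(bl$trans == 1))
  H <- msm_hessian(d, c(0.3, 0.1))
  expect_equal(H[2, 2], 0)
})
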