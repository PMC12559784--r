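test_that("the AML scenario config carries the benchmark truth", {
  cfg <- aml_dgp()
  expect_equal(cfg$N, 1000L)
  expect_equal(cfg$baseline_hazards, rep(0.05, 8))
  tb <- cfg$true_beta
  expect_equal(tb[1, 1], 1.5)
  expect_equal(tb[1, 3], 1.2); expect_equal(tb[1, 7], 1.2)
  expect_equal(tb[1, 4], -0.8); expect_equal(tb[1, 8], -0.8)
  expect_equal(tb[1, c(2, 5, 6)], rep(0, 3))
  expect_equal(tb[2, ], rep(0, 8))
  expect_equal(sum(true_beta_vector(cfg) != 0), 5)  # d = 5
})

test_that("simulated paths honour the at-risk row contract", {
  cfg <- aml_dgp(N = 80)
  dat <- simulate_paths(cfg, seed = 5)
  expect_silent(validate_long_format(dat, cfg$chart))
  # one status = 1 row per completed sojourn; all subjects absorbed
  per_sojourn <- tapply(dat$status, paste(dat$id, dat$Tstart), sum)
  expect_true(all(per_sojourn == 1))
  vis <- attr(dat, "visits")
  last <- vis[!duplicated(vis$id, fromLast = TRUE), ]
  expect_true(all(last$next_state %in% cfg$chart$absorbing))
  # covariates constant within subject
  expect_true(all(tapply(dat$X1, dat$id, function(x) length(unique(x))) == 1))
})

test_that("simulation is reproducible and seeds are per-replicate", {
  cfg <- aml_dgp(N = 40)
  a <- simulate_paths(cfg, seed = 9)
  b <- simulate_paths(cfg, seed = 9)
  expect_identical(a, b)
  c1 <- simulate_paths(cfg, seed = 10)
  expect_false(identical(a$Tstop, c1$Tstop))
})

test_that("visits round-trip through the wide-to-long converter", {
  cfg <- aml_dgp(N = 30)
  dat <- simulate_paths(cfg, seed = 77)
  vis <- attr(dat, "visits")
  covs <- unique(data.frame(id = dat$id, X1 = dat$X1, X2 = dat$X2))
  rebuilt <- visits_to_long(vis, covs, cfg$chart)
  expect_equal(rebuilt$trans, dat$trans)
  expect_equal(rebuilt$Tstart, dat$Tstart)
  expect_equal(rebuilt$Tstop, dat$Tstop)
  expect_equal(rebuilt$status, dat$status)
  expect_equal(rebuilt$X1, dat$X1)
})

test_that("sojourns and destinations follow the competing-risks race", {
  # two exits from state 1 with equal hazards 0.05 and no covariate effect
  ch <- state_chart(c("s1", "s2", "s3"), rbind(c(1L, 2L), c(1L, 3L)))
  cfg <- dgp_config(ch, baseline_hazards = 0.05,
                    true_beta = matrix(0, 1, 2), N = 4000)
  dat <- simulate_paths(cfg, seed = 123)
  soj <- dat$Tstop[dat$trans == 1]
  expect_equal(mean(soj), 10, tolerance = 3 * 10 / sqrt(4000) / 10)
  p1 <- mean(dat$status[dat$trans == 1])
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("covariate effects tilt the race as exp(beta)", {
  ch <- state_chart(c("s1", "s2", "s3"), rbind(c(1L, 2L), c(1L, 3L)))
  beta <- matrix(c(1.5, 0), 1, 2)
  cfg <- dgp_config(ch, 0.05, beta, N = 6000)
  dat <- simulate_paths(cfg, seed = 321)
  x <- dat$X1[dat$trans == 1]
  d1 <- dat$status[dat$trans == 1]
  p_hat <- mean(d1[x == 1])
  p_true <- 0.05 * exp(1.5) / (0.05 * exp(1.5) + 0.05)
  n1 <- sum(x == 1)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n1))
})

test_that("an administrative horizon censors instead of absorbing", {
  cfg <- aml_dgp(N = 60)
  cfg$max_time <- 5
  dat <- simulate_paths(cfg, seed = 6)
  expect_true(all(dat$Tstop <= 5))
  at_horizon <- dat$Tstop == 5
  expect_true(all(dat$status[at_horizon] == 0))
})

test_that("replicated studies are reproducible and isolable", {
  cfg <- aml_dgp(N = 60)
  lams <- default_lambda_grid(n = 4, min = 5, max = 100)
  s1 <- run_study(cfg, nsim = 2, base_seed = 50, lambdas = lams,
                  methods = c("unpenalized", "lasso"))
  s2 <- run_study(cfg, nsim = 2, base_seed = 50, lambdas = lams,
                  methods = c("unpenalized", "lasso"))
  expect_identical(s1$results, s2$results)
  # replicate 2 rerun in isolation gives identical rows
  s3 <- run_study(cfg, nsim = 2, base_seed = 50, lambdas = lams,
                  methods = c("unpenalized", "lasso"), replicates = 2)
  r2 <- s1$results[s1$results$replicate == 2, ]
  rownames(r2) <- NULL
  expect_equal(s3$results, r2)
  summ <- summarize_study(s1)
  expect_true(all(c("selection", "estimation", "coefficients", "tuning")
                  %in% names(summ)))
})
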