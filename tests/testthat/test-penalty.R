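test_that("penalty structure blocks match the small worked example", {
  ch <- state_chart(c("s1", "s2", "s3"), rbind(c(1L, 2L), c(1L, 3L)),
                    similar_pairs = rbind(c(1L, 2L)))
  ps <- penalty_structure(ch, P = 2)
  expect_equal(ps$s, 2)       # one contrast per (pair, covariate)
  expect_equal(ps$M, 10)      # 4 lasso + 2 fusion + 4 group rows
  # first fusion contrast couples covariate 1 on transitions 1 and 2
  expect_equal(unname(ps$K[5, ]), c(1, -1, 0, 0))
  expect_equal(unname(ps$K[6, ]), c(0, 0, 1, -1))
  # group block of transition 1 selects beta[1,1] and beta[2,1]
  g1 <- ps$K[ps$group_rows[[1]], ]
  expect_equal(unname(g1), rbind(c(1, 0, 0, 0), c(0, 0, 1, 0)))
  # lasso block is the identity
  expect_equal(unname(ps$K[1:4, ]), diag(4))
  expect_true(all(ps$K %in% c(-1, 0, 1)))
})

test_that("AML penalty structure has M = 16 + 4 + 16", {
  ps <- penalty_structure(aml_state_chart(), P = 2)
  expect_equal(ps$s, 4)
  expect_equal(ps$M, 36)
  expect_equal(qr(ps$K)$rank, 16)  # lasso block alone gives full column rank
  ev <- eigen(ps$KtK, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("penalty value matches the printed formula and block identity", {
  ps <- penalty_structure(aml_state_chart(), P = 2)
  b <- numeric(16)
  expect_equal(penalty_value(b, ps, 1, 1, 1), 0)
  b[stack_index(1, 1, 8)] <- 2
  expect_equal(penalty_value(b, ps, 1, 1, 1), 2)  # pure lasso
  # identical fused coefficients contribute no fusion term
  b2 <- numeric(16)
  b2[stack_index(1, 3, 8)] <- b2[stack_index(1, 7, 8)] <- 1.3
  expect_equal(penalty_value(b2, ps, 1, 1, 0), 0)

  # random beta: block decomposition oracle computed straight from K rows
  set.seed(20)
  for (r in 1:5) {
    beta <- rnorm(16)
    lam <- runif(1, 0.1, 5); a <- runif(1); g <- runif(1)
    Kb <- drop(ps$K %*% beta)
    oracle <- lam * a * g * sum(abs(Kb[1:16])) +
      lam * (1 - g) * sum(abs(Kb[17:20])) +
      lam * (1 - a) * g * sum(vapply(ps$group_rows, function(gr)
        sqrt(2) * sqrt(sum(Kb[gr]^2)), numeric(1)))
    expect_equal(penalty_value(beta, ps, lam, a, g), oracle,
                 tolerance = 1e-12)
    # convexity and positive homogeneity
    beta2 <- rnorm(16); t <- runif(1)
    expect_lte(penalty_value(t * beta + (1 - t) * beta2, ps, lam, a, g),
               t * penalty_value(beta, ps, lam, a, g) +
                 (1 - t) * penalty_value(beta2, ps, lam, a, g) + 1e-10)
    s <- runif(1, 0, 3)
    expect_equal(penalty_value(s * beta, ps, lam, a, g),
                 s * penalty_value(beta, ps, lam, a, g), tolerance = 1e-10)
  }
})

test_that("unpenalized covariates are excluded from every block", {
  ps <- penalty_structure(aml_state_chart(), P = 2, unpenalized = 2)
  expect_equal(ps$zeta[stack_index(2, 1:8, 8)], rep(0, 8))
  expect_equal(ps$zeta[stack_index(1, 1:8, 8)], rep(1, 8))
  expect_equal(ps$s, 2)                     # fusion only for covariate 1
  expect_equal(ps$M, 16 + 2 + 8)            # group blocks shrink to size 1
  # no fusion or group row touches covariate 2's columns
  cols2 <- stack_index(2, 1:8, 8)
  expect_true(all(ps$K[-(1:16), cols2] == 0))
  expect_equal(ps$group_weights, rep(1, 8))
})

test_that("hyperparameter corners map to the classical penalties", {
  expect_equal(reduction_mode(1, 1), "global-lasso")
  expect_equal(reduction_mode(0, 1), "group")
  expect_equal(reduction_mode(1, 0), "fusion")
  expect_equal(reduction_mode(0, 0), "fusion")
  expect_equal(reduction_mode(0.75, 0.5), "mixed")
})

test_that("triplet export reproduces K", {
  ps <- penalty_structure(aml_state_chart(), P = 2)
  tr <- penalty_triplets(ps)
  K2 <- matrix(0, ps$M, 16)
  K2[cbind(tr$row, tr$col)] <- tr$value
  expect_equal(K2, unname(ps$K))
})
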