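# Shared fixtures and independent oracles for the test suite.

# Toy single-transition design: two subjects, x = (1, 0), subject 1 fails at
# t = 1, subject 2 at t = 2, no censoring.
toy_design <- function() {
  chart <- state_chart(c("a", "b"), rbind(c(1L, 2L)))
  dat <- data.frame(id = 1:2, trans = 1L, Tstart = 0, Tstop = c(1, 2),
                    status = 1L, x = c(1, 0))
  expand_design(dat, chart)
}

# Random small long-format tables for property-style tests: rows are
# independent (id, transition, interval, covariates) tuples, which is all the
# stratified partial likelihood sees.
random_design <- function(n = 40, P = 2, Q = 3, seed = 1) {
  set.seed(seed)
  chart <- state_chart(as.character(seq_len(Q + 1)),
                       cbind(rep(1L, Q), 2:(Q + 1L)))
  dat <- data.frame(id = seq_len(n),
                    trans = sample.int(Q, n, replace = TRUE),
                    Tstart = round(stats::runif(n, 0, 2), 2),
                    status = stats::rbinom(n, 1, 0.6))
  dat$Tstop <- dat$Tstart + round(stats::runif(n, 0.1, 3), 2)
  for (p in seq_len(P)) dat[[paste0("x", p)]] <- round(stats::rnorm(n), 2)
  list(design = expand_design(dat, chart), chart = chart, data = dat)
}

# Direct risk-set enumeration of the negative log partial likelihood
# (Breslow ties), independent of the package's cumulative-sum path.
naive_nll <- function(design, beta) {
  eta <- drop(design$X %*% beta)
  total <- 0
  for (i in seq_along(design$delta)) {
    if (design$delta[i] == 0) next
    t <- design$tstop[i]
    risk <- design$strata == design$strata[i] &
      design$tstart < t & design$tstop >= t
    total <- total - eta[i] + log(sum(exp(eta[risk])))
  }
  total
}

fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Small AML-scenario dataset shared across solver tests.
aml_test_design <- function(N = 250, seed = 42) {
  dat <- simulate_paths(aml_dgp(N = N), seed = seed)
  expand_design(dat, aml_state_chart())
}
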