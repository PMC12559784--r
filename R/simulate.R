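#' Configuration of the multi-state data-generating process
#'
#' The simulator draws event histories from transition-specific proportional
#' hazards with constant baselines, as a nested series of competing-risks
#' experiments: in each transient state the sojourn time is exponential with
#' the sum of the outgoing transition hazards
#' `h_q(x) = h0_q * exp(beta_q' x)`, and the destination is drawn with
#' probabilities proportional to the individual hazards.
#'
#' @param chart A `state_chart`.
#' @param baseline_hazards Constant baseline hazard per transition (recycled).
#' @param true_beta `P x Q` matrix of true coefficients (`true_beta[p, q]` is
#'   the effect of covariate `p` on transition `q`).
#' @param covariate_law List of per-covariate generators; each element is
#'   either a function `n -> numeric(n)` or a list like
#'   `list(dist = "bernoulli", p = 0.5)` (also supported: `"normal"` with
#'   `mean`, `sd`).
#' @param N Number of subjects.
#' @param start_state Initial state of every subject.
#' @param max_time Optional administrative censoring horizon (default `NULL`:
#'   no censoring, paths run to absorption).
#' @param seed Optional integer seed drawn on at simulation time.
#' @return A list of class `dgp_config`.
#' @export
dgp_config <- function(chart, baseline_hazards, true_beta,
                       covariate_law = NULL, N = 1000, start_state = 1,
                       max_time = NULL, seed = NULL) {
  chart <- validate_state_chart(chart)
  Q <- n_transitions(chart)
  baseline_hazards <- rep_len(baseline_hazards, Q)
  stopifnot(all(baseline_hazards > 0))
  true_beta <- as.matrix(true_beta)
  stopifnot(ncol(true_beta) == Q, all(is.finite(true_beta)))
  P <- nrow(true_beta)
  if (is.null(covariate_law))
    covariate_law <- rep(list(list(dist = "bernoulli", p = 0.5)), P)
  stopifnot(length(covariate_law) == P)
  structure(list(chart = chart, baseline_hazards = baseline_hazards,
                 true_beta = true_beta, covariate_law = covariate_law,
                 N = as.integer(N), start_state = as.integer(start_state),
                 max_time = max_time, seed = seed),
            class = "dgp_config")
}

#' The nine-state AML simulation scenario
#'
#' The packaged benchmark scenario: the [aml_state_chart()], constant
#' baseline hazards 0.05 on all eight transitions, two independent
#' Bernoulli(0.5) biomarkers, and true effects of the first biomarker
#' `beta[1,1] = 1.5`, `beta[1,3] = beta[1,7] = 1.2`,
#' `beta[1,4] = beta[1,8] = -0.8`, zero elsewhere; the second biomarker has
#' no effect on any transition. Five coefficients are truly nonzero.
#'
#' @param N Number of subjects (default 1000).
#' @param seed Optional seed stored in the config.
#' @return A `dgp_config`.
#' @export
aml_dgp <- function(N = 1000, seed = NULL) {
  beta <- matrix(0, 2, 8)
  beta[1, 1] <- 1.5
  beta[1, 3] <- beta[1, 7] <- 1.2
  beta[1, 4] <- beta[1, 8] <- -0.8
  dgp_config(aml_state_chart(), baseline_hazards = 0.05, true_beta = beta,
             N = N, seed = seed)
}

#' True stacked coefficient vector of a DGP configuration
#'
#' @param cfg A `dgp_config`.
#' @return Numeric vector of length `P * Q` in covariate-major stacking.
#' @export
true_beta_vector <- function(cfg) {
  as.vector(t(cfg$true_beta))
}

draw_covariates <- function(law, n) {
  vapply(law, function(l) {
    if (is.function(l)) return(l(n))
    switch(l$dist,
           bernoulli = stats::rbinom(n, 1, l$p),
           normal = stats::rnorm(n, l$mean %||% 0, l$sd %||% 1),
           stop("unknown covariate distribution: ", l$dist))
  }, numeric(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate multi-state event histories
#'
#' Draws covariates, then walks each subject through the state chart:
#' from the current state, the sojourn time is exponential with the summed
#' outgoing hazards and the destination is a categorical draw proportional
#' to the individual transition hazards (equivalent to the minimum of
#' per-transition exponential clocks). Walks stop in absorbing states or at
#' the administrative horizon. Returns long-format data with one row per
#' at-risk transition per sojourn.
#'
#' @param cfg A `dgp_config`.
#' @param seed Optional seed; overrides `cfg$seed`.
#' @return Long-format data frame (see [validate_long_format()]) with
#'   covariate columns `X1..XP` and attribute `visits` holding the
#'   per-subject state history.
#' @export
simulate_paths <- function(cfg, seed = NULL) {
  seed <- seed %||% cfg$seed
  if (!is.null(seed)) set.seed(seed)
  chart <- cfg$chart
  tr <- chart$transitions
  Q <- nrow(tr); P <- nrow(cfg$true_beta); N <- cfg$N
  Z <- draw_covariates(cfg$covariate_law, N)
  colnames(Z) <- paste0("X", seq_len(P))
  # per-transition subject hazards h_q(x) = h0_q * exp(beta_q' x)
  H <- exp(Z %*% cfg$true_beta) *
    matrix(cfg$baseline_hazards, N, Q, byrow = TRUE)

  state <- rep(cfg$start_state, N)
  time <- rep(0, N)
  active <- rep(TRUE, N)
  rows <- list()
  visits <- list()
  transient <- setdiff(seq_along(chart$states), chart$absorbing)
  wave <- 0L
  while (any(active)) {
    wave <- wave + 1L
    for (st in transient) {
      subj <- which(active & state == st)
      if (length(subj) == 0) next
      qs <- which(tr[, 1] == st)
      rates <- H[subj, qs, drop = FALSE]
      total <- rowSums(rates)
      sojourn <- stats::rexp(length(subj), rate = total)
      # categorical destination draw proportional to transition hazards
      uu <- stats::runif(length(subj)) * total
      cum <- rates
      if (ncol(cum) > 1)
        for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1] + cum[, j]
      pick <- pmin(rowSums(cum < uu) + 1L, length(qs))
      q_real <- qs[pick]
      exit <- time[subj] + sojourn
      censored <- rep(FALSE, length(subj))
      if (!is.null(cfg$max_time)) {
        censored <- exit > cfg$max_time
        exit[censored] <- cfg$max_time
      }
      for (j in seq_along(qs)) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = subj, trans = qs[j], Tstart = time[subj], Tstop = exit,
          status = as.integer(!censored & q_real == qs[j]))
      }
      visits[[length(visits) + 1L]] <- data.frame(
        id = subj, state = st, entry = time[subj], exit = exit,
        next_state = ifelse(censored, NA_integer_, tr[q_real, 2]))
      time[subj] <- exit
      state[subj] <- ifelse(censored, state[subj], tr[q_real, 2])
      active[subj] <- !censored & !(state[subj] %in% chart$absorbing)
    }
    if (wave > 10000L) stop("path generation did not reach absorption; ",
                            "set max_time for cyclic charts")
  }
  long <- do.call(rbind, rows)
  long <- cbind(long, Z[long$id, , drop = FALSE])
  long <- long[order(long$id, long$Tstart, long$trans), , drop = FALSE]
  rownames(long) <- NULL
  vis <- do.call(rbind, visits)
  vis <- vis[order(vis$id, vis$entry), , drop = FALSE]
  rownames(vis) <- NULL
  attr(long, "visits") <- vis
  long
}
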