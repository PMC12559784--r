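# Stacked multi-state Cox partial likelihood and derivatives.
#
# The multi-state partial likelihood factorizes over transitions as a product
# of stratified Cox partial likelihoods on the long-format rows, with risk
# sets restricted by left truncation: row l is at risk at event time t of its
# transition iff Tstart_l < t <= Tstop_l. All risk-set sums are accumulated
# via cumulative sums over rows sorted by entry/exit time (O(n log n)), with
# max-subtraction for overflow safety. Ties are handled by Breslow's method
# throughout, matching the Breslow baseline estimator.

# One-off precomputation per design: everything that depends on times and the
# sparsity pattern only, so each likelihood evaluation at a new beta is a few
# cumulative sums per stratum.
cox_precompute <- function(design) {
  P <- design$P; Q <- design$Q
  strata <- design$strata
  pre <- vector("list", Q)
  for (q in seq_len(Q)) {
    rows <- which(strata == q)
    if (length(rows) == 0) { pre[[q]] <- NULL; next }
    Zq <- design$Z[rows, , drop = FALSE]
    start <- design$tstart[rows]; stop <- design$tstop[rows]
    status <- design$delta[rows]
    ord_stop <- order(stop); ord_start <- order(start)
    ss <- stop[ord_stop]; st <- start[ord_start]
    ev <- which(status == 1L)
    tj <- sort(unique(stop[ev]))
    dj <- as.numeric(tabulate(match(stop[ev], tj), nbins = length(tj)))
    pre[[q]] <- list(
      rows = rows, Z = Zq, start = start, stop = stop, status = status,
      ord_stop = ord_stop, ord_start = ord_start,
      ev = ev, tj = tj, dj = dj,
      # of rows with stop (resp. start) strictly before each event time
      pos_stop = findInterval(tj, ss, left.open = TRUE),
      pos_start = findInterval(tj, st, left.open = TRUE),
      sum_z_ev = colSums(Zq[ev, , drop = FALSE]),
      # baseline-hazard interval index per row, for cumulative hazards mu
      k_stop = findInterval(stop, tj),
      k_start = findInterval(start, tj),
      cols = stack_index(seq_len(P), q, Q))
  }
  pre
}

# Core evaluator: negative log partial likelihood, score and Hessian of
# log l(beta), Breslow cumulative hazards mu per row, baseline increments.
cox_eval <- function(design, beta, pre = NULL,
                     what = c("nll", "score", "hessian"),
                     hessian_mode = c("exact", "poisson")) {
  hessian_mode <- match.arg(hessian_mode)
  if (is.null(pre)) pre <- cox_precompute(design)
  P <- design$P; Q <- design$Q; PQ <- P * Q
  need_score <- "score" %in% what || "mu" %in% what
  need_hess <- "hessian" %in% what
  need_mu <- "mu" %in% what || hessian_mode == "poisson"
  nll <- 0
  score <- numeric(PQ)
  hess <- if (need_hess) matrix(0, PQ, PQ) else NULL
  mu <- numeric(length(design$delta))
  baseline <- vector("list", Q)
  for (q in seq_len(Q)) {
    pq <- pre[[q]]
    if (is.null(pq)) next
    bq <- beta[pq$cols]
    eta <- drop(pq$Z %*% bq)
    J <- length(pq$tj)
    if (J == 0) { baseline[[q]] <- list(time = numeric(0), haz = numeric(0)); next }
    cmax <- max(eta)
    w <- exp(eta - cmax)
    cs_stop <- c(0, cumsum(w[pq$ord_stop]))
    cs_start <- c(0, cumsum(w[pq$ord_start]))
    S0 <- cs_start[pq$pos_start + 1L] - cs_stop[pq$pos_stop + 1L]
    nll <- nll + sum(pq$dj * (log(S0) + cmax)) - sum(eta[pq$ev])
    dLam <- pq$dj / (S0 * exp(cmax))
    cumLam <- c(0, cumsum(dLam))
    baseline[[q]] <- list(time = pq$tj, haz = dLam)
    if (need_mu || need_score) {
      mu_q <- exp(eta) * (cumLam[pq$k_stop + 1L] - cumLam[pq$k_start + 1L])
      mu[pq$rows] <- mu_q
    }
    if (need_score || (need_hess && hessian_mode == "exact")) {
      S1 <- matrix(0, J, P)
      for (p in seq_len(P)) {
        wz <- w * pq$Z[, p]
        S1[, p] <- c(0, cumsum(wz[pq$ord_start]))[pq$pos_start + 1L] -
          c(0, cumsum(wz[pq$ord_stop]))[pq$pos_stop + 1L]
      }
      m <- S1 / S0
      if (need_score)
        score[pq$cols] <- pq$sum_z_ev - colSums(pq$dj * m)
      if (need_hess && hessian_mode == "exact") {
        Hq <- matrix(0, P, P)
        for (a in seq_len(P)) for (b in a:P) {
          wzz <- w * pq$Z[, a] * pq$Z[, b]
          S2ab <- c(0, cumsum(wzz[pq$ord_start]))[pq$pos_start + 1L] -
            c(0, cumsum(wzz[pq$ord_stop]))[pq$pos_stop + 1L]
          Hq[a, b] <- Hq[b, a] <- -sum(pq$dj * (S2ab / S0 - m[, a] * m[, b]))
        }
        hess[pq$cols, pq$cols] <- Hq
      }
    }
    if (need_hess && hessian_mode == "poisson") {
      mu_q <- exp(eta) * (cumLam[pq$k_stop + 1L] - cumLam[pq$k_start + 1L])
      hess[pq$cols, pq$cols] <- -crossprod(pq$Z * sqrt(mu_q))
    }
  }
  list(nll = nll, score = score, hessian = hess, mu = mu, baseline = baseline)
}

#' Negative multi-state partial log-likelihood
#'
#' Evaluates `L(beta) = sum_i delta_i [-x_i' beta + log sum_{l in R_i}
#' exp(x_l' beta)]` over the long-format rows, with transition-stratified,
#' left-truncated risk sets and Breslow handling of ties.
#'
#' @param design A `stacked_design` from [expand_design()].
#' @param beta Stacked coefficient vector of length `P * Q`.
#' @return The scalar negative log partial likelihood.
#' @export
msm_nll <- function(design, beta) {
  cox_eval(design, beta, what = "nll")$nll
}

#' Score vector of the multi-state partial log-likelihood
#'
#' Gradient of `log l(beta)` (i.e. minus the gradient of [msm_nll()]).
#' Two algebraically identical forms are available: the classical risk-set
#' weighted-mean accumulation, and `X'(delta - mu)` with the Breslow
#' cumulative-hazard plug-in `mu_i`.
#'
#' @inheritParams msm_nll
#' @param form `"riskset"` (default) or `"breslow"`.
#' @return Numeric vector of length `P * Q`.
#' @export
msm_score <- function(design, beta, form = c("riskset", "breslow")) {
  form <- match.arg(form)
  ev <- cox_eval(design, beta, what = c("nll", "score"))
  if (form == "riskset") return(ev$score)
  as.numeric(crossprod(design$X, design$delta - ev$mu))
}

#' Hessian of the multi-state partial log-likelihood
#'
#' Second derivative matrix of `log l(beta)`; symmetric negative
#' semidefinite and block-diagonal across transitions. `mode = "exact"`
#' returns the exact partial-likelihood Hessian; `mode = "poisson"` returns
#' the first-order Poisson-style approximation `-X' diag(mu) X` built from
#' the Breslow cumulative hazards, useful as a cross-check.
#'
#' @inheritParams msm_nll
#' @param mode `"exact"` (default) or `"poisson"`.
#' @return `PQ x PQ` matrix.
#' @export
msm_hessian <- function(design, beta, mode = c("exact", "poisson")) {
  mode <- match.arg(mode)
  cox_eval(design, beta, what = c("nll", "hessian"),
           hessian_mode = mode)$hessian
}

#' Breslow estimate of the cumulative baseline hazards
#'
#' Per-transition nondecreasing step functions with jumps
#' `d_j / sum_{l in R_j} exp(x_l' beta_q)` at the event times of each
#' transition.
#'
#' @inheritParams msm_nll
#' @return A data frame with columns `trans`, `time`, `increment`, `cumhaz`.
#' @export
breslow_baseline <- function(design, beta) {
  ev <- cox_eval(design, beta, what = "nll")
  out <- lapply(seq_len(design$Q), function(q) {
    b <- ev$baseline[[q]]
    if (is.null(b) || length(b$time) == 0)
      return(data.frame(trans = integer(0), time = numeric(0),
                        increment = numeric(0), cumhaz = numeric(0)))
    data.frame(trans = q, time = b$time, increment = b$haz,
               cumhaz = cumsum(b$haz))
  })
  do.call(rbind, out)
}
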