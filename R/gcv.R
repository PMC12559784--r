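#' Effective number of parameters of a penalized fit
#'
#' Local-quadratic-approximation degrees of freedom
#' `e = tr[(H + Sigma)^(-1) H]`, where `H` is the Hessian of the negative
#' log partial likelihood at the fitted coefficients and `Sigma` the
#' curvature of the locally quadratic approximated penalty, both restricted
#' to the active set (coefficients not estimated as exact zeros). Inactive
#' coefficients contribute zero. In the pure-lasso case `Sigma` reduces to
#' the diagonal `lambda / |beta_j|` form.
#'
#' @param design A `stacked_design`.
#' @param ps A `penalty_structure`.
#' @param fit An `fsgl_fit`.
#' @param sigma_mode `"lqa"` (default): generalized quadratic approximation
#'   `sum_m mult_m w_m / ||K_m beta|| K_m' K_m` over penalty rows with
#'   nonzero argument; `"diagonal"`: its diagonal only.
#' @return Scalar `e` in `[0, PQ]`.
#' @export
effective_parameters <- function(design, ps, fit,
                                 sigma_mode = c("lqa", "diagonal")) {
  sigma_mode <- match.arg(sigma_mode)
  beta <- fit$beta_hat
  active <- which(beta != 0 | ps$zeta == 0)
  if (length(active) == 0) return(0)
  H <- -msm_hessian(design, beta)[active, active, drop = FALSE]
  lev <- penalty_row_levels(ps, fit$lambda, fit$alpha, fit$gamma)
  Sig <- matrix(0, length(active), length(active))
  Kb <- drop(ps$K %*% beta)
  sc <- c(ps$lasso_rows, ps$fusion_rows)
  for (m in sc) {
    if (lev[m] == 0 || abs(Kb[m]) <= 1e-8) next
    km <- ps$K[m, active]
    Sig <- Sig + (lev[m] / abs(Kb[m])) * tcrossprod(km)
  }
  for (q in seq_len(ps$Q)) {
    gr <- ps$group_rows[[q]]
    if (length(gr) == 0 || lev[gr[1]] == 0) next
    nrm <- sqrt(sum(Kb[gr]^2))
    if (nrm <= 1e-8) next
    Kg <- ps$K[gr, active, drop = FALSE]
    Sig <- Sig + (lev[gr[1]] / nrm) * crossprod(Kg)
  }
  if (sigma_mode == "diagonal") Sig <- diag(diag(Sig), nrow = nrow(Sig))
  A <- H + Sig
  e <- tryCatch(sum(diag(solve(A, H))),
                error = function(err) {
                  warning("singular curvature matrix; adding ridge jitter")
                  sum(diag(solve(A + diag(1e-8, nrow(A)), H)))
                })
  min(max(e, 0), ps$P * ps$Q)
}

#' Generalized cross-validation statistic
#'
#' `GCV = L / (N * (1 - e/N)^2)` with `L` the negative log partial
#' likelihood of the fit, `e` the effective number of parameters and `N` the
#' sample size. [fsgl_tune()] calls this with the per-row averaged
#' likelihood `L/N` and `N` the long-format row count; see its `N_mode`
#' argument.
#'
#' @param nll Negative log partial likelihood at the fitted coefficients
#'   (or an average thereof; the argmin over `lambda` is unaffected by
#'   constant scaling).
#' @param e Effective number of parameters.
#' @param N Number of subjects.
#' @return Scalar GCV value.
#' @export
gcv_statistic <- function(nll, e, N) {
  if (e >= N) stop("effective parameters must be smaller than N")
  nll / (N * (1 - e / N)^2)
}

#' Default tuning grids
#'
#' The default overall-level grid has 20 values of `lambda` from 0.01 to 500,
#' equally spaced on a logarithmic scale; the mixing grids cover
#' `{0, 0.25, 0.5, 0.75, 1}`.
#'
#' @param n Number of lambda values.
#' @param min,max Grid range.
#' @return Numeric vector of increasing lambda values.
#' @export
default_lambda_grid <- function(n = 20, min = 0.01, max = 500) {
  exp(seq(log(min), log(max), length.out = n))
}

#' @rdname default_lambda_grid
#' @export
default_mixing_grid <- function() c(0, 0.25, 0.5, 0.75, 1)

#' Tune the FSGL penalty by generalized cross-validation
#'
#' For each `(alpha, gamma)` combination, fits the model along the `lambda`
#' grid and selects the `lambda` minimizing the GCV statistic (ties broken
#' toward the smallest `lambda`, i.e. toward sparsity; note GCV values are
#' generically distinct so ties are a degenerate case). Optionally refines
#' the per-combination optimum by Brent minimization of GCV over the grid
#' interval bracketing the grid minimum.
#'
#' @param design A `stacked_design`.
#' @param ps A `penalty_structure`.
#' @param alphas,gammas Candidate mixing parameters.
#' @param lambdas Increasing positive grid of overall penalty levels.
#' @param control An [admm_control()].
#' @param warm_start Reuse the previous `lambda`'s solution as initialization
#'   while walking the grid from its largest value (default `TRUE`).
#' @param refine Apply Brent refinement of `lambda` around each
#'   per-combination grid minimum (default `FALSE`).
#' @param N_mode Sample size `N` in the GCV statistic: `"rows"` (default)
#'   uses the number of long-format rows — the sample size of the stacked
#'   likelihood, which calibrates the degrees-of-freedom correction to the
#'   likelihood's own scale — while `"subjects"` uses the subject count.
#'   The numerator is the per-unit average `L(beta)/N`, so the two modes
#'   differ in the strength of the effective-parameter correction, not just
#'   by a constant factor.
#' @param keep_fits Keep every fitted model (memory-heavy; default `FALSE`
#'   keeps only the selected fit per combination).
#' @return An object of class `fsgl_tune`: `surface` (data frame with
#'   `alpha`, `gamma`, `lambda`, `gcv`, `e`, `nll`, `n_selected`,
#'   `converged`), `best` (one row per combination with the selected
#'   `lambda`), `fits` (list of selected `fsgl_fit`s keyed by
#'   `"alpha/gamma"`), and `argmin` (overall best row).
#' @export
fsgl_tune <- function(design, ps, alphas = 1, gammas = 1,
                      lambdas = default_lambda_grid(),
                      control = admm_control(), warm_start = TRUE,
                      refine = FALSE, N_mode = c("rows", "subjects"),
                      keep_fits = FALSE) {
  N_mode <- match.arg(N_mode)
  stopifnot(all(diff(lambdas) > 0), all(lambdas > 0))
  N <- if (N_mode == "subjects") design$n_subjects else nrow(design$X)
  combos <- expand.grid(alpha = alphas, gamma = gammas,
                        KEEP.OUT.ATTRS = FALSE)
  surface <- list()
  best <- list()
  fits <- list()
  all_fits <- list()
  eval_fit <- function(fit) {
    e <- effective_parameters(design, ps, fit)
    data.frame(alpha = fit$alpha, gamma = fit$gamma, lambda = fit$lambda,
               gcv = gcv_statistic(fit$nll / N, e, N), e = e, nll = fit$nll,
               n_selected = sum(fit$selected), converged = fit$converged)
  }
  for (ci in seq_len(nrow(combos))) {
    a <- combos$alpha[ci]; g <- combos$gamma[ci]
    rows <- vector("list", length(lambdas))
    cfits <- vector("list", length(lambdas))
    init <- NULL
    for (k in rev(seq_along(lambdas))) {  # large lambda first: sparse, easy
      fit <- suppressWarnings(
        fsgl_fit(design, ps, lambdas[k], a, g, control = control,
                 init = if (warm_start) init else NULL))
      if (warm_start) init <- fit$beta_admm
      rows[[k]] <- eval_fit(fit)
      cfits[[k]] <- fit
    }
    surf <- do.call(rbind, rows)
    kbest <- which(surf$gcv == min(surf$gcv))[1]  # smallest lambda on ties
    sel_fit <- cfits[[kbest]]
    sel_row <- surf[kbest, ]
    if (refine) {
      lo <- lambdas[max(kbest - 1, 1)]
      hi <- lambdas[min(kbest + 1, length(lambdas))]
      if (hi > lo) {
        gcv_of <- function(loglam) {
          f <- suppressWarnings(
            fsgl_fit(design, ps, exp(loglam), a, g, control = control,
                     init = if (warm_start) sel_fit$beta_admm else NULL))
          eval_fit(f)$gcv
        }
        opt <- stats::optimize(gcv_of, c(log(lo), log(hi)))
        if (opt$objective < sel_row$gcv) {
          ref_fit <- suppressWarnings(
            fsgl_fit(design, ps, exp(opt$minimum), a, g, control = control,
                     init = if (warm_start) sel_fit$beta_admm else NULL))
          sel_fit <- ref_fit
          sel_row <- eval_fit(ref_fit)
        }
      }
    }
    key <- paste(a, g, sep = "/")
    fits[[key]] <- sel_fit
    if (keep_fits) all_fits[[key]] <- cfits
    surface[[ci]] <- surf
    best[[ci]] <- sel_row
  }
  surface <- do.call(rbind, surface)
  best <- do.call(rbind, best)
  rownames(surface) <- rownames(best) <- NULL
  structure(list(surface = surface, best = best, fits = fits,
                 all_fits = if (keep_fits) all_fits else NULL,
                 argmin = best[which.min(best$gcv), ]),
            class = "fsgl_tune")
}

#' @export
print.fsgl_tune <- function(x, ...) {
  cat("GCV tuning over", nrow(x$surface), "fits\n")
  cat("Per-combination optima:\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}
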