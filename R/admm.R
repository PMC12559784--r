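#' Control parameters for the ADMM solver
#'
#' Defaults follow the solver settings used throughout the package's
#' simulation study: `rho0 = 1`, adaptive step-size factors `tau = 2`,
#' `eta = 10`, stopping tolerances `eps_abs = 1e-4`, `eps_rel = 1e-2`,
#' `maxiter = 500`, inner Cox-estimation tolerance `tol_inner = 1e-6`, and
#' gradient-descent step `step_gd = 0.01` for the hybrid first step.
#'
#' @param rho0 Initial augmented Lagrangian step size.
#' @param tau Multiplicative factor for adaptive step-size updates (`> 1`).
#' @param eta Residual imbalance ratio that triggers a step-size change.
#' @param eps_abs,eps_rel Absolute and relative stopping tolerances.
#' @param maxiter Maximum number of outer ADMM iterations.
#' @param beta_update `"hybrid"` (single gradient step, then Newton;
#'   default), `"newton"`, or `"gradient"`.
#' @param tol_inner Convergence tolerance of the inner Cox update (change in
#'   the augmented objective).
#' @param step_gd Gradient-descent step size.
#' @param inner_maxiter Cap on inner iterations per beta-update.
#' @param stop_mode `"sqrt"` (default) scales the absolute tolerance with the
#'   square root of the residual dimension, as in the standard ADMM stopping
#'   rule; `"literal"` scales linearly.
#' @param hessian_mode Passed to the likelihood Hessian: `"exact"` or
#'   `"poisson"`.
#' @return A list of class `admm_control`.
#' @export
admm_control <- function(rho0 = 1, tau = 2, eta = 10, eps_abs = 1e-4,
                         eps_rel = 1e-2, maxiter = 500,
                         beta_update = c("hybrid", "newton", "gradient"),
                         tol_inner = 1e-6, step_gd = 0.01,
                         inner_maxiter = 50,
                         stop_mode = c("sqrt", "literal"),
                         hessian_mode = c("exact", "poisson")) {
  stopifnot(rho0 > 0, tau > 1, eta > 0, eps_abs > 0, eps_rel > 0,
            maxiter >= 1, tol_inner > 0, step_gd > 0, inner_maxiter >= 1)
  structure(list(rho0 = rho0, tau = tau, eta = eta, eps_abs = eps_abs,
                 eps_rel = eps_rel, maxiter = as.integer(maxiter),
                 beta_update = match.arg(beta_update),
                 tol_inner = tol_inner, step_gd = step_gd,
                 inner_maxiter = as.integer(inner_maxiter),
                 stop_mode = match.arg(stop_mode),
                 hessian_mode = match.arg(hessian_mode)),
            class = "admm_control")
}

#' Vector soft-thresholding operator
#'
#' `S_kappa(a) = (1 - kappa / ||a||_2)+ * a`, with `S_kappa(0) = 0`. For a
#' scalar argument this is the familiar `sign(a) * (|a| - kappa)+`; for a
#' vector it is the proximal operator of the (group) L2 norm, shrinking the
#' whole block toward zero and mapping it exactly to zero when its norm does
#' not exceed `kappa`.
#'
#' @param a Numeric vector (a scalar is a length-1 vector).
#' @param kappa Nonnegative threshold.
#' @return Shrunk vector of the same length; exact zeros where thresholded.
#' @export
#' @examples
#' soft_threshold(3, 1)        # 2
#' soft_threshold(c(3, 4), 1)  # c(2.4, 3.2)
soft_threshold <- function(a, kappa) {
  stopifnot(kappa >= 0)
  nrm <- sqrt(sum(a^2))
  if (nrm <= kappa) return(rep(0, length(a)))
  (1 - kappa / nrm) * a
}

# Blockwise proximal step: scalar thresholds on lasso/fusion rows, vector
# thresholds on group blocks; rows with level 0 pass through untouched.
admm_theta_update <- function(a, ps, levels, rho) {
  theta <- a
  kap <- levels / rho
  sc <- c(ps$lasso_rows, ps$fusion_rows)
  theta[sc] <- sign(theta[sc]) * pmax(abs(theta[sc]) - kap[sc], 0)
  for (q in seq_len(ps$Q)) {
    gr <- ps$group_rows[[q]]
    if (length(gr) > 0 && kap[gr[1]] > 0)
      theta[gr] <- soft_threshold(a[gr], kap[gr[1]])
  }
  theta
}

# Inner minimization of f(beta) + rho/2 ||K beta - theta + u||^2 by the
# hybrid gradient/Newton scheme with step halving.
admm_beta_update <- function(beta, theta, u, rho, design, pre, ps, control,
                             first_outer = FALSE) {
  K <- ps$K; KtK <- ps$KtK
  aug <- function(b, nll) nll + rho / 2 * sum((drop(K %*% b) - theta + u)^2)
  evalf <- function(b, hess = TRUE) {
    cox_eval(design, b, pre,
             what = if (hess) c("nll", "score", "hessian") else c("nll", "score"),
             hessian_mode = control$hessian_mode)
  }
  gradient_at <- function(b, score)
    -score + rho * drop(KtK %*% b - crossprod(K, theta - u))
  ev <- evalf(beta, hess = FALSE)
  obj <- aug(beta, ev$nll)
  grad <- gradient_at(beta, ev$score)

  if (control$beta_update %in% c("hybrid", "gradient") && first_outer) {
    step <- control$step_gd
    repeat {
      cand <- beta - step * grad
      evc <- evalf(cand, hess = FALSE)
      objc <- aug(cand, evc$nll)
      if (is.finite(objc) && objc <= obj) {
        beta <- cand; ev <- evc; obj <- objc
        grad <- gradient_at(beta, ev$score)
        break
      }
      step <- step / 2
      if (step < 1e-12) break
    }
  }

  newton <- control$beta_update != "gradient"
  for (it in seq_len(control$inner_maxiter)) {
    if (!newton) {
      dir <- -control$step_gd * grad
    } else {
      H <- -evalf(beta, hess = TRUE)$hessian + rho * KtK
      dir <- -tryCatch(
        solve(H, grad),
        error = function(e) solve(H + diag(1e-8, nrow(H)), grad))
    }
    step <- 1
    improved <- FALSE
    for (h in 1:30) {
      cand <- beta + step * dir
      evc <- evalf(cand, hess = FALSE)
      objc <- aug(cand, evc$nll)
      if (is.finite(objc) && objc <= obj + 1e-12) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    delta_obj <- obj - objc
    beta <- cand; ev <- evc; obj <- objc
    grad <- gradient_at(beta, ev$score)
    if (delta_obj < control$tol_inner) break
  }
  list(beta = beta, nll = ev$nll, obj = obj)
}

# Residual-based stopping decision (standard primal/dual rule).
admm_check_stopping <- function(primal, dual, Kb_norm, theta_norm, Ktnu_norm,
                                PQ, M, control) {
  fac1 <- if (control$stop_mode == "sqrt") sqrt(M) else PQ
  fac2 <- if (control$stop_mode == "sqrt") sqrt(PQ) else M
  eps1 <- fac1 * control$eps_abs +
    control$eps_rel * max(Kb_norm, theta_norm)
  eps2 <- fac2 * control$eps_abs + control$eps_rel * Ktnu_norm
  list(stop = primal < eps1 && dual < eps2, eps1 = eps1, eps2 = eps2)
}

# Adaptive step size (residual balancing): grow rho when the primal residual
# dominates, shrink when the dual residual dominates.
admm_adapt_rho <- function(rho, primal, dual, control) {
  if (primal > control$eta * dual) rho * control$tau
  else if (dual > control$eta * primal) rho / control$tau
  else rho
}

#' Fit an FSGL-penalized multi-state Cox model by ADMM
#'
#' Minimizes the penalized negative multi-state partial log-likelihood
#' `L(beta) + p(beta)` by the alternating direction method of multipliers:
#' a smooth beta-update (hybrid gradient/Newton minimization of the augmented
#' Lagrangian), a closed-form proximal theta-update (blockwise
#' soft-thresholding), a dual ascent step, and adaptive step-size balancing.
#' The auxiliary variable `theta` is exactly sparse; the returned coefficient
#' vector is the lasso block of `theta` (with group-zeroed transitions set to
#' zero when the group penalty is active), and the selection mask is derived
#' from its exact zeros.
#'
#' @param design A `stacked_design`.
#' @param ps A `penalty_structure` built for the same chart and covariates.
#' @param lambda,alpha,gamma FSGL hyperparameters (see [penalty_value()]).
#' @param control An [admm_control()] list.
#' @param init Optional initial coefficient vector (warm start); default
#'   zeros.
#' @param trace If `TRUE`, store the per-iteration residual and step-size
#'   path in the result.
#' @return An object of class `fsgl_fit`: `beta_hat` (sparse coefficients on
#'   the scale of the supplied design), `beta_admm` (raw non-sparse beta
#'   iterate), `theta`, `nu` (unscaled dual), `selected` (logical mask over
#'   the `PQ` coefficients), `converged`, `iterations`, `rho`, `nll` (at
#'   `beta_hat`), `primal_res`, `dual_res`, `baseline` (Breslow cumulative
#'   baseline hazards at `beta_hat`), hyperparameters, and optionally
#'   `trace`.
#' @export
fsgl_fit <- function(design, ps, lambda, alpha, gamma,
                     control = admm_control(), init = NULL, trace = FALSE) {
  check_hyperparams(lambda, alpha, gamma)
  if (sum(design$delta) == 0) stop("no events in the data")
  PQ <- ps$P * ps$Q
  stopifnot(ncol(design$X) == PQ)
  pre <- cox_precompute(design)
  K <- ps$K; M <- ps$M
  levels <- penalty_row_levels(ps, lambda, alpha, gamma)

  beta <- if (is.null(init)) numeric(PQ) else as.numeric(init)
  theta <- drop(K %*% beta)
  u <- numeric(M)
  rho <- control$rho0
  converged <- FALSE
  tr <- if (trace) vector("list", control$maxiter) else NULL
  iter <- 0L
  primal <- dual <- Inf

  for (r in seq_len(control$maxiter)) {
    iter <- r
    bu <- admm_beta_update(beta, theta, u, rho, design, pre, ps, control,
                           first_outer = (r == 1L))
    beta <- bu$beta
    Kb <- drop(K %*% beta)
    theta_old <- theta
    theta <- admm_theta_update(Kb + u, ps, levels, rho)
    u <- u + Kb - theta
    primal <- sqrt(sum((theta - Kb)^2))
    dual <- rho * sqrt(sum(drop(crossprod(K, theta - theta_old))^2))
    nu <- rho * u
    st <- admm_check_stopping(primal, dual, sqrt(sum(Kb^2)),
                              sqrt(sum(theta^2)),
                              sqrt(sum(drop(crossprod(K, nu))^2)),
                              PQ, M, control)
    if (trace)
      tr[[r]] <- c(iter = r, primal = primal, dual = dual, rho = rho,
                   eps1 = st$eps1, eps2 = st$eps2, nll = bu$nll)
    if (st$stop) { converged <- TRUE; break }
    rho_new <- admm_adapt_rho(rho, primal, dual, control)
    if (rho_new != rho) {
      u <- u * rho / rho_new  # preserve the unscaled multiplier
      rho <- rho_new
    }
  }
  if (!converged)
    warning("ADMM did not converge in ", control$maxiter, " iterations")

  beta_hat <- theta[ps$lasso_rows]
  if ((1 - alpha) * gamma > 0) {
    for (q in seq_len(ps$Q)) {
      gr <- ps$group_rows[[q]]
      if (length(gr) > 0 && all(theta[gr] == 0)) {
        zero_cols <- which(apply(ps$K[gr, , drop = FALSE] != 0, 2, any))
        beta_hat[zero_cols] <- 0
      }
    }
  }
  selected <- if (alpha * gamma > 0) beta_hat != 0 & ps$zeta > 0
              else abs(beta_hat) > 1e-8 & ps$zeta > 0
  ev <- cox_eval(design, beta_hat, pre, what = "nll")
  structure(list(
    beta_hat = beta_hat, beta_admm = beta, theta = theta, nu = rho * u,
    selected = selected, converged = converged, iterations = iter,
    rho = rho, nll = ev$nll, primal_res = primal, dual_res = dual,
    baseline = breslow_baseline(design, beta_hat),
    lambda = lambda, alpha = alpha, gamma = gamma,
    trace = if (trace) do.call(rbind, tr[seq_len(iter)]) else NULL),
    class = "fsgl_fit")
}

#' @export
print.fsgl_fit <- function(x, ...) {
  cat(sprintf(
    "FSGL multi-state fit: lambda = %g, alpha = %g, gamma = %g\n",
    x$lambda, x$alpha, x$gamma))
  cat(sprintf("  %d / %d coefficients selected; %s after %d iterations\n",
              sum(x$selected), length(x$beta_hat),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Extract coefficients from an FSGL fit
#'
#' @param object An `fsgl_fit`.
#' @param design Optional `stacked_design`; when supplied (and standardized),
#'   coefficients are mapped back to the original covariate scale.
#' @param ... Unused.
#' @return Named coefficient vector of length `P * Q`.
#' @export
coef.fsgl_fit <- function(object, design = NULL, ...) {
  b <- object$beta_hat
  if (!is.null(design)) {
    b <- unscale_coefficients(b, design)
    names(b) <- colnames(design$X)
  }
  b
}

#' Coefficient table of an FSGL fit
#'
#' @param fit An `fsgl_fit`.
#' @param design The `stacked_design` the model was fitted on.
#' @return Data frame with columns `covariate`, `trans`, `coefficient`
#'   (original scale), `selected`.
#' @export
fit_table <- function(fit, design) {
  P <- design$P; Q <- design$Q
  b <- unscale_coefficients(fit$beta_hat, design)
  idx <- expand.grid(q = seq_len(Q), p = seq_len(P))
  data.frame(covariate = design$covariates[idx$p], trans = idx$q,
             coefficient = b[stack_index(idx$p, idx$q, Q)],
             selected = fit$selected[stack_index(idx$p, idx$q, Q)])
}
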