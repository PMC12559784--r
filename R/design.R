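#' Column index of a coefficient in the stacked parameter vector
#'
#' The stacked regression vector orders coefficients covariate-major:
#' `beta = (beta[1,1], ..., beta[1,Q], beta[2,1], ..., beta[P,Q])`, so the
#' coefficient of covariate `p` on transition `q` sits at `(p - 1) * Q + q`.
#' This single function defines the convention package-wide.
#'
#' @param p Covariate index (1..P), vectorized.
#' @param q Transition index (1..Q), vectorized.
#' @param Q Number of transitions.
#' @return Integer column index into the stacked vector of length `P * Q`.
#' @export
stack_index <- function(p, q, Q) (as.integer(p) - 1L) * as.integer(Q) + as.integer(q)

#' Expand long-format data into the stacked transition-specific design
#'
#' Each long-format row is expanded into a sparse row of the stacked design
#' matrix `X` (`n` rows, `P * Q` columns): the row's `P` covariate values are
#' placed in the columns of its transition, all other entries are zero, so
#' that `X %*% beta` evaluates the transition-specific linear predictor
#' `x' beta_q` for every row.
#'
#' @param data Long-format data frame (see [validate_long_format()]).
#' @param chart A `state_chart`.
#' @param covariates Covariate column names (default: everything after the
#'   five required columns).
#' @return An object of class `stacked_design`: a list with the dense matrix
#'   `X`, the per-row covariate matrix `Z` (`n x P`), `delta` (event
#'   indicators), `strata` (transition per row), `tstart`, `tstop`, `id`,
#'   dimensions `P`, `Q`, `n_subjects`, covariate names, and per-column
#'   `scale_factors` (all 1 until [standardize_design()] is applied).
#' @export
#' @examples
#' ch <- aml_state_chart()
#' dat <- simulate_paths(aml_dgp(N = 50, seed = 1))
#' d <- expand_design(dat, ch)
#' dim(d$X)
expand_design <- function(data, chart, covariates = NULL) {
  data <- validate_long_format(data, chart, covariates)
  covariates <- attr(data, "covariates")
  P <- length(covariates)
  Q <- n_transitions(chart)
  n <- nrow(data)
  Z <- as.matrix(data[, covariates, drop = FALSE])
  dimnames(Z) <- list(NULL, covariates)
  X <- matrix(0, n, P * Q)
  strata <- as.integer(data$trans)
  for (p in seq_len(P)) {
    cols <- stack_index(p, strata, Q)
    X[cbind(seq_len(n), cols)] <- Z[, p]
  }
  colnames(X) <- as.vector(t(outer(covariates, seq_len(Q), paste, sep = ".")))
  structure(list(
    X = X, Z = Z, delta = as.integer(data$status), strata = strata,
    tstart = as.numeric(data$Tstart), tstop = as.numeric(data$Tstop),
    id = data$id, P = P, Q = Q,
    n_subjects = length(unique(data$id)),
    covariates = covariates,
    scale_factors = rep(1, P * Q)),
    class = "stacked_design")
}

#' @export
print.stacked_design <- function(x, ...) {
  cat("Stacked multi-state design:", nrow(x$X), "rows,",
      x$n_subjects, "subjects,", x$P, "covariates x", x$Q,
      "transitions =", x$P * x$Q, "coefficients\n")
  invisible(x)
}

#' Standardize continuous covariate columns of a stacked design
#'
#' Divides the named covariates' columns by their empirical standard deviation
#' (no centering, which would break the sparsity pattern of the stacked rows)
#' so that penalization acts on a common scale. Binary covariates are left
#' untouched by convention. The scale is computed per stacked column, i.e.
#' within each transition's risk rows, and recorded in `scale_factors` so
#' fitted coefficients can be mapped back via [unscale_coefficients()].
#'
#' @param design A `stacked_design`.
#' @param continuous Covariate names or indices to standardize.
#' @return The design with scaled `X`, `Z`, and `scale_factors` updated.
#' @export
standardize_design <- function(design, continuous) {
  if (is.character(continuous)) {
    continuous <- match(continuous, design$covariates)
    if (anyNA(continuous)) stop("unknown covariate in 'continuous'")
  }
  Q <- design$Q
  n <- nrow(design$X)
  for (p in continuous) {
    for (q in seq_len(Q)) {
      rows <- design$strata == q
      if (!any(rows)) next
      j <- stack_index(p, q, Q)
      s <- stats::sd(design$X[rows, j])
      s <- s * sqrt((sum(rows) - 1) / sum(rows))  # population sd
      if (!is.finite(s) || s <= 0)
        stop("zero-variance continuous column: covariate ", p,
             ", transition ", q)
      design$X[rows, j] <- design$X[rows, j] / s
      design$Z[rows, p] <- design$Z[rows, p] / s
      design$scale_factors[j] <- design$scale_factors[j] * s
    }
  }
  design
}

#' Map coefficients fitted on the standardized scale back to original scale
#'
#' @param beta Coefficient vector of length `P * Q` on the standardized scale.
#' @param design The `stacked_design` whose `scale_factors` were recorded by
#'   [standardize_design()].
#' @return Coefficients on the original covariate scale
#'   (`beta / scale_factors`), leaving every linear predictor unchanged.
#' @export
unscale_coefficients <- function(beta, design) {
  beta / design$scale_factors
}
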