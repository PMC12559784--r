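#' Build the fused sparse-group lasso penalty structure
#'
#' Assembles the penalty structure matrix `K` whose rows/blocks are the
#' arguments of the three FSGL penalty terms, in fixed block order:
#' \describe{
#'   \item{lasso block}{`P * Q` unit rows, one per coefficient; rows of
#'     unpenalized covariates get penalty scaling factor `zeta = 0` (they
#'     pass through the proximal step unshrunk).}
#'   \item{fusion block}{one `(+1, -1)` contrast row per (similar transition
#'     pair, penalized covariate), penalizing `|beta[p,q] - beta[p,q']|`.}
#'   \item{group blocks}{one block per transition selecting the penalized
#'     coefficients of that transition, penalized through the group L2 norm
#'     with weight `w_q`.}
#' }
#' Columns follow the covariate-major stacking of [stack_index()]. With no
#' unpenalized covariates `K` has `M = PQ + |S| * P + PQ` rows.
#'
#' @param chart A `state_chart` supplying `Q` and the similar pairs `S`.
#' @param P Number of covariates.
#' @param unpenalized Integer indices (in `1..P`) of covariates excluded from
#'   all three penalty blocks (e.g. established clinical predictors).
#' @param group_weight `"sqrt"` (default) for the standard group-lasso weight
#'   `sqrt(group size)`, or `"size"` for the literal group size.
#' @return An object of class `penalty_structure`: list with matrix `K`,
#'   row-block labels `block` (`"lasso"`, `"fusion"`, `"group"`), `zeta`
#'   (length `PQ` penalty scaling factors), `group_rows` (list of row index
#'   vectors, one per transition with a nonempty block), `group_weights`,
#'   `fusion_rows`, `lasso_rows`, and dimensions `P`, `Q`, `M`, `s`.
#' @export
#' @examples
#' ps <- penalty_structure(aml_state_chart(), P = 2)
#' ps$M  # 16 + 4 + 16
penalty_structure <- function(chart, P, unpenalized = integer(0),
                              group_weight = c("sqrt", "size")) {
  group_weight <- match.arg(group_weight)
  stopifnot(P >= 1)
  chart <- validate_state_chart(chart)
  Q <- n_transitions(chart)
  PQ <- P * Q
  if (length(unpenalized) > 0 &&
      (any(unpenalized < 1) || any(unpenalized > P)))
    stop("unpenalized covariate index outside 1..P")
  pen_cov <- setdiff(seq_len(P), unpenalized)
  Ppen <- length(pen_cov)
  sp <- chart$similar_pairs
  s <- nrow(sp) * Ppen

  zeta <- rep(1, PQ)
  for (p in unpenalized) zeta[stack_index(p, seq_len(Q), Q)] <- 0

  # lasso block: identity on all PQ coefficients
  K_lasso <- diag(PQ)

  # fusion block: one contrast per (pair, penalized covariate)
  K_fusion <- matrix(0, s, PQ)
  r <- 0L
  if (nrow(sp) > 0) {
    for (k in seq_len(nrow(sp))) {
      for (p in pen_cov) {
        r <- r + 1L
        K_fusion[r, stack_index(p, sp[k, 1], Q)] <- 1
        K_fusion[r, stack_index(p, sp[k, 2], Q)] <- -1
      }
    }
  }

  # group blocks: penalized coefficients of each transition
  K_group <- matrix(0, Ppen * Q, PQ)
  group_rows <- vector("list", Q)
  r <- 0L
  for (q in seq_len(Q)) {
    idx <- integer(Ppen)
    for (j in seq_along(pen_cov)) {
      r <- r + 1L
      K_group[r, stack_index(pen_cov[j], q, Q)] <- 1
      idx[j] <- r
    }
    group_rows[[q]] <- PQ + s + idx
  }
  gw <- if (group_weight == "sqrt") sqrt(Ppen) else Ppen

  K <- rbind(K_lasso, K_fusion, K_group)
  M <- nrow(K)
  structure(list(
    K = K, M = M, s = s, P = P, Q = Q,
    block = c(rep("lasso", PQ), rep("fusion", s), rep("group", Ppen * Q)),
    zeta = zeta, pen_cov = pen_cov, unpenalized = as.integer(unpenalized),
    lasso_rows = seq_len(PQ),
    fusion_rows = if (s > 0) PQ + seq_len(s) else integer(0),
    group_rows = group_rows,
    group_weights = rep(gw, Q),
    KtK = crossprod(K)),
    class = "penalty_structure")
}

#' @export
print.penalty_structure <- function(x, ...) {
  cat("FSGL penalty structure: K is", x$M, "x", x$P * x$Q,
      "(", length(x$lasso_rows), "lasso +", x$s, "fusion +",
      x$M - length(x$lasso_rows) - x$s, "group rows )\n")
  if (length(x$unpenalized) > 0)
    cat("Unpenalized covariates:", paste(x$unpenalized, collapse = ", "), "\n")
  invisible(x)
}

# Per-row soft-threshold levels kappa_m = lambda_m * w_m / rho, vectorized
# over blocks: lasso rows lambda*alpha*gamma*zeta, fusion rows
# lambda*(1-gamma), group blocks lambda*(1-alpha)*gamma*w_q.
penalty_row_levels <- function(ps, lambda, alpha, gamma) {
  PQ <- ps$P * ps$Q
  lev <- numeric(ps$M)
  lev[ps$lasso_rows] <- lambda * alpha * gamma * ps$zeta
  lev[ps$fusion_rows] <- lambda * (1 - gamma)
  for (q in seq_len(ps$Q)) {
    gr <- ps$group_rows[[q]]
    if (length(gr) > 0)
      lev[gr] <- lambda * (1 - alpha) * gamma * ps$group_weights[q]
  }
  lev
}

#' Evaluate the FSGL penalty function
#'
#' `p(beta) = lambda * [ alpha*gamma * sum |beta[p,q]| + (1-gamma) *
#' sum_{(q,q') in S} sum_p |beta[p,q] - beta[p,q']| + (1-alpha)*gamma *
#' sum_q w_q * ||beta_q||_2 ]`, with all sums restricted to penalized
#' coefficients and lasso terms weighted by the scaling factors `zeta`.
#'
#' @param beta Stacked coefficient vector (`P * Q`).
#' @param ps A `penalty_structure`.
#' @param lambda Overall regularization level, `> 0` (0 allowed, giving 0).
#' @param alpha Balance between global lasso (`alpha = 1`) and group penalty
#'   (`alpha = 0`), in `[0, 1]`.
#' @param gamma Balance between sparse penalties (`gamma = 1`) and the fusion
#'   penalty (`gamma = 0`), in `[0, 1]`.
#' @return Scalar penalty value.
#' @export
penalty_value <- function(beta, ps, lambda, alpha, gamma) {
  check_hyperparams(lambda, alpha, gamma)
  Kb <- drop(ps$K %*% beta)
  val <- sum(lambda * alpha * gamma * ps$zeta * abs(Kb[ps$lasso_rows]))
  if (ps$s > 0)
    val <- val + lambda * (1 - gamma) * sum(abs(Kb[ps$fusion_rows]))
  for (q in seq_len(ps$Q)) {
    gr <- ps$group_rows[[q]]
    if (length(gr) > 0)
      val <- val + lambda * (1 - alpha) * gamma * ps$group_weights[q] *
        sqrt(sum(Kb[gr]^2))
  }
  val
}

check_hyperparams <- function(lambda, alpha, gamma) {
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  invisible(TRUE)
}

#' Which classical penalty does a hyperparameter pair reduce to?
#'
#' At the corners of the `(alpha, gamma)` square the FSGL penalty collapses
#' to a single classical penalty: `(1,1)` global lasso, `(0,1)` group
#' penalty, `(1,0)` and `(0,0)` fusion penalty; anything else is the mixed
#' penalty.
#'
#' @inheritParams penalty_value
#' @return One of `"global-lasso"`, `"group"`, `"fusion"`, `"mixed"`.
#' @export
reduction_mode <- function(alpha, gamma) {
  if (alpha == 1 && gamma == 1) return("global-lasso")
  if (alpha == 0 && gamma == 1) return("group")
  if (gamma == 0) return("fusion")
  "mixed"
}

#' Export a penalty structure as sparse triplets
#'
#' @param ps A `penalty_structure`.
#' @return Data frame with columns `row`, `col`, `value`, `block` listing the
#'   nonzero entries of `K`.
#' @export
penalty_triplets <- function(ps) {
  nz <- which(ps$K != 0, arr.ind = TRUE)
  out <- data.frame(row = nz[, 1], col = nz[, 2],
                    value = ps$K[nz], block = ps$block[nz[, 1]])
  out[order(out$row, out$col), , drop = FALSE]
}
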