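#' Confusion counts of coefficient selection
#'
#' Elementwise comparison of a selection mask with the true nonzero mask over
#' the `PQ` stacked coefficients.
#'
#' @param selected Logical vector: coefficients selected by the method.
#' @param truth Logical vector: coefficients truly nonzero.
#' @return Named vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(selected, truth) {
  stopifnot(length(selected) == length(truth))
  c(TP = sum(selected & truth), FP = sum(selected & !truth),
    TN = sum(!selected & !truth), FN = sum(!selected & truth))
}

#' True positive rate and false discovery rate
#'
#' `TPR = TP / (TP + FN)`; `FDR = FP / (TP + FP)`, defined as 0 when nothing
#' is selected (no discoveries, hence no false ones).
#'
#' @param counts Named vector from [confusion_counts()].
#' @return Named vector `c(TPR, FDR)`.
#' @export
tpr_fdr <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  tpr <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  fdr <- if (tp + fp == 0) 0 else fp / (tp + fp)
  c(TPR = tpr, FDR = fdr)
}

#' Bias and non-zero mean squared error of coefficient estimates
#'
#' Bias is reported per coefficient (`beta_hat - beta`); the mean squared
#' error is averaged over the `d` truly nonzero coefficients only.
#'
#' @param beta_hat Estimated stacked coefficient vector.
#' @param truth True stacked coefficient vector.
#' @return List with `bias` (vector) and `mse_nz` (scalar).
#' @export
bias_mse_nonzero <- function(beta_hat, truth) {
  stopifnot(length(beta_hat) == length(truth))
  nz <- truth != 0
  if (!any(nz)) stop("no truly nonzero coefficients")
  list(bias = beta_hat - truth,
       mse_nz = mean((beta_hat[nz] - truth[nz])^2))
}

#' Monte Carlo standard error of a simulation aggregate
#'
#' For a mean, the sample standard deviation over replicates divided by
#' `sqrt(nsim)`; for a proportion `p`, `sqrt(p * (1 - p) / nsim)`.
#'
#' @param values Replicate values (for `"mean"`), or the estimated proportion
#'   (scalar, for `"proportion"`).
#' @param statistic `"mean"` or `"proportion"`.
#' @param nsim Number of replicates; required for `"proportion"`, inferred
#'   from `length(values)` for `"mean"`.
#' @return Scalar MCSE.
#' @export
mcse <- function(values, statistic = c("mean", "proportion"), nsim = NULL) {
  statistic <- match.arg(statistic)
  if (statistic == "mean") {
    nsim <- nsim %||% length(values)
    stopifnot(nsim >= 2)
    return(stats::sd(values) / sqrt(nsim))
  }
  stopifnot(!is.null(nsim), length(values) == 1)
  sqrt(values * (1 - values) / nsim)
}

#' Replicates needed for a target selection-rate precision
#'
#' Plans the number of simulation repetitions so that the Monte Carlo
#' standard error of an anticipated true positive rate stays below a target:
#' `nsim = ceiling(tpr * (1 - tpr) / mcse^2)`.
#'
#' @param target_tpr Anticipated true positive rate, in (0, 1).
#' @param target_mcse Largest acceptable MCSE, `> 0`.
#' @return Integer replicate count.
#' @export
#' @examples
#' required_nsim(0.9, 0.02)  # 225
required_nsim <- function(target_tpr, target_mcse) {
  stopifnot(target_tpr > 0, target_tpr < 1, target_mcse > 0)
  as.integer(ceiling(target_tpr * (1 - target_tpr) / target_mcse^2))
}

# Lower median: for an even number of values, the smaller of the two middle
# order statistics (deterministic, always an observed value).
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}
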