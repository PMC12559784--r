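#' Run a replicated multi-state variable-selection study
#'
#' For each replicate: simulate event histories from the data-generating
#' process, then fit the requested methods — unpenalized stacked Cox
#' estimation (`lambda = 0`), the global lasso (`alpha = gamma = 1`) with
#' GCV-selected `lambda`, and the fused sparse-group lasso at a fixed
#' `(alpha, gamma)` combination with GCV-selected `lambda` — and record the
#' coefficient estimates, selection masks and selection/estimation metrics.
#' Each replicate draws from its own seed (`base_seed + replicate`), so any
#' replicate can be re-run in isolation and failures are recorded rather
#' than fatal.
#'
#' @param cfg A `dgp_config` (e.g. [aml_dgp()]).
#' @param nsim Number of replicates.
#' @param base_seed Base seed; replicate `k` uses `base_seed + k`.
#' @param methods Subset of `c("unpenalized", "lasso", "fsgl")`.
#' @param lambdas Lambda grid for the penalized methods.
#' @param fsgl_alpha,fsgl_gamma Mixing parameters of the `"fsgl"` method.
#'   Vectors are allowed: each replicate is then tuned over every
#'   combination and the one with the smallest GCV (at its own selected
#'   `lambda`) provides the FSGL estimate, with the full per-combination
#'   surface kept in the `gcv` table.
#' @param control An [admm_control()].
#' @param warm_start Warm-start the lambda path during tuning.
#' @param unpenalized_covariates Covariate indices left unpenalized.
#' @param replicates Which replicate indices to run (default all of
#'   `1..nsim`); used to resume interrupted studies.
#' @return An object of class `msm_study`: `results` (one row per replicate
#'   and method: `lambda_opt`, `gcv`, `e`, TP/FP/TN/FN, `tpr`, `fdr`,
#'   `mse_nz`, `converged`, `iterations`, `error`), `coefficients` (one row
#'   per replicate, method and coefficient, with estimate, selection flag
#'   and truth), and the study configuration.
#' @export
run_study <- function(cfg, nsim, base_seed = 1,
                      methods = c("unpenalized", "lasso", "fsgl"),
                      lambdas = default_lambda_grid(),
                      fsgl_alpha = 1, fsgl_gamma = 0.25,
                      control = admm_control(), warm_start = TRUE,
                      unpenalized_covariates = integer(0),
                      replicates = seq_len(nsim)) {
  methods <- match.arg(methods, several.ok = TRUE)
  chart <- cfg$chart
  P <- nrow(cfg$true_beta); Q <- n_transitions(chart)
  truth <- true_beta_vector(cfg)
  truth_mask <- truth != 0
  ps <- penalty_structure(chart, P, unpenalized = unpenalized_covariates)
  res_rows <- list(); coef_rows <- list(); gcv_rows <- list()
  coef_names <- as.vector(t(outer(paste0("X", seq_len(P)),
                                  seq_len(Q), paste, sep = ".")))
  record <- function(k, method, fit, lambda_opt = NA, gcv = NA, e = NA,
                     alpha = NA, gamma = NA, err = NA_character_) {
    if (is.null(fit)) {
      res_rows[[length(res_rows) + 1L]] <<- data.frame(
        replicate = k, method = method, alpha = alpha, gamma = gamma,
        lambda_opt = NA, gcv = NA, e = NA,
        TP = NA, FP = NA, TN = NA, FN = NA, tpr = NA, fdr = NA,
        mse_nz = NA, converged = NA, iterations = NA, error = err)
      return(invisible())
    }
    cc <- confusion_counts(fit$selected, truth_mask)
    tf <- tpr_fdr(cc)
    mse_nz <- if (any(truth != 0))
      bias_mse_nonzero(fit$beta_hat, truth)$mse_nz else NA_real_
    res_rows[[length(res_rows) + 1L]] <<- data.frame(
      replicate = k, method = method, alpha = alpha, gamma = gamma,
      lambda_opt = lambda_opt, gcv = gcv,
      e = e, TP = cc[["TP"]], FP = cc[["FP"]], TN = cc[["TN"]],
      FN = cc[["FN"]], tpr = tf[["TPR"]], fdr = tf[["FDR"]],
      mse_nz = mse_nz, converged = fit$converged,
      iterations = fit$iterations, error = err)
    coef_rows[[length(coef_rows) + 1L]] <<- data.frame(
      replicate = k, method = method, coef = coef_names,
      estimate = fit$beta_hat, selected = fit$selected, truth = truth)
  }
  for (k in replicates) {
    data <- simulate_paths(cfg, seed = base_seed + k)
    design <- expand_design(data, chart)
    if ("unpenalized" %in% methods) {
      fit <- tryCatch(
        suppressWarnings(fsgl_fit(design, ps, 0, 1, 1, control = control)),
        error = function(e) e)
      if (inherits(fit, "error")) record(k, "unpenalized", NULL,
                                         err = conditionMessage(fit))
      else record(k, "unpenalized", fit, lambda_opt = 0)
    }
    tune_one <- function(label, a, g) {
      tn <- tryCatch(
        fsgl_tune(design, ps, alphas = a, gammas = g, lambdas = lambdas,
                  control = control, warm_start = warm_start),
        error = function(e) e)
      if (inherits(tn, "error")) {
        record(k, label, NULL, err = conditionMessage(tn))
      } else {
        b <- tn$argmin
        record(k, label, tn$fits[[paste(b$alpha, b$gamma, sep = "/")]],
               lambda_opt = b$lambda, gcv = b$gcv, e = b$e,
               alpha = b$alpha, gamma = b$gamma)
        gcv_rows[[length(gcv_rows) + 1L]] <<-
          cbind(replicate = k, method = label, tn$best)
      }
    }
    if ("lasso" %in% methods) tune_one("lasso", 1, 1)
    if ("fsgl" %in% methods) tune_one("fsgl", fsgl_alpha, fsgl_gamma)
  }
  structure(list(results = do.call(rbind, res_rows),
                 coefficients = do.call(rbind, coef_rows),
                 gcv = do.call(rbind, gcv_rows),
                 truth = truth, coef_names = coef_names,
                 nsim = nsim, base_seed = base_seed,
                 fsgl_alpha = fsgl_alpha, fsgl_gamma = fsgl_gamma),
            class = "msm_study")
}

#' Aggregate study results across replicates
#'
#' Selection aggregates use the lower median across replicates (an observed
#' value even for even replicate counts); estimation aggregates are means
#' with Monte Carlo standard errors.
#'
#' @param study An `msm_study` from [run_study()].
#' @return List with `selection` (per method: median TP/FP/TN/FN counts,
#'   median TPR and FDR with MCSE of the mean), `estimation` (per method:
#'   mean MSE over nonzero coefficients and mean bias with MCSEs),
#'   `coefficients` (per method and coefficient: mean estimate, mean bias,
#'   selection frequency), `tuning` (per method: modal selected lambda,
#'   mean GCV at the optimum), and `gcv_by_combo` (per method and
#'   `(alpha, gamma)` combination: modal selected lambda, mean GCV, and how
#'   often the combination won the per-replicate comparison).
#' @export
summarize_study <- function(study) {
  res <- study$results
  ok <- is.na(res$error) | res$error == ""
  res <- res[ok, , drop = FALSE]
  per_method <- function(df) split(df, df$method)
  selection <- do.call(rbind, lapply(per_method(res), function(d) {
    data.frame(method = d$method[1], n = nrow(d),
               TP = lower_median(d$TP), FP = lower_median(d$FP),
               TN = lower_median(d$TN), FN = lower_median(d$FN),
               tpr_median = lower_median(d$tpr),
               fdr_median = lower_median(d$fdr),
               tpr_mean = mean(d$tpr), fdr_mean = mean(d$fdr),
               tpr_mcse = mcse(d$tpr), fdr_mcse = mcse(d$fdr))
  }))
  estimation <- do.call(rbind, lapply(per_method(res), function(d) {
    data.frame(method = d$method[1], mse_nz_mean = mean(d$mse_nz),
               mse_nz_mcse = mcse(d$mse_nz))
  }))
  cf <- study$coefficients
  coefficients <- do.call(rbind, lapply(split(cf, list(cf$method, cf$coef)),
    function(d) data.frame(method = d$method[1], coef = d$coef[1],
                           truth = d$truth[1],
                           estimate_mean = mean(d$estimate),
                           estimate_median = lower_median(d$estimate),
                           bias_mean = mean(d$estimate - d$truth),
                           bias_mcse = mcse(d$estimate - d$truth),
                           selection_freq = mean(d$selected))))
  rownames(coefficients) <- NULL
  tuning <- do.call(rbind, lapply(per_method(res[res$method != "unpenalized", ,
                                                 drop = FALSE]), function(d) {
    tab <- table(d$lambda_opt)
    data.frame(method = d$method[1],
               lambda_modal = as.numeric(names(tab)[which.max(tab)]),
               gcv_mean = mean(d$gcv))
  }))
  gcv_by_combo <- NULL
  if (!is.null(study$gcv)) {
    g <- study$gcv
    wins <- res[, c("replicate", "method", "alpha", "gamma")]
    gcv_by_combo <- do.call(rbind, lapply(
      split(g, list(g$method, g$alpha, g$gamma), drop = TRUE), function(d) {
        tab <- table(d$lambda)
        won <- sum(wins$method == d$method[1] &
                     wins$alpha == d$alpha[1] & wins$gamma == d$gamma[1],
                   na.rm = TRUE)
        data.frame(method = d$method[1], alpha = d$alpha[1],
                   gamma = d$gamma[1],
                   lambda_modal = as.numeric(names(tab)[which.max(tab)]),
                   gcv_mean = mean(d$gcv), n = nrow(d), n_won = won)
      }))
    rownames(gcv_by_combo) <- NULL
  }
  rownames(selection) <- rownames(estimation) <- NULL
  if (!is.null(tuning)) rownames(tuning) <- NULL
  list(selection = selection, estimation = estimation,
       coefficients = coefficients, tuning = tuning,
       gcv_by_combo = gcv_by_combo)
}
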