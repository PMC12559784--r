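#' Read and write experiment run configurations
#'
#' Run configurations are human-readable YAML files describing a state chart,
#' a data-generating process, tuning grids and solver settings; they
#' round-trip losslessly so that an output directory's manifest suffices to
#' re-run an experiment. Omitted blocks fall back to the package defaults
#' (the benchmark AML scenario and the default grids).
#'
#' @param path YAML file path.
#' @param config A configuration list as returned by `read_run_config`.
#' @return `read_run_config` returns a list with elements `chart`
#'   (`state_chart`), `dgp` (`dgp_config`), `lambdas`, `alphas`, `gammas`,
#'   `control` (`admm_control`), `nsim`, `base_seed`, `unpenalized`, plus the
#'   raw YAML under `raw`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build_run_config(raw)
}

build_run_config <- function(raw) {
  if (is.null(raw$chart)) {
    chart <- aml_state_chart()
  } else {
    chart <- state_chart(
      states = raw$chart$states,
      transitions = do.call(rbind, lapply(raw$chart$transitions, unlist)),
      similar_pairs = if (length(raw$chart$similar_pairs) > 0)
        do.call(rbind, lapply(raw$chart$similar_pairs, unlist)) else NULL)
  }
  d <- raw$dgp
  if (is.null(d)) {
    dgp <- aml_dgp()
  } else {
    tb <- if (!is.null(d$true_beta)) {
      do.call(rbind, lapply(d$true_beta, unlist))
    } else if (is.null(raw$chart) && is.null(d$P)) {
      aml_dgp()$true_beta  # benchmark truth for the default chart
    } else {
      matrix(0, d$P %||% 2, n_transitions(chart))
    }
    law <- if (!is.null(d$covariate_law))
      lapply(d$covariate_law, as.list) else NULL
    dgp <- dgp_config(chart,
                      baseline_hazards = d$baseline_hazards %||% 0.05,
                      true_beta = tb, covariate_law = law,
                      N = d$N %||% 1000,
                      start_state = d$start_state %||% 1,
                      max_time = d$max_time, seed = d$seed)
  }
  g <- raw$grid
  lambdas <- if (!is.null(g$lambdas)) as.numeric(g$lambdas) else
    default_lambda_grid(g$n_lambda %||% 20, g$lambda_min %||% 0.01,
                        g$lambda_max %||% 500)
  ctl <- do.call(admm_control, as.list(raw$admm %||% list()))
  list(chart = chart, dgp = dgp, lambdas = lambdas,
       alphas = as.numeric(raw$grid$alphas %||% default_mixing_grid()),
       gammas = as.numeric(raw$grid$gammas %||% default_mixing_grid()),
       control = ctl, nsim = raw$nsim %||% 225,
       base_seed = raw$base_seed %||% 1,
       unpenalized = as.integer(raw$unpenalized %||% integer(0)),
       fsgl_alpha = raw$fsgl_alpha %||% 1,
       fsgl_gamma = raw$fsgl_gamma %||% 0.25,
       raw = raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  raw <- config$raw %||% config
  yaml::write_yaml(raw, path)
  invisible(path)
}

# Manifest describing an output directory well enough to re-run it.
write_manifest <- function(dir, config_raw, seed, extra = list()) {
  manifest <- c(list(
    package = "fusedmsm",
    version = as.character(utils::packageVersion("fusedmsm")),
    seed = seed, config = config_raw), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
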