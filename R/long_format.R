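#' Validate event-history data in long format
#'
#' Long format holds one row per subject and transition for which the subject
#' is at risk during a sojourn: columns `id`, `trans`, `Tstart`, `Tstop`,
#' `status`, followed by one column per covariate. `status = 1` marks the
#' transition that actually occurred at `Tstop`; all competing at-risk rows of
#' the same sojourn carry `status = 0`.
#'
#' @param data A data frame in long format.
#' @param chart The `state_chart` the transition ids refer to.
#' @param covariates Character vector of covariate column names; default: all
#'   columns after the five required ones.
#' @return `data`, invisibly unchanged, with attribute `covariates` set.
#' @export
validate_long_format <- function(data, chart, covariates = NULL) {
  req <- c("id", "trans", "Tstart", "Tstop", "status")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0) stop("missing required columns: ",
                             paste(miss, collapse = ", "))
  if (is.null(covariates)) covariates <- setdiff(names(data), req)
  if (length(covariates) < 1) stop("at least one covariate column required")
  Q <- n_transitions(chart)
  if (any(data$trans < 1 | data$trans > Q))
    stop("transition id outside 1..", Q)
  if (any(data$Tstart >= data$Tstop))
    stop("Tstart must be strictly smaller than Tstop")
  if (any(data$Tstart < 0)) stop("negative entry time")
  if (!all(data$status %in% c(0, 1))) stop("status must be 0/1")
  for (v in covariates) {
    if (!is.numeric(data[[v]])) stop("covariate column not numeric: ", v)
    if (anyNA(data[[v]])) stop("missing values in covariate: ", v)
  }
  attr(data, "covariates") <- covariates
  invisible(data)
}

#' Convert per-subject state visit histories to long format
#'
#' Builds the "one row per at-risk transition" layout from a table of visited
#' states: for each sojourn in a transient state, one row is emitted per
#' outgoing transition of that state, with `status = 1` on the transition that
#' was realized (if any).
#'
#' @param visits Data frame with columns `id`, `state`, `entry`, `exit`, and
#'   `next_state` (`NA` for a sojourn that ends by censoring).
#' @param covariates Data frame with column `id` and one column per covariate
#'   (one row per subject).
#' @param chart A `state_chart`.
#' @return A long-format data frame.
#' @export
visits_to_long <- function(visits, covariates, chart) {
  tr <- chart$transitions
  out <- vector("list", nrow(visits))
  for (i in seq_len(nrow(visits))) {
    v <- visits[i, ]
    qs <- which(tr[, 1] == v$state)
    if (length(qs) == 0) next
    dest <- tr[qs, 2]
    out[[i]] <- data.frame(
      id = v$id, trans = qs, Tstart = v$entry, Tstop = v$exit,
      status = as.integer(!is.na(v$next_state) & dest == v$next_state))
  }
  long <- do.call(rbind, out)
  long <- merge(long, covariates, by = "id", sort = FALSE)
  long <- long[order(long$id, long$Tstart, long$trans), , drop = FALSE]
  rownames(long) <- NULL
  long
}

#' Read / write long-format event-history data as CSV
#'
#' @param path File path.
#' @param data A long-format data frame.
#' @return `read_long_format` returns the data frame; `write_long_format`
#'   returns `path` invisibly.
#' @export
read_long_format <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' @rdname read_long_format
#' @export
write_long_format <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
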