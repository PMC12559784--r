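#' Define a multi-state model state chart
#'
#' A state chart fixes the structure of a multi-state model: the finite state
#' space, the directed transitions between states, and an optional set of
#' "similar" transition pairs whose covariate effects are candidates for
#' fusion (penalization of their pairwise differences).
#'
#' @param states Character vector of state labels. Position defines the state
#'   number `1..K`.
#' @param transitions Two-column integer matrix (or data frame) with one row
#'   per directed transition; columns are the `from` and `to` state numbers.
#'   Row position defines the transition number `q = 1..Q`.
#' @param similar_pairs Two-column integer matrix (possibly with zero rows) of
#'   unordered pairs of transition numbers assumed to carry effects of similar
#'   magnitude; these pairs receive the fusion penalty.
#' @return An object of class `state_chart` with elements `states`,
#'   `transitions` (integer matrix with columns `from`, `to`), `similar_pairs`,
#'   and the derived `absorbing` set (states with no outgoing transition).
#' @seealso [aml_state_chart()] for the nine-state acute myeloid leukemia
#'   chart used throughout the examples.
#' @export
#' @examples
#' ch <- state_chart(c("healthy", "ill", "dead"),
#'                   rbind(c(1, 2), c(1, 3), c(2, 3)))
#' ch$absorbing
state_chart <- function(states, transitions, similar_pairs = NULL) {
  states <- as.character(states)
  transitions <- as.matrix(transitions)
  storage.mode(transitions) <- "integer"
  colnames(transitions) <- c("from", "to")
  if (is.null(similar_pairs)) {
    similar_pairs <- matrix(integer(0), ncol = 2)
  } else {
    similar_pairs <- matrix(as.integer(as.matrix(similar_pairs)), ncol = 2)
  }
  colnames(similar_pairs) <- c("q1", "q2")
  chart <- structure(
    list(states = states, transitions = transitions,
         similar_pairs = similar_pairs, absorbing = integer(0)),
    class = "state_chart")
  validate_state_chart(chart)
}

#' Validate a state chart
#'
#' Checks the structural invariants of a [state_chart()]: transitions join two
#' distinct existing states, no `(from, to)` pair occurs twice, and every
#' similar pair references two distinct valid transitions. The derived
#' `absorbing` set (states with no outgoing transition) is (re)computed.
#'
#' @param chart A `state_chart`.
#' @return The validated chart, with `absorbing` filled in.
#' @export
validate_state_chart <- function(chart) {
  stopifnot(inherits(chart, "state_chart"))
  K <- length(chart$states)
  tr <- chart$transitions
  if (K < 1L) stop("state chart needs at least one state")
  if (anyDuplicated(chart$states)) stop("duplicate state labels")
  if (nrow(tr) > 0) {
    bad <- tr < 1L | tr > K
    if (any(bad)) stop("transition references unknown state ", tr[bad][1])
    if (any(tr[, 1] == tr[, 2])) stop("transition must join two distinct states")
    key <- paste(tr[, 1], tr[, 2])
    if (anyDuplicated(key)) stop("duplicate transition: ", key[duplicated(key)][1])
  }
  Q <- nrow(tr)
  sp <- chart$similar_pairs
  if (nrow(sp) > 0) {
    if (any(sp < 1L | sp > Q)) stop("similar pair references unknown transition")
    if (any(sp[, 1] == sp[, 2])) stop("similar pair must join distinct transitions")
  }
  chart$absorbing <- setdiff(seq_len(K), unique(tr[, 1]))
  chart
}

#' @export
print.state_chart <- function(x, ...) {
  cat("Multi-state chart:", length(x$states), "states,",
      nrow(x$transitions), "transitions\n")
  lab <- x$states
  for (q in seq_len(nrow(x$transitions))) {
    cat(sprintf("  %2d: %s -> %s\n", q,
                lab[x$transitions[q, 1]], lab[x$transitions[q, 2]]))
  }
  if (nrow(x$similar_pairs) > 0) {
    cat("Similar transition pairs:",
        paste(sprintf("(%d,%d)", x$similar_pairs[, 1], x$similar_pairs[, 2]),
              collapse = " "), "\n")
  }
  cat("Absorbing states:", paste(x$absorbing, collapse = ", "), "\n")
  invisible(x)
}

#' Number of transitions of a state chart
#' @param chart A `state_chart`.
#' @return Integer count of directed transitions `Q`.
#' @export
n_transitions <- function(chart) nrow(chart$transitions)

#' The nine-state acute myeloid leukemia state chart
#'
#' The AML disease pathway used in the package's simulation study: nine states
#' and eight transitions. From active disease a patient reaches first complete
#' remission (CR1, transition 1) or dies early (transition 2); from CR1,
#' first relapse (3) or death in CR1 (4); from first relapse, second complete
#' remission (CR2, 5) or death after relapse (6); from CR2, second relapse (7)
#' or death in CR2 (8). Transitions 3/7 (CR to relapse) and 4/8 (CR to death)
#' form the two similar pairs used for fusion.
#'
#' @return A `state_chart` with 9 states, 8 transitions and similar pairs
#'   (3,7) and (4,8).
#' @export
#' @examples
#' aml_state_chart()
aml_state_chart <- function() {
  state_chart(
    states = c("active disease", "CR1", "early death", "first relapse",
               "death in CR1", "CR2", "death after relapse",
               "second relapse", "death in CR2"),
    transitions = rbind(
      c(1L, 2L),  # 1: active disease -> CR1
      c(1L, 3L),  # 2: active disease -> early death
      c(2L, 4L),  # 3: CR1 -> first relapse
      c(2L, 5L),  # 4: CR1 -> death in CR1
      c(4L, 6L),  # 5: first relapse -> CR2
      c(4L, 7L),  # 6: first relapse -> death after relapse
      c(6L, 8L),  # 7: CR2 -> second relapse
      c(6L, 9L)), # 8: CR2 -> death in CR2
    similar_pairs = rbind(c(3L, 7L), c(4L, 8L)))
}
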