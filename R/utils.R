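#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition so callers can distinguish error families.
#' @noRd
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("sa_config_error", "error")))
}

#' @noRd
stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("sa_format_error", "error")))
}

#' @noRd
stop_empty_selection <- function(...) {
  stop(errorCondition(paste0(...), class = c("sa_empty_selection_error", "error")))
}

#' @noRd
stop_insufficient <- function(...) {
  stop(errorCondition(paste0(...), class = c("sa_insufficient_data_error", "error")))
}

#' @noRd
stop_contract <- function(...) {
  stop(errorCondition(paste0(...), class = c("sa_contract_error", "error")))
}

#' @noRd
check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_config(name, " must lie in [0, 1]")
  }
  invisible(x)
}

#' Derive a reproducible child seed from a root seed and an index.
#'
#' Simple splitmix-style integer hash, kept below 2^31 so it is a valid R
#' integer seed. Distinct (root, index) pairs map to well-separated seeds so
#' per-fly streams generated in any order are identical.
#' @noRd
child_seed <- function(root, index) {
  x <- (as.double(root) * 2654435761 + as.double(index) * 40503 + 12345) %% 2147483647
  as.integer(x)
}

#' Uniform time grid of a trace (computed on demand; only x is stored).
#' @noRd
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$x) - 1) / trace$frame_rate
}

#' Fold an unbounded coordinate into [0, L] (triangle wave reflection).
#' @noRd
fold_position <- function(y, L) {
  L - abs(y %% (2 * L) - L)
}
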