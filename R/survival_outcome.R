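#' Construct a survival outcome
#'
#' Bundles observed times and event indicators for `n` samples. An event
#' indicator of 1 means the event time was observed; 0 means the sample was
#' right-censored at that time. The censoring rate is the fraction of
#' censored samples, `(n - K)/n` where `K` is the number of events.
#'
#' @param time Numeric vector of positive observed times (study time units).
#' @param status Integer/numeric vector of event indicators, each 0 or 1.
#' @param id Optional character vector of sample identifiers.
#'
#' @return An object of class `"survival_outcome"`: a list with elements
#'   `time`, `status`, `id`, `n`, `n_events` and `censoring_rate`.
#'
#' @examples
#' y <- survival_outcome(c(2.3, 1.1, 4.5), c(1, 0, 1))
#' y$censoring_rate
#' @export
survival_outcome <- function(time, status, id = NULL) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  if (length(time) != length(status))
    stop("'time' and 'status' must have the same length")
  if (length(time) == 0L) stop("empty outcome")
  if (anyNA(time) || any(!is.finite(time)))
    stop("all times must be finite")
  if (any(time <= 0))
    stop("all times must be > 0 (first offending sample: ",
         which(time <= 0)[1L], ")")
  if (anyNA(status) || !all(status %in% c(0, 1)))
    stop("'status' entries must be 0 (censored) or 1 (event)")
  if (!is.null(id)) {
    id <- as.character(id)
    if (length(id) != length(time)) stop("'id' length mismatch")
  }
  n <- length(time)
  K <- sum(status)
  structure(list(time = time, status = as.integer(status), id = id,
                 n = n, n_events = as.integer(K),
                 censoring_rate = (n - K) / n),
            class = "survival_outcome")
}

#' @export
print.survival_outcome <- function(x, ...) {
  cat(sprintf("Survival outcome: n = %d, events = %d, censoring rate = %.3f\n",
              x$n, x$n_events, x$censoring_rate))
  invisible(x)
}

# internal: validate + coerce anything outcome-like
as_survival_outcome <- function(outcome) {
  if (inherits(outcome, "survival_outcome")) return(outcome)
  if (is.list(outcome) && all(c("time", "status") %in% names(outcome)))
    return(survival_outcome(outcome$time, outcome$status))
  stop("'outcome' must be a survival_outcome (see ?survival_outcome)")
}

# internal: sort order by increasing time, computed once per outcome use
outcome_order <- function(outcome) order(outcome$time)

check_ties <- function(ties) match.arg(ties, c("efron", "breslow"))
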