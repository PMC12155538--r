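#' PIP calibration table
#'
#' Bins variables into `n_bins` equally spaced PIP bins on `[0, 1]`
#' (half-open `[a, b)`, last bin closed) and reports, per bin, the mean
#' PIP and the fraction of variables that are truly causal. A
#' well-calibrated method puts these points near the diagonal. Bins with
#' fewer than `min_bin_count` variables are removed.
#'
#' @param pips Numeric vector of posterior inclusion probabilities.
#' @param truth Logical (or 0/1) vector of the same length; `TRUE` =
#'   causal.
#' @param n_bins Number of equally spaced bins (default 10).
#' @param min_bin_count Minimum variables per retained bin (default 10).
#' @return Data frame with columns `bin`, `mean_pip`, `causal_fraction`,
#'   `count`.
#' @export
pip_calibration <- function(pips, truth, n_bins = 10L, min_bin_count = 10L) {
  if (length(pips) == 0L) stop("empty input")
  if (length(pips) != length(truth)) stop("length mismatch")
  truth <- as.logical(truth)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(pips, edges, rightmost.closed = TRUE)
  rows <- lapply(seq_len(n_bins), function(k) {
    idx <- bin == k
    cnt <- sum(idx)
    if (cnt < min_bin_count) return(NULL)
    data.frame(bin = k, mean_pip = mean(pips[idx]),
               causal_fraction = mean(truth[idx]), count = cnt)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(bin = integer(0), mean_pip = numeric(0),
                      causal_fraction = numeric(0), count = integer(0))
  out
}

#' Power/FDR curve over PIP thresholds
#'
#' At each threshold `t`, variables with `PIP >= t` are called positive;
#' the curve reports `TP`, `FP`, `FN`, `power = TP/(TP+FN)` and
#' `FDR = FP/(TP+FP)` (defined as 0 when there are no positives). The
#' default grid is 101 equally spaced thresholds plus the conventional
#' highlight at 0.95.
#'
#' @inheritParams pip_calibration
#' @param thresholds Numeric vector of thresholds (default
#'   `seq(0, 1, 0.01)` plus 0.95).
#' @return Data frame with columns `threshold`, `tp`, `fp`, `fn`, `power`,
#'   `fdr`.
#' @export
power_fdr_curve <- function(pips, truth, thresholds = NULL) {
  if (length(pips) != length(truth)) stop("length mismatch")
  truth <- as.logical(truth)
  if (is.null(thresholds))
    thresholds <- sort(unique(c(seq(0, 1, length.out = 101L), 0.95)))
  n_causal <- sum(truth)
  rows <- lapply(thresholds, function(t) {
    pos <- pips >= t
    tp <- sum(pos & truth); fp <- sum(pos & !truth)
    fn <- n_causal - tp
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn,
               power = if (n_causal > 0) tp / n_causal else NA_real_,
               fdr = if (tp + fp > 0) fp / (tp + fp) else 0)
  })
  do.call(rbind, rows)
}

#' Credible-set performance metrics
#'
#' Summarizes a list of credible sets against known causal labels:
#' `coverage` is the proportion of sets containing at least one causal
#' variable; `power` is the proportion of causal variables appearing in at
#' least one set; `median_mas` is the median over sets of the mean
#' absolute pairwise Pearson correlation among members (singleton sets
#' have MAS 1). With no sets, coverage and median MAS are `NA` and power
#' is 0 when causal variables exist.
#'
#' @param cs_list A [credible_sets()] result (or plain list of lists with
#'   a `members` element).
#' @param truth Logical (or 0/1) causal-indicator vector over variables.
#' @param X Covariate matrix (for the correlation computation).
#' @return List with `coverage`, `power`, `median_mas`, `n_cs`.
#' @export
cs_metrics <- function(cs_list, truth, X) {
  truth <- as.logical(truth)
  causal <- which(truth)
  if (length(cs_list) == 0L)
    return(list(coverage = NA_real_,
                power = if (length(causal) > 0) 0 else NA_real_,
                median_mas = NA_real_, n_cs = 0L))
  members <- lapply(cs_list, `[[`, "members")
  if (any(unlist(members) > length(truth)))
    stop("credible-set member out of range")
  covered <- vapply(members, function(m) any(m %in% causal), logical(1))
  in_any <- unique(unlist(members))
  list(coverage = mean(covered),
       power = if (length(causal) > 0)
         mean(causal %in% in_any) else NA_real_,
       median_mas = median(vapply(members, function(m) cs_mas(m, X), 0)),
       n_cs = length(cs_list))
}
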