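#' Cox partial log-likelihood for a single covariate
#'
#' Evaluates the log partial likelihood \eqn{\log\ell(b; x, c)} of the Cox
#' proportional hazards model with hazard
#' \eqn{\lambda_i(t) = \lambda_0(t)\exp(b x_i + c_i)}, where `c` is a fixed
#' per-sample offset. Only the ranks of the observed times enter the
#' computation, and the value is invariant to adding a constant to all
#' offsets. Tied event times are handled by Efron's (default) or Breslow's
#' correction; the two agree exactly when no event times are tied.
#'
#' @param b Scalar coefficient at which to evaluate.
#' @param x Numeric covariate vector, one entry per sample.
#' @param outcome A [survival_outcome()].
#' @param offset Optional numeric offset vector `c` (default all zero).
#' @param ties Tie-handling method, `"efron"` or `"breslow"`.
#'
#' @return The scalar log partial likelihood.
#' @seealso [fit_univariate_coxph()]
#' @export
partial_loglik <- function(b, x, outcome, offset = NULL,
                           ties = c("efron", "breslow")) {
  ties <- check_ties(ties)
  outcome <- as_survival_outcome(outcome)
  x <- as.numeric(x)
  if (length(x) != outcome$n) stop("length(x) != n")
  if (!is.finite(b)) stop("'b' must be finite")
  if (any(!is.finite(x))) stop("'x' must be finite")
  if (outcome$n_events == 0L) stop("no events")
  offset <- check_offset(offset, outcome$n)
  ord <- outcome_order(outcome)
  .cox_eval_cpp(outcome$time[ord], outcome$status[ord], x[ord], offset[ord],
                b, ties == "efron")[1L]
}

check_offset <- function(offset, n) {
  if (is.null(offset)) return(numeric(n))
  offset <- as.numeric(offset)
  if (length(offset) == 1L) offset <- rep(offset, n)
  if (length(offset) != n) stop("offset length != n")
  if (any(!is.finite(offset))) stop("offsets must be finite")
  offset
}

#' Univariate Cox proportional hazards fit
#'
#' Maximizes the partial likelihood over the scalar coefficient `b` by
#' Newton-Raphson (started at 0, with step-halving on likelihood decrease),
#' returning the maximum partial likelihood estimate \eqn{\hat b}, its
#' standard error \eqn{s} (inverse square root of the observed information at
#' \eqn{\hat b}), the z-score \eqn{z = \hat b/s}, and the log partial
#' likelihood at \eqn{\hat b} and at 0. These are the three statistics the
#' Laplace Bayes factor needs.
#'
#' A covariate with zero variance within every risk set carries no
#' information about `b`; such fits are flagged `degenerate` and returned as
#' null fits (`bhat = 0`, `se = Inf`, `loglik_mle = loglik_null`) rather
#' than raising an error, so scans over monomorphic variants proceed.
#' Under complete separation (partial likelihood monotone in `b`) the
#' estimate is capped at `|b| = 15` and `converged` is set to `FALSE`.
#'
#' @inheritParams partial_loglik
#' @param tol Convergence tolerance on the absolute score (gradient).
#' @param max_iter Maximum Newton-Raphson iterations.
#'
#' @return An object of class `"univariate_coxfit"`: list with `bhat`, `se`,
#'   `z`, `loglik_mle`, `loglik_null`, `converged`, `degenerate`, `n_iter`.
#' @examples
#' set.seed(1)
#' x <- rbinom(60, 2, 0.3)
#' y <- survival_outcome(rexp(60, exp(0.5 * x)), rep(1, 60))
#' fit_univariate_coxph(x, y)
#' @export
fit_univariate_coxph <- function(x, outcome, offset = NULL,
                                 ties = c("efron", "breslow"),
                                 tol = 1e-8, max_iter = 25L) {
  ties <- check_ties(ties)
  outcome <- as_survival_outcome(outcome)
  x <- as.numeric(x)
  if (length(x) != outcome$n) stop("length(x) != n")
  if (any(!is.finite(x))) stop("'x' must be finite")
  if (outcome$n_events == 0L) stop("no events")
  offset <- check_offset(offset, outcome$n)
  ord <- outcome_order(outcome)
  res <- .cox_univariate_batch_cpp(outcome$time[ord], outcome$status[ord],
                                   matrix(x[ord], ncol = 1), offset[ord],
                                   ties == "efron", tol, as.integer(max_iter),
                                   15)
  univariate_coxfit_from_row(res[1L, ])
}

univariate_coxfit_from_row <- function(r) {
  se <- r[2L]
  structure(list(bhat = r[1L], se = se,
                 z = if (is.finite(se) && se > 0) r[1L] / se else 0,
                 loglik_mle = r[3L], loglik_null = r[4L],
                 converged = r[5L] == 1, degenerate = r[6L] == 1,
                 n_iter = as.integer(r[7L])),
            class = "univariate_coxfit")
}

#' @export
print.univariate_coxfit <- function(x, ...) {
  cat(sprintf("Univariate Cox fit: bhat = %.4g, se = %.4g, z = %.3f\n",
              x$bhat, x$se, x$z))
  cat(sprintf("  loglik: %.4f (MLE), %.4f (null); converged: %s%s\n",
              x$loglik_mle, x$loglik_null, x$converged,
              if (x$degenerate) "; degenerate" else ""))
  invisible(x)
}

# internal: batched univariate fits for all columns of X against one outcome
# and offset; returns a p x 7 matrix (bhat, se, loglik_mle, loglik_null,
# converged, degenerate, n_iter).  This is the O(np) inner loop of the SER.
cox_univariate_scan <- function(X, outcome, offset, ties, tol = 1e-8,
                                max_iter = 25L) {
  ord <- outcome_order(outcome)
  .cox_univariate_batch_cpp(outcome$time[ord], outcome$status[ord],
                            X[ord, , drop = FALSE], offset[ord],
                            ties == "efron", tol, as.integer(max_iter), 15)
}

#' Estimate fixed-covariate offsets for fine-mapping
#'
#' Fits a Cox proportional hazards model containing only the `m` fixed
#' covariates (sex, genetic principal components, ...) and returns the
#' per-sample linear predictor \eqn{\hat w^\top z_i}, centered to mean zero
#' (allowed because the partial likelihood is shift-invariant). The result
#' initializes the offsets of the gIBSS algorithm, so covariates are
#' adjusted for at a one-time cost instead of entering every single-variable
#' integral.
#'
#' Constant columns are unidentifiable in a partial likelihood and are
#' dropped; exactly collinear columns raise an error naming them.
#'
#' @param Z Numeric `n x m` covariate matrix (column names recommended).
#' @inheritParams partial_loglik
#'
#' @return Numeric offset vector of length `n` with mean 0.
#' @export
fit_covariate_offsets <- function(Z, outcome, ties = c("efron", "breslow")) {
  ties <- check_ties(ties)
  outcome <- as_survival_outcome(outcome)
  Z <- as.matrix(Z)
  if (!is.numeric(Z)) stop("'Z' must be numeric")
  if (nrow(Z) != outcome$n) stop("nrow(Z) != n")
  if (ncol(Z) < 1L) stop("'Z' must have at least one column")
  if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  keep <- apply(Z, 2L, function(col) stats::var(col) > 0)
  Zk <- Z[, keep, drop = FALSE]
  if (ncol(Zk) == 0L) return(numeric(outcome$n))
  qrz <- qr(scale(Zk, center = TRUE, scale = FALSE))
  if (qrz$rank < ncol(Zk)) {
    bad <- colnames(Zk)[qrz$pivot[seq.int(qrz$rank + 1L, ncol(Zk))]]
    stop("collinear covariate columns: ", paste(bad, collapse = ", "))
  }
  fit <- survival::coxph(
    survival::Surv(outcome$time, outcome$status) ~ Zk,
    ties = ties)
  off <- drop(Zk %*% coef(fit))
  off - mean(off)
}
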