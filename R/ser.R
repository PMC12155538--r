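#' Cox proportional hazards single-effect regression (SER)
#'
#' Fits the single-effect regression for censored outcomes: exactly one of
#' the `p` columns of `X` has a non-zero log-hazard coefficient, with prior
#' \eqn{b \sim N(0, \sigma_0^2)} on that coefficient and prior inclusion
#' weights \eqn{\pi} over columns (uniform by default). Each column gets a
#' univariate Cox fit at the supplied offset; per-variable evidence is the
#' Laplace Bayes factor, and the posterior inclusion vector is
#' \deqn{\alpha_j = \pi_j \widehat{BF}_j / \sum_{j'} \pi_{j'}
#'   \widehat{BF}_{j'},}
#' computed by max-subtracted softmax in log space. The conditional effect
#' posterior for column `j` is \eqn{N(\mu_{1j}, \sigma_{1j}^2)} from
#' [posterior_moments()], and the posterior mean single-effect vector is
#' \eqn{\bar b = \alpha \circ \mu_1}.
#'
#' The per-column fits are independent of one another, so the scan
#' parallelizes trivially; results are deterministic regardless of
#' execution order. If every column is degenerate (monomorphic), `alpha`
#' equals the prior weights and the result carries `all_degenerate = TRUE`.
#'
#' @param X Numeric `n x p` covariate (genotype dosage) matrix.
#' @param outcome A [survival_outcome()].
#' @param offset Optional per-sample offset vector on the linear predictor.
#' @param sigma0sq Prior variance of the non-zero effect.
#' @param prior_weights Prior inclusion probabilities \eqn{\pi} (length `p`,
#'   non-negative, summing to 1); default uniform.
#' @param ties Tie-handling method for the partial likelihood.
#'
#' @return An object of class `"coxph_ser"`: list with p-vectors `alpha`,
#'   `mu1`, `sigma1sq`, `log_bf`, `bhat`, `se`, `z`, `degenerate`; scalars
#'   `log_bf_ser` (log of the softmax normalizer,
#'   \eqn{\mathrm{logsumexp}_j\{\log\pi_j + \log\widehat{BF}_j\}}),
#'   `loglik_null`, `sigma0sq`; and `prior_weights`.
#' @seealso [coxph_susie()], [em_update_sigma0sq()], [ser_logml()]
#' @export
coxph_ser <- function(X, outcome, offset = NULL, sigma0sq = 1,
                      prior_weights = NULL, ties = c("efron", "breslow")) {
  ties <- check_ties(ties)
  outcome <- as_survival_outcome(outcome)
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 1L) stop("X must have at least one column")
  if (nrow(X) != outcome$n) stop("nrow(X) != n")
  if (is.null(prior_weights)) prior_weights <- rep(1 / p, p)
  if (length(prior_weights) != p || any(prior_weights < 0) ||
      abs(sum(prior_weights) - 1) > 1e-8)
    stop("'prior_weights' must be a length-p probability vector")
  stopifnot(sigma0sq >= 0)
  offset <- check_offset(offset, outcome$n)

  scan <- cox_univariate_scan(X, outcome, offset, ties)
  bhat <- scan[, 1L]; se <- scan[, 2L]
  degenerate <- scan[, 6L] == 1
  lbf <- .log_laplace_bf_vec(scan, sigma0sq)
  s2 <- se^2
  mu1 <- .post_mean(bhat, s2, sigma0sq)
  sigma1sq <- .post_var(s2, sigma0sq)

  sm <- alpha_from_log_bf(lbf, prior_weights)

  structure(list(alpha = sm$alpha, mu1 = mu1, sigma1sq = sigma1sq,
                 log_bf = lbf,
                 log_bf_ser = sm$log_normalizer,
                 loglik_null = scan[1L, 4L],
                 bhat = bhat, se = se,
                 z = ifelse(is.finite(se) & se > 0, bhat / se, 0),
                 degenerate = degenerate,
                 all_degenerate = all(degenerate),
                 sigma0sq = sigma0sq,
                 prior_weights = prior_weights,
                 variable_names = colnames(X)),
            class = "coxph_ser")
}

# posterior inclusion weights alpha_j = pi_j BF_j / sum(pi BF), evaluated
# by max-subtracted softmax in log space; also returns the log normalizer
# logsumexp_j(log pi_j + log BF_j)
alpha_from_log_bf <- function(log_bf, prior_weights) {
  lp <- ifelse(prior_weights > 0, log(prior_weights), -Inf) + log_bf
  m <- max(lp)
  w <- exp(lp - m)
  list(alpha = w / sum(w), log_normalizer = m + log(sum(w)))
}

#' @export
print.coxph_ser <- function(x, ...) {
  p <- length(x$alpha)
  top <- order(x$alpha, decreasing = TRUE)[seq_len(min(5L, p))]
  cat(sprintf("CoxPH single-effect regression over %d variables (sigma0sq = %.3g)\n",
              p, x$sigma0sq))
  cat("Top posterior inclusion weights:\n")
  nm <- if (is.null(x$variable_names)) paste0("x", top) else
    x$variable_names[top]
  for (i in seq_along(top))
    cat(sprintf("  %-12s alpha = %.4f  mu1 = %+.4f\n",
                nm[i], x$alpha[top[i]], x$mu1[top[i]]))
  invisible(x)
}

#' EM update of the single-effect prior variance
#'
#' One M-step of the expectation-maximization algorithm that maximizes the
#' approximate SER marginal likelihood over \eqn{\sigma_0^2}:
#' \deqn{\sigma_0^2 \leftarrow \sum_j \alpha_j (\mu_{1j}^2 +
#'   \sigma_{1j}^2).}
#' For a null effect the update can collapse to zero; it is floored at
#' `floor` and the returned value then carries attribute
#' `null_like = TRUE`, letting the caller deactivate the effect.
#'
#' @param ser A [coxph_ser()] result (the E-step quantities).
#' @param floor Lower bound for the returned variance.
#' @return The updated prior variance (scalar), with logical attribute
#'   `null_like`.
#' @export
em_update_sigma0sq <- function(ser, floor = 1e-8) {
  stopifnot(inherits(ser, "coxph_ser"))
  v <- sum(ser$alpha * (ser$mu1^2 + ser$sigma1sq))
  null_like <- !is.finite(v) || v < floor
  structure(max(v, floor), null_like = null_like)
}

#' Approximate SER log marginal likelihood
#'
#' Evaluates \eqn{\log \hat\ell_{SER}(\sigma_0^2) = \mathrm{logsumexp}_j
#' \{\log \pi_j + \log \widehat{BF}_j\} + \log\ell(0; \cdot, c)}: the log of
#' the prior-weighted sum of per-variable Laplace-approximate marginal
#' likelihoods. Used to monitor the EM iterations for \eqn{\sigma_0^2}
#' (each [em_update_sigma0sq()] / [coxph_ser()] alternation is
#' non-decreasing in this quantity).
#'
#' @param ser A [coxph_ser()] result.
#' @return Scalar log marginal likelihood.
#' @export
ser_logml <- function(ser) {
  stopifnot(inherits(ser, "coxph_ser"))
  ser$log_bf_ser + ser$loglik_null
}
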