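#' Configuration for synthetic fine-mapping data
#'
#' Collects the knobs of the synthetic-data generator: genotype dosages are
#' drawn per variant as Binomial(2, MAF), optionally with AR(1)
#' Gaussian-copula correlation between adjacent variants standing in for
#' linkage disequilibrium; censored time-to-event outcomes are drawn from a
#' Cox proportional hazards model \eqn{\lambda_i(t) =
#' \lambda_0(t)\exp(b^\top x_i)} with independent exponential censoring
#' calibrated to a target censoring rate.
#'
#' @param n Number of samples.
#' @param p Number of variants.
#' @param maf Minor allele frequency in (0, 0.5]; scalar or length-`p`.
#' @param ld_rho AR(1) latent correlation in `[0, 1)` between adjacent
#'   variants (0 = independent).
#' @param causal_indices Indices of causal variants (possibly empty).
#' @param effects Log-hazard-ratio per causal variant (recycled to match
#'   `causal_indices`).
#' @param baseline Baseline hazard family: `"exponential"`
#'   (\eqn{\lambda_0(t) = 1}; the partial likelihood is invariant to
#'   \eqn{\lambda_0}, so this only sets the time scale) or `"weibull"`.
#' @param baseline_shape Weibull shape parameter (ignored for
#'   exponential).
#' @param target_censoring Target censoring rate in `[0, 1)`.
#' @param seed Integer root seed; the genotype draw uses `seed` and the
#'   outcome draw uses `seed + 1`, so standalone and combined calls agree.
#'
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n = 2000L, p = 200L, maf = 0.3, ld_rho = 0.9,
                       causal_indices = integer(0), effects = numeric(0),
                       baseline = c("exponential", "weibull"),
                       baseline_shape = 1.5, target_censoring = 0.2,
                       seed = 1L) {
  baseline <- match.arg(baseline)
  n <- as.integer(n); p <- as.integer(p)
  stopifnot(n >= 1L, p >= 1L)
  if (any(maf <= 0 | maf > 0.5)) stop("'maf' must lie in (0, 0.5]")
  if (!(length(maf) %in% c(1L, p))) stop("'maf' must be scalar or length p")
  stopifnot(ld_rho >= 0, ld_rho < 1)
  causal_indices <- as.integer(causal_indices)
  if (any(causal_indices < 1L | causal_indices > p))
    stop("'causal_indices' out of range")
  if (length(causal_indices) > 0L)
    effects <- rep_len(as.numeric(effects), length(causal_indices))
  if (any(!is.finite(effects))) stop("'effects' must be finite")
  if (target_censoring < 0 || target_censoring >= 1)
    stop("'target_censoring' must lie in [0, 1)")
  structure(list(n = n, p = p, maf = maf, ld_rho = ld_rho,
                 causal_indices = causal_indices, effects = effects,
                 baseline = baseline, baseline_shape = baseline_shape,
                 target_censoring = target_censoring,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate genotype dosages with optional LD
#'
#' Draws an `n x p` dosage matrix with entries in \{0, 1, 2\}. Column `j`
#' is marginally Binomial(2, `maf[j]`). For `ld_rho > 0`, dosages are
#' produced by thresholding a latent AR(1) Gaussian process at the
#' binomial quantiles (a Gaussian copula), so adjacent columns are
#' positively correlated — a one-parameter stand-in for linkage
#' disequilibrium.
#'
#' @param config A [sim_config()].
#' @return Integer matrix with columns named `snp1 ... snpp`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n; p <- config$p
  maf <- rep_len(config$maf, p)
  rho <- config$ld_rho
  X <- with_seed(config$seed, {
    Zl <- matrix(0, n, p)
    Zl[, 1L] <- rnorm(n)
    if (p > 1L) {
      sd_innov <- sqrt(1 - rho^2)
      for (j in 2L:p)
        Zl[, j] <- rho * Zl[, j - 1L] + sd_innov * rnorm(n)
    }
    U <- pnorm(Zl)
    vapply(seq_len(p), function(j) qbinom(U[, j], 2L, maf[j]),
           numeric(n))
  })
  colnames(X) <- paste0("snp", seq_len(p))
  storage.mode(X) <- "double"
  X
}

#' Simulate censored time-to-event outcomes from a Cox model
#'
#' Event times are generated by inverse-transform sampling from
#' \eqn{\lambda(t) = \lambda_0(t)\exp(b^\top x)} with the configured
#' baseline hazard. Censoring times are independent exponentials whose
#' rate is calibrated by root-solving so that the expected censoring
#' fraction, given the drawn event times, equals `target_censoring`; the
#' empirical rate is then within Monte-Carlo error of the target.
#'
#' @param X Dosage matrix from [simulate_genotypes()].
#' @param config A [sim_config()]; `causal_indices`/`effects` define
#'   \eqn{b}.
#' @return A [survival_outcome()].
#' @export
simulate_tte <- function(X, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(X)
  eta <- numeric(n)
  if (length(config$causal_indices) > 0L)
    eta <- drop(X[, config$causal_indices, drop = FALSE] %*% config$effects)
  with_seed(config$seed + 1L, {
    u <- runif(n)
    cumhaz <- -log(u) / exp(eta)       # Lambda_0(T) values
    T <- switch(config$baseline,
                exponential = cumhaz,
                weibull = cumhaz^(1 / config$baseline_shape))
    if (config$target_censoring == 0) {
      survival_outcome(T, rep(1L, n))
    } else {
      # E[censored | T] = mean(1 - exp(-theta * T)); monotone in theta
      f <- function(log_theta)
        mean(1 - exp(-exp(log_theta) * T)) - config$target_censoring
      log_theta <- uniroot(f, c(-40, 40), tol = 1e-10)$root
      C <- rexp(n, rate = exp(log_theta))
      survival_outcome(pmin(T, C), as.integer(T <= C))
    }
  })
}

#' Generate a complete synthetic fine-mapping dataset
#'
#' Draws genotypes and a censored survival outcome under one
#' [sim_config()], returning the inputs together with the causal-indicator
#' vector for evaluation. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `X` (dosage matrix), `outcome`
#'   ([survival_outcome()]), `truth` (logical length-`p`), and `config`.
#' @export
make_finemap_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  X <- simulate_genotypes(config)
  outcome <- simulate_tte(X, config)
  truth <- logical(config$p)
  truth[config$causal_indices] <- TRUE
  list(X = X, outcome = outcome, truth = truth, config = config)
}
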