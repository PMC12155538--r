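# Independent oracles and small fixtures. Everything here is written
# directly from first principles (risk-set definitions, brute-force search,
# dense-grid integration) and never calls the package's own computational
# path for the quantity it checks.

# Naive Cox partial log-likelihood: explicit product over event times with
# risk sets enumerated per event, Efron or Breslow tie correction written
# out longhand.
naive_partial_loglik <- function(b, x, time, status, offset = 0,
                                 ties = "efron") {
  offset <- rep_len(offset, length(x))
  eta <- b * x + offset
  ll <- 0
  for (tk in sort(unique(time[status == 1]))) {
    dead <- which(time == tk & status == 1)
    risk <- which(time >= tk)
    d <- length(dead)
    ll <- ll + sum(eta[dead])
    for (r in seq_len(d) - 1L) {
      f <- if (ties == "efron") r / d else 0
      ll <- ll - log(sum(exp(eta[risk])) - f * sum(exp(eta[dead])))
    }
  }
  ll
}

# brute-force 1-d maximization by golden-section search
golden_max <- function(f, lo, hi, tol = 1e-10) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    }
  }
  (a + b) / 2
}

# dense-grid trapezoid integral of the exact BF over b
trapezoid_log_bf <- function(x, outcome, sigma0sq, offset = NULL,
                             n_grid = 20001L, width = 10) {
  fit <- fit_univariate_coxph(x, outcome, offset)
  grid <- seq(fit$bhat - width * fit$se, fit$bhat + width * fit$se,
              length.out = n_grid)
  ll0 <- partial_loglik(0, x, outcome, offset)
  logint <- vapply(grid, function(b)
    partial_loglik(b, x, outcome, offset) +
      dnorm(b, 0, sqrt(sigma0sq), log = TRUE), 0) - ll0
  m <- max(logint)
  h <- grid[2L] - grid[1L]
  w <- rep(1, n_grid); w[c(1L, n_grid)] <- 0.5
  m + log(sum(w * exp(logint - m))) + log(h)
}

# fixed toy dataset: n = 6, two tied event times, dosage covariate
toy_tied_data <- function() {
  list(time = c(1, 2, 2, 3, 4, 4),
       status = c(1, 1, 1, 0, 1, 1),
       x = c(0, 1, 2, 1, 0, 2))
}

# small random censored survival fixture via the package simulator
rand_fixture <- function(seed, n = 120, p = 1, maf = 0.3, b = 1,
                         censoring = 0.2, ld_rho = 0) {
  cfg <- sim_config(n = n, p = p, maf = maf, ld_rho = ld_rho,
                    causal_indices = if (b != 0) 1L else integer(0),
                    effects = b, target_censoring = censoring, seed = seed)
  make_finemap_dataset(cfg)
}
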