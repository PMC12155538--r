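mock_fit <- function(bhat, se, llr = NULL) {
  # a univariate_coxfit with the stated summary statistics; llr defaults to
  # the quadratic (Wald) value so identities can be exercised directly
  z2 <- (bhat / se)^2
  if (is.null(llr)) llr <- z2 / 2
  structure(list(bhat = bhat, se = se, z = bhat / se,
                 loglik_mle = -100 + llr, loglik_null = -100,
                 converged = TRUE, degenerate = FALSE),
            class = "univariate_coxfit")
}

test_that("posterior moments follow the harmonic-shrinkage closed form", {
  pm <- posterior_moments(mock_fit(2, 1), 1)
  expect_equal(pm$variance, 0.5)
  expect_equal(pm$mean, 1)
  # point-mass prior
  pm0 <- posterior_moments(mock_fit(2, 1), 0)
  expect_equal(pm0$variance, 0)
  expect_equal(pm0$mean, 0)
  # flat-prior limit recovers the MLE
  pmf <- posterior_moments(mock_fit(2, 1), 1e12)
  expect_equal(pmf$variance, 1, tolerance = 1e-6)
  expect_equal(pmf$mean, 2, tolerance = 1e-6)
  # shrinkage invariants on random cases
  set.seed(1)
  for (i in 1:25) {
    b <- rnorm(1); s <- runif(1, 0.1, 3); v0 <- runif(1, 0.01, 5)
    pm <- posterior_moments(mock_fit(b, s), v0)
    expect_lte(pm$variance, min(s^2, v0) + 1e-12)
    expect_lte(abs(pm$mean), abs(b) + 1e-12)
  }
})

test_that("asymptotic Bayes factor: Occam factor at z = 0, null prior, monotone in z^2", {
  expect_equal(log_abf(mock_fit(0, 1), 3), log(0.5))
  expect_equal(log_abf(mock_fit(1.3, 0.7), 0), 0)
  zs <- seq(0, 10, by = 0.5)
  vals <- vapply(zs, function(z) log_abf(mock_fit(z * 0.5, 0.5), 2), 0)
  expect_true(all(diff(vals) > 0))
  # no overflow at extreme z
  expect_true(is.finite(log_abf(mock_fit(1e4, 1), 1)))
})

test_that("Laplace BF identity holds and reduces to the ABF at bhat = 0", {
  f0 <- mock_fit(0, 2, llr = 0)
  expect_equal(log_laplace_bf(f0, 1), 0.5 * log(4 / 5))
  expect_equal(log_laplace_bf(f0, 1), log_abf(f0, 1))
  set.seed(42)
  for (i in 1:50) {
    f <- mock_fit(rnorm(1), runif(1, 0.05, 2), llr = runif(1, 0, 8))
    v0 <- runif(1, 0.01, 4)
    llr <- f$loglik_mle - f$loglik_null
    expect_equal(log_laplace_bf(f, v0) - log_abf(f, v0) + f$z^2 / 2 - llr,
                 0, tolerance = 1e-12)
  }
})

test_that("degenerate fits give BF = 1 under every estimator", {
  dat <- rand_fixture(2, n = 60)
  y <- dat$outcome
  fd <- fit_univariate_coxph(rep(1, 60), y)
  expect_true(fd$degenerate)
  expect_equal(log_abf(fd, 1), 0)
  expect_equal(log_laplace_bf(fd, 1), 0)
  pm <- posterior_moments(fd, 1)
  expect_equal(pm$mean, 0)
  expect_equal(pm$variance, 0)
})

test_that("Gauss-Hermite rule integrates normal moments exactly", {
  gh <- gauss_hermite(16)
  w <- gh$weights / sqrt(pi)           # probability weights under N(0, 1/2)
  t <- gh$nodes * sqrt(2)              # nodes under N(0, 1)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(sum(w * t^2), 1, tolerance = 1e-10)     # E[Z^2]
  expect_equal(sum(w * t^4), 3, tolerance = 1e-9)      # E[Z^4]
  expect_equal(sum(w * t^3), 0, tolerance = 1e-10)
})

test_that("quadrature BF matches a dense trapezoid integral and is node-stable", {
  dat <- rand_fixture(21, n = 200, b = 0.5, maf = 0.25)
  y <- dat$outcome
  x <- dat$X[, 1]
  lq <- log_quadrature_bf(x, y, sigma0sq = 1)
  lt <- trapezoid_log_bf(x, y, sigma0sq = 1)
  expect_equal(lq, lt, tolerance = 1e-6)
  # stability in the number of nodes
  lq64 <- log_quadrature_bf(x, y, sigma0sq = 1, n_nodes = 64)
  expect_lt(abs(lq - lq64), 1e-4)
  # prior-centered nodes are adequate when the prior is no wider than the
  # likelihood; match the scales and compare against the same oracle
  fit <- fit_univariate_coxph(x, y)
  v0 <- fit$se^2
  lqp <- log_quadrature_bf(x, y, sigma0sq = v0, adaptive = FALSE,
                           n_nodes = 64)
  expect_equal(lqp, trapezoid_log_bf(x, y, sigma0sq = v0), tolerance = 1e-4)
})

test_that("quadrature BF collapses to 1 as the prior collapses to the null", {
  dat <- rand_fixture(22, n = 100, b = 0.5)
  expect_equal(log_quadrature_bf(dat$X[, 1], dat$outcome, sigma0sq = 1e-10),
               0, tolerance = 1e-4)
  expect_equal(log_quadrature_bf(dat$X[, 1], dat$outcome, sigma0sq = 0), 0)
})
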