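test_that("survival_outcome validates and summarizes its inputs", {
  y <- survival_outcome(c(2, 1, 3), c(1, 0, 1))
  expect_equal(y$n, 3L)
  expect_equal(y$n_events, 2L)
  expect_equal(y$censoring_rate, 1 / 3)
  expect_error(survival_outcome(c(0, 1), c(1, 1)), "times must be")
  expect_error(survival_outcome(c(1, 2), c(1, 2)), "0.*1|status")
  expect_error(survival_outcome(c(1, NA), c(1, 1)), "finite")
})

test_that("null model with distinct event times gives -log(n!)-style value", {
  # 3 subjects, all events, x = 0: risk sets of size 3, 2, 1
  y <- survival_outcome(c(1, 2, 3), c(1, 1, 1))
  expect_equal(partial_loglik(0.7, rep(0, 3), y), -log(6))
  # offset shift leaves the value unchanged
  expect_equal(partial_loglik(0.7, rep(0, 3), y, offset = rep(5, 3)),
               -log(6))
})

test_that("partial likelihood matches the longhand risk-set expansion", {
  d <- toy_tied_data()
  y <- survival_outcome(d$time, d$status)
  off <- c(0.3, -0.2, 0.1, 0, -0.5, 0.4)
  for (ties in c("efron", "breslow")) {
    for (b in c(-1.3, 0, 0.42, 2)) {
      expect_equal(partial_loglik(b, d$x, y, offset = off, ties = ties),
                   naive_partial_loglik(b, d$x, d$time, d$status, off, ties),
                   tolerance = 1e-12)
    }
  }
})

test_that("partial likelihood is invariant to offset shifts and monotone time transforms", {
  dat <- rand_fixture(11, n = 80)
  y <- dat$outcome
  x <- dat$X[, 1]
  off <- rnorm(80)
  base <- partial_loglik(0.5, x, y, offset = off)
  expect_equal(partial_loglik(0.5, x, y, offset = off + 17.3), base)
  # strictly increasing transform of all times: ranks unchanged
  y2 <- survival_outcome(exp(y$time) + y$time^3, y$status)
  expect_equal(partial_loglik(0.5, x, y2, offset = off), base)
})

test_that("Efron and Breslow coincide exactly without tied event times", {
  dat <- rand_fixture(5, n = 100)   # continuous times, no ties
  y <- dat$outcome
  x <- dat$X[, 1]
  expect_identical(partial_loglik(0.8, x, y, ties = "efron"),
                   partial_loglik(0.8, x, y, ties = "breslow"))
  fe <- fit_univariate_coxph(x, y, ties = "efron")
  fb <- fit_univariate_coxph(x, y, ties = "breslow")
  expect_equal(fe$bhat, fb$bhat, tolerance = 1e-10)
})

test_that("errors: no events, non-finite inputs", {
  y0 <- survival_outcome(c(1, 2), c(0, 0))
  expect_error(partial_loglik(0, c(1, 2), y0), "no events")
  y <- survival_outcome(c(1, 2), c(1, 1))
  expect_error(partial_loglik(Inf, c(1, 2), y), "finite")
  expect_error(partial_loglik(0, c(1, NaN), y), "finite")
  expect_error(fit_univariate_coxph(c(1, 2), y0), "no events")
})

test_that("Newton-Raphson matches golden-section maximization on random fixtures", {
  for (seed in 1:20) {
    dat <- rand_fixture(seed, n = 50, b = 1, maf = 0.3)
    y <- dat$outcome
    x <- dat$X[, 1]
    if (var(x) == 0) next
    fit <- fit_univariate_coxph(x, y)
    if (!fit$converged) next   # separation on tiny n; checked elsewhere
    b_star <- golden_max(function(b) partial_loglik(b, x, y), -10, 10)
    expect_equal(fit$bhat, b_star, tolerance = 1e-6)
    expect_gte(fit$loglik_mle, fit$loglik_null)
    expect_equal(fit$z, fit$bhat / fit$se)
  }
})

test_that("univariate fit agrees with survival::coxph on tied data", {
  set.seed(77)
  n <- 150
  x <- rbinom(n, 2, 0.4)
  tm <- ceiling(rexp(n, exp(0.6 * x)) * 8)   # heavy ties
  st <- rbinom(n, 1, 0.75)
  y <- survival_outcome(tm, st)
  for (ties in c("efron", "breslow")) {
    fit <- fit_univariate_coxph(x, y, ties = ties)
    ref <- survival::coxph(survival::Surv(tm, st) ~ x, ties = ties)
    expect_equal(fit$bhat, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$se, sqrt(vcov(ref)[1, 1]), tolerance = 1e-6)
    expect_equal(fit$loglik_mle, ref$loglik[2], tolerance = 1e-8)
    expect_equal(fit$loglik_null, ref$loglik[1], tolerance = 1e-8)
  }
})

test_that("degenerate, sign-symmetry and ordering properties of the fit", {
  dat <- rand_fixture(3, n = 90)
  y <- dat$outcome
  x <- dat$X[, 1]
  # constant covariate carries no information
  f0 <- fit_univariate_coxph(rep(2, 90), y)
  expect_true(f0$degenerate)
  expect_equal(f0$bhat, 0)
  expect_equal(f0$loglik_mle, f0$loglik_null)
  # sign symmetry
  f1 <- fit_univariate_coxph(x, y)
  f2 <- fit_univariate_coxph(-x, y)
  expect_equal(f1$bhat, -f2$bhat, tolerance = 1e-9)
  expect_equal(f1$se, f2$se, tolerance = 1e-9)
  expect_equal(f1$loglik_mle, f2$loglik_mle, tolerance = 1e-10)
  # permuting samples leaves the fit unchanged
  perm <- sample(90)
  yp <- survival_outcome(y$time[perm], y$status[perm])
  fp <- fit_univariate_coxph(x[perm], yp)
  expect_equal(f1$bhat, fp$bhat, tolerance = 1e-10)
  expect_equal(f1$loglik_mle, fp$loglik_mle, tolerance = 1e-10)
})

test_that("complete separation is capped and flagged", {
  # events all carried by x = 1 and occurring first: likelihood monotone
  y <- survival_outcome(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0))
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- fit_univariate_coxph(x, y)
  expect_false(fit$converged)
  expect_lte(abs(fit$bhat), 15)
})

test_that("covariate offsets: constants dropped, single column matches the univariate fit", {
  dat <- rand_fixture(9, n = 100)
  y <- dat$outcome
  x <- dat$X[, 1]
  # all-ones column is unidentifiable and dropped
  expect_equal(fit_covariate_offsets(matrix(1, 100, 1), y), rep(0, 100))
  # single covariate: offsets equal bhat * x, centered
  off <- fit_covariate_offsets(matrix(x, ncol = 1), y)
  fit <- fit_univariate_coxph(x, y)
  expect_equal(off, fit$bhat * x - mean(fit$bhat * x), tolerance = 1e-4)
  expect_equal(mean(off), 0, tolerance = 1e-12)
  # exact collinearity is an error naming the columns
  Z <- cbind(a = x, b = x)
  expect_error(fit_covariate_offsets(Z, y), "collinear.*b")
})
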