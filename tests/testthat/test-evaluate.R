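test_that("calibration bins: removal rule, degenerate input, edge handling", {
  # 15 variables at PIP ~ 0.05, 9 at ~ 0.95: the small bin is removed
  pips <- c(rep(0.05, 15), rep(0.95, 9))
  truth <- c(rep(FALSE, 15), rep(TRUE, 9))
  tab <- pip_calibration(pips, truth)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$count, 15)
  # all PIPs zero, nothing causal: one bin, causal fraction 0
  tab0 <- pip_calibration(rep(0, 50), rep(FALSE, 50))
  expect_equal(nrow(tab0), 1)
  expect_equal(tab0$causal_fraction, 0)
  # PIP = 1 lands in the last (closed) bin
  tab1 <- pip_calibration(rep(1, 20), rep(TRUE, 20))
  expect_equal(tab1$bin, 10)
  expect_error(pip_calibration(numeric(0), logical(0)), "empty")
})

test_that("perfectly calibrated PIPs sit on the diagonal", {
  set.seed(81)
  pips <- runif(10000)
  truth <- rbinom(10000, 1, pips) == 1   # causal status drawn at the PIP
  tab <- pip_calibration(pips, truth)
  expect_lt(max(abs(tab$causal_fraction - tab$mean_pip)), 0.05)
})

test_that("power/FDR counts match brute-force enumeration", {
  set.seed(82)
  pips <- round(runif(200), 2)
  truth <- rbinom(200, 1, 0.1) == 1
  curve <- power_fdr_curve(pips, truth)
  expect_true(0.95 %in% curve$threshold)
  for (k in sample(nrow(curve), 10)) {
    t <- curve$threshold[k]
    tp <- 0; fp <- 0; fn <- 0
    for (j in seq_along(pips)) {
      if (pips[j] >= t && truth[j]) tp <- tp + 1
      if (pips[j] >= t && !truth[j]) fp <- fp + 1
      if (pips[j] < t && truth[j]) fn <- fn + 1
    }
    expect_equal(curve$tp[k], tp)
    expect_equal(curve$fp[k], fp)
    expect_equal(curve$fn[k], fn)
  }
  # monotonicity: positives never increase with the threshold
  expect_true(all(diff(curve$tp + curve$fp) <= 0))
  expect_true(all(diff(curve$power) <= 1e-12))
})

test_that("oracle PIPs give perfect discovery; saturated PIPs give the causal fraction", {
  truth <- c(rep(TRUE, 10), rep(FALSE, 90))
  oracle <- power_fdr_curve(as.numeric(truth), truth,
                            thresholds = c(0.25, 0.5, 0.75, 1))
  expect_true(all(oracle$power == 1))
  expect_true(all(oracle$fdr == 0))
  half <- power_fdr_curve(rep(1, 100), c(rep(TRUE, 50), rep(FALSE, 50)))
  expect_true(all(half$fdr == 0.5))
  expect_true(all(half$power == 1))
})

test_that("credible-set metrics match exhaustive enumeration", {
  set.seed(83)
  X <- matrix(rnorm(50 * 12), 50, 12)
  truth <- rep(FALSE, 12); truth[c(2, 7, 11)] <- TRUE
  cs_list <- list(list(members = c(1, 2)), list(members = c(3, 4)),
                  list(members = 7L), list(members = c(5, 6, 8)),
                  list(members = c(11, 12)))
  m <- cs_metrics(cs_list, truth, X)
  covered <- sapply(cs_list, function(cs) any(truth[cs$members]))
  expect_equal(m$coverage, mean(covered))
  in_any <- unique(unlist(lapply(cs_list, `[[`, "members")))
  expect_equal(m$power, mean(which(truth) %in% in_any))
  mas <- sapply(cs_list, function(cs) {
    mm <- cs$members
    if (length(mm) == 1) return(1)
    pairs <- combn(mm, 2)
    mean(apply(pairs, 2, function(ij) abs(cor(X[, ij[1]], X[, ij[2]]))))
  })
  expect_equal(m$median_mas, median(mas))
  expect_equal(m$n_cs, 5L)
  # perfect single CS
  mperf <- cs_metrics(list(list(members = which(truth))), truth, X)
  expect_equal(mperf$coverage, 1)
  expect_equal(mperf$power, 1)
  # no causal member anywhere
  mnone <- cs_metrics(list(list(members = c(1, 3))), truth, X)
  expect_equal(mnone$coverage, 0)
  # empty list
  mempty <- cs_metrics(list(), truth, X)
  expect_true(is.na(mempty$coverage))
  expect_equal(mempty$power, 0)
})

test_that("metrics are invariant to a consistent variable relabeling", {
  set.seed(84)
  p <- 30
  pips <- runif(p)
  truth <- rbinom(p, 1, 0.2) == 1
  X <- matrix(rnorm(40 * p), 40, p)
  perm <- sample(p)
  inv <- order(perm)
  c1 <- power_fdr_curve(pips, truth)
  c2 <- power_fdr_curve(pips[perm], truth[perm])
  expect_equal(c1, c2)
  cs <- list(list(members = c(3, 5, 9)), list(members = 12L))
  cs_p <- lapply(cs, function(s) list(members = inv[s$members]))
  expect_equal(cs_metrics(cs, truth, X),
               cs_metrics(cs_p, truth[perm], X[, perm]))
})
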