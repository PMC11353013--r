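test_that("noiseless log-logistic generate-then-refit round trip is exact", {
  d <- dil3(10, 9)
  truth <- list(upper = 1, lower = 0.1, ec50 = 0.05, h = 1.5)
  v <- ll_fun(d, truth$upper, truth$lower, truth$ec50, truth$h)
  f <- fit_dose_response(d, v, "LL3u")
  expect_true(f$converged)
  expect_lt(abs(f$lower - truth$lower) / truth$lower, 1e-6)
  expect_lt(abs(f$ec50 - truth$ec50) / truth$ec50, 1e-6)
  expect_lt(abs(f$hill - truth$h) / truth$h, 1e-6)

  # four-parameter form recovers a free upper asymptote too
  v4 <- ll_fun(d, 0.9, 0.2, 0.3, 2)
  f4 <- fit_dose_response(d, v4, "LL4")
  expect_lt(abs(f4$upper - 0.9) / 0.9, 1e-5)
  expect_lt(abs(f4$ec50 - 0.3) / 0.3, 1e-5)
})

test_that("flat viability gives undefined IC50, Emax 1, AUC 0", {
  d <- dil3(10, 8)
  f <- fit_dose_response(d, rep(1, length(d)))
  expect_true(is.na(f$ic50_abs))
  expect_equal(f$emax, 1, tolerance = 1e-8)
  expect_equal(f$auc, 0, tolerance = 1e-8)
})

test_that("symmetric unit-Hill curve crosses 0.5 at its ec50", {
  d <- dil3(10, 9)
  v <- 1 / (1 + d / 0.1)
  f <- fit_dose_response(d, v, "LL3u")
  expect_equal(f$ic50_abs, 0.1, tolerance = 1e-6)
})

test_that("fewer than 4 nonzero doses is refused", {
  expect_error(fit_dose_response(c(0, 1, 3, 10), c(1, 0.8, 0.5, 0.2)),
               "fit-degenerate")
})

test_that("parameter recovery stays within 5% relative error at noise sd 0.02", {
  d <- dil3(10, 9)
  truth <- list(upper = 1, lower = 0.1, ec50 = 0.05, h = 1.5)
  v0 <- ll_fun(d, truth$upper, truth$lower, truth$ec50, truth$h)
  rel_err <- sapply(seq_len(100), function(s) {
    set.seed(s)
    v <- v0 * exp(rnorm(length(d), 0, 0.02))
    f <- fit_dose_response(d, v, "LL3u")
    abs(c(f$lower, f$ec50, f$hill) -
          c(truth$lower, truth$ec50, truth$h)) /
      c(truth$lower, truth$ec50, truth$h)
  })
  expect_lt(median(rel_err[2, ]), 0.05)  # ec50
  expect_lt(median(rel_err[3, ]), 0.05)  # hill
  expect_lt(median(rel_err[1, ]), 0.05)  # lower asymptote
})

test_that("single-agent metrics respect the dose range and normalization bounds", {
  d <- dil3(10, 9)
  f <- fit_dose_response(d, ll_fun(d, 1, 0, 0.1, 1), "LL3u")
  m <- single_agent_metrics(f, c(0.001, 10))
  expect_equal(m$ic50_abs, 0.1, tolerance = 1e-6)

  f_floor <- fit_dose_response(d, ll_fun(d, 1, 0.6, 0.1, 1.5), "LL3u")
  expect_true(is.na(single_agent_metrics(f_floor, c(0.001, 10))$ic50_abs))

  flat1 <- fit_dose_response(d, rep(1, 9))
  expect_equal(single_agent_metrics(flat1, c(0.01, 10))$auc, 0,
               tolerance = 1e-8)
  flat0 <- fit_dose_response(d, rep(0, 9))
  expect_equal(single_agent_metrics(flat0, c(0.01, 10))$auc, 1,
               tolerance = 1e-8)
  expect_error(single_agent_metrics(f, c(10, 1)), "dose_range")
})

test_that("smoothing is idempotent on constant and separable surfaces", {
  da <- halflog_doses(10); db <- halflog_doses(5)
  const <- combination_matrix(matrix(0.7, 9, 9), da, db, zero_tol = 1)
  sm <- suppressWarnings(smooth_combination_matrix(const))
  expect_equal(sm, matrix(0.7, 9, 9), tolerance = 1e-6)

  sep <- generate_viability_matrix(
    margin_a = ll_margin(lower = 0.1, ec50 = 0.3, hill = 1.5),
    margin_b = ll_margin(lower = 0.2, ec50 = 0.05, hill = 1.2),
    doses_a = da, doses_b = db, noise_sd = 0)
  sm2 <- smooth_combination_matrix(sep)
  expect_lt(max(abs(sm2 - sep$viability)), 1e-3)
})

test_that("smoothing reduces RMSE against the noiseless truth", {
  da <- halflog_doses(10); db <- halflog_doses(5)
  wins <- 0L
  for (s in 1:100) {
    m <- generate_viability_matrix(
      margin_a = ll_margin(lower = 0.1, ec50 = 0.3, hill = 1.5),
      margin_b = ll_margin(lower = 0.2, ec50 = 0.05, hill = 1.2),
      doses_a = da, doses_b = db, noise_sd = 0.05, seed = s)
    truth <- attr(m, "ground_truth")$noiseless
    sm <- tryCatch(smooth_combination_matrix(m), error = function(e) NULL)
    if (is.null(sm)) next
    rmse_obs <- sqrt(mean((m$viability - truth)^2))
    rmse_sm <- sqrt(mean((sm - truth)^2))
    if (rmse_sm < rmse_obs) wins <- wins + 1L
  }
  expect_gt(wins, 90)
})
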