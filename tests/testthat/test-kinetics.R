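test_that("one-phase decay satisfies its endpoint and half-life identities", {
  expect_equal(one_phase_decay(0, y0 = 1, y_plateau = 0.2, k = 0.09), 1)
  expect_equal(one_phase_decay(1e6, y0 = 1, y_plateau = 0.2, k = 0.09),
               0.2)
  # half-life with zero plateau
  expect_equal(one_phase_decay(log(2) / 0.31, y0 = 1, y_plateau = 0,
                               k = 0.31), 0.5)
  # the literal (no additive plateau) variant decays to zero instead
  expect_equal(one_phase_decay(1e6, y0 = 1, y_plateau = 0.2, k = 0.09,
                               form = "literal"), 0)
  expect_equal(one_phase_decay(0, y0 = 1, y_plateau = 0.2, k = 0.09,
                               form = "literal"), 0.8)
  expect_error(one_phase_decay(1, 1, 0, k = -1), "positive")
})

test_that("time course construction normalizes to t0 and validates", {
  tc <- time_course(c(0, 10, 20, 30), c(2, 1.5, 1.2, 1.0))
  expect_equal(tc$y[1], 1)
  expect_error(time_course(c(10, 20, 30, 40), rep(1, 4)), "0")
  expect_error(time_course(c(0, 20, 10), rep(1, 3)), "ascending")
  expect_error(time_course(c(0, 10), c(0, 1)), "positive")
})

test_that("decay fitting recovers noiseless parameters to 1e-6", {
  set.seed(99)
  for (rep in 1:20) {
    k <- stats::runif(1, 0.02, 0.35)
    yp <- stats::runif(1, 0, 0.4)
    tc <- gen_proteolysis_timecourse(k, y_plateau = yp, noise_rel = 0)
    fit <- fit_decay(tc)
    expect_lt(abs(fit$k - k) / k, 1e-6)
    expect_lt(abs(fit$y0 - 1), 1e-6)
    expect_lt(abs(fit$y_plateau - yp) / max(yp, 1e-3), 1e-4)
    expect_gt(fit$r2, 1 - 1e-10)
  }
})

test_that("a constant series is reported as degenerate, not a rate", {
  tc <- time_course(c(0, 10, 20, 30, 60, 120), rep(1, 6))
  fit <- fit_decay(tc)
  expect_true(fit$degenerate)
  expect_equal(fit$y0, 1)
  expect_equal(fit$y_plateau, 1)
  expect_true(is.na(fit$k))
})

test_that("the estimated rate is invariant to rescaling the ordinate", {
  tc1 <- gen_proteolysis_timecourse(0.15, y_plateau = 0.1, seed = 4,
                                    noise_rel = 0.02)
  tc2 <- time_course(tc1$t, 7.3 * tc1$y, normalize = FALSE)
  expect_equal(fit_decay(tc1)$k, fit_decay(tc2)$k, tolerance = 1e-8)
})

test_that("the LM decay fit beats a dense profiled grid search", {
  # oracle: for each k on a dense grid the model is linear in
  # (y_plateau, y0 - y_plateau), so OLS gives the exact SSE profile
  tc <- gen_proteolysis_timecourse(0.15, y_plateau = 0.1, seed = 12,
                                   noise_rel = 0.03)
  fit <- fit_decay(tc)
  sse_fit <- sum((tc$y - fit$fitted)^2)
  kk <- exp(seq(log(0.001), log(5), length.out = 4000))
  sse_grid <- vapply(kk, function(k) {
    X <- cbind(1, exp(-k * tc$t))
    sum(stats::lm.fit(X, tc$y)$residuals^2)
  }, numeric(1))
  expect_lte(sse_fit, min(sse_grid) + 1e-10)
})

test_that("association fits recover self-generated curves exactly", {
  x <- c(0, 1, 2, 4, 8, 16)
  y <- one_phase_association(x, y_start = -59.3, y_plateau = -39.1,
                             k = 0.3)
  fit <- fit_association(x, y, direction = "associate")
  expect_equal(fit$y_start, -59.3, tolerance = 1e-6)
  expect_equal(fit$y_plateau, -39.1, tolerance = 1e-6)
  expect_equal(fit$k, 0.3, tolerance = 1e-6)
  # x = 0 returns y_start in both directions
  yd <- one_phase_decay(x, y0 = 5, y_plateau = 1, k = 0.5)
  fd <- fit_association(x, yd, direction = "decay")
  expect_equal(fd$y_start, 5, tolerance = 1e-6)
  expect_equal(fd$y_plateau, 1, tolerance = 1e-6)
  expect_error(fit_association(1:3, 1:3), "4")
})

test_that("synthetic zeta-adsorption curves refit to their endpoints", {
  z <- gen_zeta_adsorption(seed = 5)
  truth <- attr(z, "truth")
  fit <- fit_association(z$adsorbed, z$zeta, direction = "associate")
  expect_equal(fit$y_start, truth$start_mv, tolerance = 3 / 59)
  expect_equal(fit$y_plateau, truth$plateau_mv, tolerance = 3 / 39)
  expect_gt(fit$r2, 0.85)
  # noiseless round trip is exact
  z0 <- gen_zeta_adsorption(seed = 5, noise_sd = 0)
  fit0 <- fit_association(z0$adsorbed, z0$zeta)
  expect_equal(fit0$k, truth$k, tolerance = 1e-6)
})

test_that("linear calibration fits, inverts, and flags extrapolation", {
  x <- c(0, 10, 25, 50, 75, 100, 150, 200)
  cal <- fit_calibration(x, 100 * x + 50)
  expect_equal(cal$r2, 1)
  expect_equal(cal$slope, 100)
  expect_equal(cal$intercept, 50)
  expect_equal(invert_calibration(cal, 100 * 60 + 50)[1], 60)
  neg <- invert_calibration(cal, 20)
  expect_lt(neg[1], 0)
  expect_true(attr(neg, "extrapolated")[1])
  # noisy standards: mid-range inversion within 2%, against closed-form OLS
  set.seed(21)
  y <- 100 * x + 50 + stats::rnorm(length(x), sd = 30)
  cal2 <- fit_calibration(x, y)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(cal2$slope, b, tolerance = 1e-12)
  expect_equal(cal2$intercept, a, tolerance = 1e-12)
  reading <- 100 * 75 + 50
  expect_equal(invert_calibration(cal2, reading)[1], 75,
               tolerance = 0.02)
  expect_error(fit_calibration(1:2, 1:2), "3")
  flat <- fit_calibration(c(1, 2, 3), c(5, 5, 5))
  expect_error(invert_calibration(flat, 4), "slope")
})

test_that("encapsulation efficiency follows (Mi - Mu)/Mi * 100", {
  expect_equal(encapsulation_efficiency(375, 0)$ee_percent, 100)
  expect_equal(encapsulation_efficiency(375, 375)$ee_percent, 0)
  expect_equal(encapsulation_efficiency(375, 243.75)$ee_percent, 35)
  # monotone decreasing in the unencapsulated mass
  ee <- vapply(c(0, 100, 200, 300),
               function(mu) encapsulation_efficiency(375, mu)$ee_percent,
               numeric(1))
  expect_true(all(diff(ee) < 0))
  expect_error(encapsulation_efficiency(0, 1), "positive")
  expect_error(encapsulation_efficiency(375, -1), "non-negative")
})

test_that("adsorption bookkeeping subtracts and flags correctly", {
  m <- adsorbed_from_supernatant(10, 9.2)
  expect_equal(m$adsorbed_conc, 0.8)
  expect_false(m$negative_flag)
  expect_equal(adsorbed_from_supernatant(10, 10)$adsorbed_conc, 0)
  over <- adsorbed_from_supernatant(10, 10.5)
  expect_true(over$negative_flag)
  expect_equal(over$adsorbed_conc, -0.5)
  expect_error(adsorbed_from_supernatant(0, 1), "positive")
  expect_equal(percent_decrease(8, 8), 0)
  expect_equal(percent_decrease(8, 2), 75)
  expect_error(percent_decrease(0, 1), "positive")
})
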