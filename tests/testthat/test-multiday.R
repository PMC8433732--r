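test_that("daily decline fits gap-normalized differences", {
  expect_equal(fit_linear(c(30, 30, 30))$delta, 0)
  expect_equal(fit_linear(c(30, 29, 28))$delta, -1)
  s <- multiday_series(as.Date("2019-10-07") + c(0, 2), 79 + c(0, 2),
                       c(0.30, 0.2868))
  expect_equal(fit_linear(s)$delta, -0.66, tolerance = 1e-12)
  expect_error(fit_linear(30), "at least 2")
})

test_that("linear prediction composes origin plus decline, floored at zero", {
  expect_equal(predict_linear(30, -0.66, 0), 30)
  expect_equal(predict_linear(30, -0.66, 5), 26.7)
  expect_equal(predict_linear(30, -0.66, 8), 24.72)
  expect_equal(predict_linear(2, -0.66, 8), 0)
})

test_that("daily ratio is the geometric mean of gap-normalized ratios", {
  expect_equal(fit_rate(c(30, 30))$r, 1)
  expect_equal(fit_rate(c(30, 29.07))$r, 0.969)
  s <- multiday_series(as.Date("2019-10-07") + c(0, 2), 79 + c(0, 2),
                       c(0.32, 0.3006))
  expect_equal(fit_rate(s)$r, sqrt(30.06 / 32), tolerance = 1e-12)
  expect_equal(fit_rate(s)$r, 0.9693, tolerance = 1e-4)
  expect_error(fit_rate(c(30, -1)), "non-positive")
  expect_equal(predict_rate(30, 1, 0:8), rep(30, 9))
  expect_equal(predict_rate(30, 0.969, 1), 29.07)
  expect_equal(predict_rate(30, 0.969, 2), 28.169, tolerance = 1e-3)
})

test_that("growth-day lookup follows the printed coefficients", {
  expect_equal(gd_from_gmc(0.25), -40.78 * log(0.25) + 36.02)
  expect_equal(gd_from_gmc(0.25), 92.55, tolerance = 1e-2)
  expect_equal(gd_from_gmc(1), 36.02)  # ln 1 = 0
  expect_equal(gd_from_gmc(0.30), 85.12, tolerance = 1e-2)
  expect_error(gd_from_gmc(0), "positive")
})

test_that("gd-log prediction is monotone decreasing in the horizon", {
  expect_equal(predict_gd_log(0.25, 0), 0.2527, tolerance = 1e-4)
  expect_equal(predict_gd_log(0.30, 3), 0.27796, tolerance = 1e-4)
  p <- predict_gd_log(0.30, 0:8)
  expect_true(all(diff(p) < 0))
})

test_that("gd-log refits recover generating coefficients exactly", {
  s <- simulate_multiday(17, 79, noise_sd = 0)
  f <- fit_gd_log(s)
  expect_equal(f$coeffs[3:4], c(-0.514, 2.58), tolerance = 1e-6)
  expect_equal(unname(f$r_squared[2]), 1, tolerance = 1e-9)
  # noisy refit stays within 15% on the slope (seeded)
  sn <- simulate_multiday(17, 79, noise_sd = 0.005, seed = 8)
  fn <- fit_gd_log(sn)
  expect_lt(abs(fn$coeffs[3] - (-0.514)) / 0.514, 0.15)
  expect_error(fit_gd_log(c(30, 29)), "multiday_series")
})

test_that("near-inverse round trip holds where the two log fits agree", {
  # the two printed regressions are independent fits, not exact inverses:
  # the i = 0 round trip agrees within 0.01 up to GMC0 ~ 0.32 and the
  # discrepancy grows monotonically to 0.0225 at 0.38
  g_lo <- seq(0.20, 0.32, by = 0.005)
  expect_lt(max(abs(predict_gd_log(g_lo, 0) - g_lo)), 0.01)
  g_all <- seq(0.20, 0.38, by = 0.005)
  err <- abs(predict_gd_log(g_all, 0) - g_all)
  expect_lt(max(err), 0.023)
  expect_equal(err[length(err)], 0.02245, tolerance = 1e-3)
})

test_that("fitted models are monotone non-increasing over horizons", {
  s <- simulate_multiday(17, 79, noise_sd = 0.003, seed = 4)
  ml <- fit_linear(s); mr <- fit_rate(s); mg <- fit_gd_log(s)
  expect_lt(ml$delta, 0)
  expect_lt(mr$r, 1)
  expect_gt(mr$r, 0)
  expect_lt(mg$coeffs[3], 0)
  for (m in list(ml, mr, mg))
    expect_true(all(diff(predict_decline(m, 30, 0:8)) <= 0))
})

test_that("mean fitted decline over 100 noisy series brackets the truth", {
  deltas <- vapply(1:100, function(k) {
    set.seed(5000 + k)
    fit_linear(33 - 0.66 * (0:16) + rnorm(17, 0, 0.3))$delta
  }, numeric(1))
  expect_gt(mean(deltas), -0.81)
  expect_lt(mean(deltas), -0.51)
})

test_that("horizon MAE is flat for the generating model, growing for linear", {
  s <- simulate_multiday(17, 79, noise_sd = 0)
  hg <- horizon_mae(s, fit_gd_log(s))
  hl <- horizon_mae(s, fit_linear(s))
  expect_lt(hg["h8"] - hg["h3"], hl["h8"] - hl["h3"])
  expect_lt(max(hg[3:8]) - min(hg[3:8]), 0.02)
  expect_gt(hl["h8"], hl["h3"])
  # a perfect model on its own generating process: zero at all horizons
  perfect <- structure(list(kind = "gd_log",
                            coeffs = c(fit_gd_log(s)$coeffs)),
                       class = "decline_model")
  # single-horizon, two-day series gives one comparison
  s2 <- multiday_series(as.Date("2020-06-01") + 0:1, 80:81, c(0.30, 0.295))
  h1 <- horizon_mae(s2, fit_linear(s2), horizons = 1)
  expect_equal(unname(h1), 0, tolerance = 1e-9)
})

test_that("harvest recommendation bands match the purchase rules", {
  expect_equal(as.character(harvest_band(32)), "inappropriate")
  expect_equal(as.character(harvest_band(30)), "appropriate")
  expect_equal(as.character(harvest_band(25)), "most_appropriate")
  expect_equal(as.character(harvest_band(c(40, 28, 27.9))),
               c("inappropriate", "appropriate", "most_appropriate"))
})

test_that("series constructor enforces its invariants", {
  expect_error(multiday_series(as.Date("2020-01-01") + c(0, 0), 1:2,
                               c(0.3, 0.3)), "strictly")
  expect_error(multiday_series(as.Date("2020-01-01") + 0:1, c(2, 1),
                               c(0.3, 0.3)), "increasing")
  expect_error(multiday_series(as.Date("2020-01-01") + 0:1, 1:2,
                               c(0.3, 1.3)), "fraction")
})
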