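test_that("standardization uses the population variance and is idempotent", {
  z <- ci_standardize(cbind(a = c(1, 2, 3)))
  expect_equal(as.numeric(z$z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(as.numeric(z$z)[1], -1.2247, tolerance = 1e-4)
  expect_warning(z2 <- ci_standardize(cbind(a = 1:5, b = rep(2, 5))),
                 "zero-variance")
  expect_equal(z2$dropped, "b")
  again <- ci_standardize(z$z)
  expect_equal(as.numeric(again$z), as.numeric(z$z), tolerance = 1e-12)
})

test_that("correlation PCA has unit-sum eigenvalues and fixed signs", {
  set.seed(21)
  x <- matrix(rnorm(500 * 6), 500, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  x[, 2] <- x[, 1] * 2 + 5  # a perfectly correlated pair
  p <- ci_pca(ci_standardize(x)$z)
  expect_equal(sum(p$eigenvalues), 6, tolerance = 1e-6)
  # the correlated pair spans one shared component with eigenvalue ~2
  expect_gt(p$eigenvalues[1], 1.9)
  for (j in seq_len(ncol(p$loadings)))
    expect_gte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  # independent variables: all eigenvalues near 1
  set.seed(22)
  xi <- matrix(rnorm(1e5 * 4), ncol = 4,
               dimnames = list(NULL, paste0("u", 1:4)))
  pi_ <- ci_pca(ci_standardize(xi)$z)
  expect_true(all(abs(pi_$eigenvalues - 1) < 0.05))
})

test_that("component retention follows Kaiser with a cumulative fallback", {
  expect_equal(retain_components(c(8.049, 5.466, 4.381, 0.05, 0.02)), 1:3)
  # all below 1: fall back to the 90% cumulative rule
  expect_equal(retain_components(c(0.9, 0.8, 0.7, 0.6) / 3), 1:4)
  ev <- c(0.5, 0.3, 0.1, 0.06, 0.04)
  expect_equal(retain_components(ev), 1:3)  # cum 0.9 at the third
  expect_equal(retain_components(5), 1L)
})

test_that("index selection reproduces the reference eight-index set", {
  # the printed three-component loading table
  L <- rbind(
    R = c(-0.246, 0.303, 0.050), G = c(0.126, 0.392, -0.084),
    B = c(-0.098, 0.057, -0.454), H1 = c(0.337, 0.118, 0.008),
    S1 = c(-0.016, 0.100, 0.464), V1 = c(-0.234, 0.316, 0.049),
    H2 = c(0.337, 0.118, 0.008), L2 = c(-0.211, 0.234, -0.278),
    S2 = c(-0.187, 0.323, 0.176), Lstar = c(0.025, 0.421, -0.074),
    astar = c(-0.338, -0.117, 0.030), bstar = c(0.096, 0.226, 0.384),
    Y = c(-0.292, 0.185, -0.141), Cr = c(-0.082, -0.251, -0.370),
    Cb = c(0.039, 0.307, -0.326), NDI = c(0.334, 0.086, -0.117),
    GI = c(0.335, 0.087, -0.111), RGRI = c(-0.333, -0.086, 0.124))
  sel <- select_cis(L, retained = 1:3)
  expect_setequal(sel, c("H1", "astar", "G", "S2", "Lstar", "B", "S1",
                         "bstar"))
  # an impossible threshold falls back with a warning per lowering step
  warns <- capture_warnings(sel2 <- select_cis(L, 1:3, threshold = 0.99))
  expect_match(warns[1], "lowering")
  expect_gt(length(sel2), 0)
  # one dominant variable per component, no redundancy
  L3 <- diag(3) * 0.9
  rownames(L3) <- c("a", "b", "c")
  expect_equal(select_cis(L3, 1:3), c("a", "b", "c"))
})

test_that("splits are disjoint, exhaustive and reproducible", {
  y <- rnorm(100, 30, 5)
  s1 <- split_and_fold(y, seed = 9)
  s2 <- split_and_fold(y, seed = 9)
  expect_identical(s1, s2)
  expect_equal(length(s1$test), 20)
  expect_equal(sort(c(s1$train, s1$test)), 1:100)
  expect_equal(length(s1$folds), 80)
  expect_equal(as.vector(table(s1$folds)), rep(16L, 5))
  expect_error(split_and_fold(rnorm(6)), "too few")
})

test_that("regressors recover exact structure where they should", {
  set.seed(31)
  x <- matrix(runif(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 + 3 * x[, 1] - 1.5 * x[, 2] + 0.5 * x[, 3]
  mlr <- gmc_train(x, y, regressor_spec("MLR"))
  expect_equal(unname(coef(mlr$fit)), c(2, 3, -1.5, 0.5), tolerance = 1e-8)
  expect_equal(predict(mlr, x), y, tolerance = 1e-8)
  rf <- suppressWarnings(  # constant response triggers a randomForest note
    gmc_train(x[1:50, ], rep(25, 50), regressor_spec("RF", ntree = 50)))
  expect_equal(predict(rf, x[1:5, ]), rep(25, 5), tolerance = 1e-9)
})

test_that("every regressor learns a noiseless monotone hue-GMC mapping", {
  d <- simulate_ci_dataset(400, seed = 5, hue_jitter_sd = 0,
                           rgb_noise_sd = 0, calibrated = FALSE)
  sp <- split_and_fold(d$gmc_wb, seed = 5)
  x <- as.matrix(d[, "H1", drop = FALSE])
  y <- d$gmc_wb
  maes <- vapply(c("SVR", "MLR", "RF", "MLP"), function(kind) {
    m <- gmc_train(x[sp$train, , drop = FALSE], y[sp$train],
                   regressor_spec(kind, seed = 5))
    mean(abs(predict(m, x[sp$test, , drop = FALSE]) - y[sp$test]))
  }, numeric(1))
  expect_true(all(maes < 0.5))
  expect_lt(maes["MLR"], 1e-8)  # the hue-GMC map is linear
})

test_that("seeded training is reproducible", {
  d <- simulate_ci_dataset(120, seed = 6)
  sp <- split_and_fold(d$gmc_wb, seed = 6)
  x <- as.matrix(d[, c("H1", "astar")])
  y <- d$gmc_wb
  for (kind in c("MLR", "RF", "MLP")) {
    p1 <- predict(gmc_train(x[sp$train, ], y[sp$train],
                            regressor_spec(kind, seed = 3)),
                  x[sp$test, ])
    p2 <- predict(gmc_train(x[sp$train, ], y[sp$train],
                            regressor_spec(kind, seed = 3)),
                  x[sp$test, ])
    expect_identical(p1, p2)
  }
})

test_that("metrics follow their definitions", {
  expect_equal(unname(gmc_metrics(c(10, 20), c(10, 20))), c(0, 0, 0))
  expect_equal(unname(gmc_metrics(c(10, 20), c(12, 18))), c(2, 2, 15))
  expect_equal(unname(gmc_metrics(50, 40)), c(10, 10, 20))
  expect_warning(m <- gmc_metrics(c(0, 10), c(1, 11)), "excluded")
  expect_equal(unname(m["MAPE"]), 10)
  y <- rnorm(50, 30, 5); yh <- y + rnorm(50)
  expect_equal(r_squared(y, yh),
               1 - sum((y - yh)^2) / sum((y - mean(y))^2))
})

test_that("interval report stratifies by true GMC", {
  y <- c(30, 45, 28, 38, 31)
  yh <- y + c(1, -2, 0.5, 1, -1)
  rep_ <- interval_report(y, yh)
  expect_equal(rep_$n, c(5L, 4L, 3L))
  expect_true(all(diff(rep_$n) <= 0))
  expect_true(all(rep_[, c("RMSE", "MAE", "MAPE")] >= 0))
  # all below 32: three identical rows
  r2 <- interval_report(c(30, 25, 28), c(31, 24, 29))
  expect_equal(r2$RMSE, rep(r2$RMSE[1], 3))
  # empty subset reported as absent
  r3 <- interval_report(c(45, 50), c(44, 51))
  expect_true(is.na(r3$RMSE[3]))
})
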