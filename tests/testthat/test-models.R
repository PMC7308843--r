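# Kennard-Stone splitting, the three regressors and evaluation metrics.

test_that("Kennard-Stone starts from the extreme pair and honours 3:1", {
  X <- matrix(c(0, 1, 2, 3), ncol = 1)
  plan <- kennard_stone_split(X, ids = c("a", "b", "c", "d"))
  expect_true(all(c("a", "d") %in% plan$calibration_ids))
  expect_length(plan$calibration_ids, 3)
  expect_length(plan$prediction_ids, 1)
})

test_that("the grouped split of 120 samples yields 90/30", {
  ds <- shared_dataset()
  sp <- crop_bands(ds$spectra)
  plan <- kennard_stone_split(sp$X, ds$truth$id, ds$truth$group)
  expect_length(plan$calibration_ids, 90)
  expect_length(plan$prediction_ids, 30)
  # 18/6 inside every storage group
  for (g in 0:4) {
    gid <- ds$truth$id[ds$truth$group == g]
    expect_identical(sum(plan$calibration_ids %in% gid), 18L)
  }
})

test_that("the split is deterministic and row-order invariant", {
  set.seed(55)
  X <- matrix(rnorm(80), 20, 4)
  ids <- sprintf("S%02d", 1:20)
  p1 <- kennard_stone_split(X, ids)
  p2 <- kennard_stone_split(X, ids)
  expect_identical(p1, p2)
  perm <- sample(20)
  p3 <- kennard_stone_split(X[perm, ], ids[perm])
  expect_identical(p1$calibration_ids, p3$calibration_ids)
})

test_that("PLSR at full rank reproduces least squares", {
  set.seed(66)
  for (i in 1:100) {
    n <- sample(15:40, 1); p <- sample(2:8, 1)
    X <- matrix(rnorm(n * p), n, p); y <- rnorm(n)
    fit <- fit_plsr(X, y, p)
    expect_lt(max(abs(predict(fit, X) - ols_oracle(X, y, X))), 1e-6)
  }
})

test_that("PLSR recovers noiseless linear data and centres correctly", {
  set.seed(2)
  X <- matrix(rnorm(200), 40, 5)
  beta <- rnorm(5)
  y <- as.numeric(X %*% beta)
  fit <- fit_plsr(X, y, 5)
  expect_gt(1 - sum((predict(fit, X) - y)^2) / sum((y - mean(y))^2),
            1 - 1e-8)
  expect_equal(predict(fit, matrix(colMeans(X), 1)), mean(y),
               tolerance = 1e-10)
  expect_error(fit_plsr(X, y, 50), "n_components")
})

test_that("SVR fits constants and interpolates with a permissive budget", {
  X <- matrix(rnorm(20), 10, 2)
  fit <- fit_svr(X, rep(2.5, 10), C = 1, gamma = 0.5, epsilon = 0.1)
  expect_true(all(abs(predict(fit, X) - 2.5) <= 0.1 + 1e-8))
  set.seed(12)
  X5 <- matrix(rnorm(10), 5, 2); y5 <- rnorm(5)
  f5 <- fit_svr(X5, y5, C = 1e6, gamma = 1, epsilon = 1e-3)
  expect_true(all(abs(predict(f5, X5) - y5) <= 2e-3))
})

test_that("SVR grid search is deterministic under a fixed seed", {
  set.seed(31)
  X <- matrix(rnorm(60), 30, 2); y <- rnorm(30)
  f1 <- fit_svr(X, y, seed = 9)
  f2 <- fit_svr(X, y, seed = 9)
  expect_identical(f1$hyperparameters, f2$hyperparameters)
  expect_equal(predict(f1, X), predict(f2, X), tolerance = 1e-12)
})

test_that("LWR interpolates locally and reduces to OLS in the uniform limit", {
  set.seed(71)
  X <- matrix(rnorm(100), 25, 4)
  y <- as.numeric(X %*% rnorm(4))
  p <- lwr_predict(X, y, X[3, , drop = FALSE], n_neighbors = 5,
                   bandwidth = 1e-4)
  expect_equal(p, y[3], tolerance = 1e-6)
  for (i in 1:100) {
    set.seed(500 + i)
    n <- sample(15:30, 1); q <- sample(2:5, 1)
    Xi <- matrix(rnorm(n * q), n, q); yi <- rnorm(n)
    Xq <- matrix(rnorm(3 * q), 3, q)
    got <- lwr_predict(Xi, yi, Xq, n_neighbors = n, kernel = "uniform",
                       bandwidth = 1e9, var_kept = 1)
    expect_lt(max(abs(got - ols_oracle(Xi, yi, Xq))), 1e-8)
  }
})

test_that("evaluation metrics match hand arithmetic", {
  ev <- evaluate(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3), c(1, 2, 4))
  expect_equal(ev$rc2, 1); expect_equal(ev$rmsec, 0)
  expect_equal(ev$rmsep, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(ev$rp2, 0.5, tolerance = 1e-12)
  # constant mean predictor scores zero
  y <- c(1, 2, 3, 4)
  ev2 <- evaluate(y, rep(mean(y), 4), y, rep(mean(y), 4))
  expect_equal(ev2$rp2, 0)
  expect_error(evaluate(c(1, 1), c(1, 1), c(2, 2), c(2, 2)), "variance")
})

test_that("RMSECV is near zero for linear data and honest on noise", {
  set.seed(5)
  X <- matrix(rnorm(300), 60, 5)
  y <- as.numeric(X %*% rnorm(5))
  expect_lt(rmsecv(X, y, 5, 5, seed = 1), 1e-8)
  expect_identical(rmsecv(X, y, 5, 5, seed = 2), rmsecv(X, y, 5, 5, seed = 2))
  # pure noise: pooled CV error close to sd(y), no spurious skill
  ratio <- vapply(1:20, function(s) {
    set.seed(900 + s)
    Xn <- matrix(rnorm(90 * 20), 90, 20); yn <- rnorm(90)
    A <- choose_components(Xn, yn, 15, 5, s)
    rmsecv(Xn, yn, 5, A, s) / sd(yn)
  }, numeric(1))
  expect_gt(mean(ratio), 0.85)
  expect_lt(mean(ratio), 1.15)
  expect_error(rmsecv(matrix(rnorm(12), 6, 2), rnorm(6), folds = 4), "fold")
})
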