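test_that("soft thresholding follows its closed form", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(-3, 1), -2)
  z <- seq(-2, 2, by = 0.25)
  expect_equal(soft_threshold(z, 0.5), sign(z) * pmax(abs(z) - 0.5, 0))
  expect_error(soft_threshold(1, -0.1))
})

test_that("standardization yields unit-variance centered columns and drops constants", {
  set.seed(21)
  X <- cbind(a = rnorm(50, 10, 3), b = runif(50), c = rep(2, 50))
  y <- rnorm(50)
  d <- standardize_design(X, y)
  expect_equal(d$names, c("a", "b"))
  expect_equal(d$dropped, "c")
  expect_lt(max(abs(colMeans(d$X_std))), 1e-10)
  expect_lt(max(abs(sqrt(colSums(d$X_std^2) / d$n) - 1)), 1e-10)
  expect_equal(mean(d$y_centered), 0)
})

test_that("penalties at or above lambda_max give the null model", {
  set.seed(22)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(20, X[, 1])
  d <- standardize_design(X, y)
  lmax <- max(abs(crossprod(d$X_std, d$y_centered))) / d$n
  f <- fit_lasso(d, lmax * 1.0001)
  expect_true(all(f$beta_std == 0))
  expect_equal(f$intercept_raw, mean(y))
})

test_that("the lambda grid follows its formula and endpoints nest", {
  x <- c(scale(rnorm(25)))            # single predictor
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- 0.8 * x + 0                    # x'y/n = 0.8 exactly after centering?
  X <- matrix(x, dimnames = list(NULL, "x"))
  d <- standardize_design(X, y)
  lmax <- max(abs(crossprod(d$X_std, d$y_centered))) / d$n
  grid <- lambda_path(d, n_lambda = 100, ratio = 0.001)
  expect_equal(grid[1], lmax)
  expect_equal(length(grid), 100)
  expect_true(all(diff(grid) < 0))
  expect_equal(grid[100], 0.001 * lmax)
  f_hi <- fit_lasso(d, grid[1])
  f_lo <- fit_lasso(d, grid[100])
  active_hi <- names(which(f_hi$beta_std != 0))
  active_lo <- names(which(f_lo$beta_std != 0))
  expect_true(all(active_hi %in% active_lo))
  expect_error(lambda_path(standardize_design(X, rep(2, 25)), 100, 0.001),
               "degenerate response")
})

test_that("orthonormal designs reproduce the soft-threshold closed form", {
  set.seed(23)
  for (i in 1:5) {
    Q <- orthonormal_design(30, 4)
    y <- rnorm(30, Q %*% c(1, -0.5, 0, 0.2))
    d <- standardize_design(Q, y)
    lam <- runif(1, 0.05, 0.6)
    f <- fit_lasso(d, lam, tol = 1e-10)
    closed <- soft_threshold(drop(crossprod(d$X_std, d$y_centered)) / d$n, lam)
    expect_lt(max(abs(f$beta_std - closed)), 1e-8)
  }
})

test_that("coordinate descent attains the KKT-oracle objective on random instances", {
  set.seed(24)
  for (i in 1:15) {
    n <- sample(15:30, 1); p <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, letters[1:p]))
    y <- rnorm(n, X %*% rnorm(p))
    d <- standardize_design(X, y)
    lam <- runif(1, 0.02, 0.5)
    f <- fit_lasso(d, lam, tol = 1e-10)
    oracle <- lasso_kkt_oracle(d$X_std, d$y_centered, lam)
    expect_lte(lasso_objective(d, f$beta_std[d$names], lam),
               oracle$value + 1e-6)
    expect_lt(max(abs(f$beta_std[d$names] - oracle$beta)), 1e-5)
  }
})

test_that("the debug path asserts a non-increasing objective and matches the kernel", {
  set.seed(25)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, letters[1:5]))
  y <- rnorm(40, X[, 1] - X[, 3])
  d <- standardize_design(X, y)
  f_dbg <- fit_lasso(d, 0.1, tol = 1e-9, debug = TRUE)
  expect_true(all(diff(f_dbg$objective_trace) <= 1e-10))
  f_cpp <- fit_lasso(d, 0.1, tol = 1e-9)
  expect_lt(max(abs(f_dbg$beta_std - f_cpp$beta_std)), 1e-7)
})

test_that("raw-scale predictions equal standardized-scale predictions", {
  set.seed(26)
  X <- cbind(a = rnorm(60, 50, 9), b = rpois(60, 4), c = rbinom(60, 1, 0.3))
  y <- rnorm(60, 0.2 * X[, 1] - X[, 3])
  d <- standardize_design(X, y)
  f <- fit_lasso(d, 0.05, tol = 1e-10)
  pred_raw <- drop(X %*% f$beta_raw) + f$intercept_raw
  pred_std <- drop(d$X_std %*% f$beta_std[d$names]) + d$y_mean
  expect_lt(max(abs(pred_raw - pred_std)), 1e-8)
})

test_that("active sets grow weakly along the path", {
  set.seed(27)
  ok <- 0; tot <- 0
  for (i in 1:10) {
    X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, letters[1:6]))
    y <- rnorm(40, X %*% c(2, -1, 0.5, 0, 0, 0))
    d <- standardize_design(X, y)
    grid <- lambda_path(d, 30, 0.01)
    fit <- pcqlasso:::cd_path_fit(d, grid, 1e-8, 1e5)
    sizes <- colSums(fit$beta != 0)
    ok <- ok + sum(diff(sizes) >= 0)
    tot <- tot + length(sizes) - 1
  }
  expect_gte(ok / tot, 0.95)
})

test_that("cross-validation is deterministic, balanced, and selects true signal", {
  d <- simulate_survey(sim_config(n = 100, seed = 28))
  cv1 <- cv_lasso(d, "pcq_total", k = 10, seed = 29)
  cv2 <- cv_lasso(d, "pcq_total", k = 10, seed = 29)
  expect_identical(cv1[c("lambda_min", "cv_mean", "beta_raw", "fold_assignment")],
                   cv2[c("lambda_min", "cv_mean", "beta_raw", "fold_assignment")])
  expect_true(all(table(cv1$fold_assignment) == 10))
  expect_true(cv1$lambda_min %in% cv1$lambda_grid)
  expect_true(all(is.finite(cv1$cv_mean)))
  expect_error(cv_lasso(d[1:5, ], "pcq_total", k = 10), "fewer complete cases")

  # strong planted signal: active set at lambda_min contains the truth
  set.seed(30)
  hits <- 0
  for (r in 1:100) {
    n <- 300; p <- 10
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    y <- drop(X[, 1:3] %*% c(5, 5, 5)) + rnorm(n)
    dat <- data.frame(y = y, X)
    cv <- cv_lasso(dat, "y", paste0("x", 1:p), k = 10, n_lambda = 50,
                   seed = r)
    if (all(cv$beta_raw[c("x1", "x2", "x3")] != 0)) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
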