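test_that("perfect and null predictors behave as the contracts state", {
  v <- withr::with_seed(30, rnorm(2000, 0, 90))
  fit <- ols_fit(cbind(x = v), v, n_splits = 3)
  expect_equal(fit$r_test, 1, tolerance = 1e-12)
  expect_equal(fit$mse_test, 0, tolerance = 1e-10)
  expect_equal(unname(fit$weights), 1, tolerance = 1e-10)

  X0 <- withr::with_seed(31, cbind(rnorm(2000)))
  fit0 <- ols_fit(X0, v, n_splits = 5)
  expect_lt(abs(fit0$r_test), 0.1)
  expect_equal(fit0$mse_test, mean(v^2), tolerance = 0.05 * mean(v^2))
})

test_that("weights equal the normal-equation oracle on a small system", {
  withr::with_seed(32, {
    X <- matrix(rnorm(300), 100, 3)
    v <- drop(X %*% c(2, -1, 0.5)) + rnorm(100)
  })
  fit <- ols_fit(X, v, n_splits = 1, seed = 4)
  sp <- flymotion:::split_pairs(seq_len(100), 4)
  Xtr <- X[sp$train, ]
  oracle <- solve(t(Xtr) %*% Xtr, t(Xtr) %*% v[sp$train])
  expect_equal(unname(fit$weights), drop(oracle), tolerance = 1e-10)
})

test_that("rank-deficient designs fall back to the minimum-norm solution", {
  withr::with_seed(33, {
    x <- rnorm(200)
    v <- 2 * x + rnorm(200, 0, 0.1)
  })
  X <- cbind(a = x, b = x) # duplicated predictor
  expect_warning(fit <- ols_fit(X, v, n_splits = 1), "rank deficient")
  expect_equal(unname(fit$weights[1]), unname(fit$weights[2]),
               tolerance = 1e-8) # minimum norm spreads the weight equally
  expect_equal(sum(fit$weights), 2, tolerance = 0.05)
})

test_that("optimal scaling satisfies the MSE-correlation identity", {
  withr::with_seed(34, {
    v <- rnorm(5000, 0, 90)
    noise <- rnorm(5000, 0, 90)
  })
  s2 <- scale_output(2 * v, v)
  expect_equal(attr(s2, "scale"), 0.5, tolerance = 1e-12)
  expect_equal(mean((v - s2)^2), 0, tolerance = 1e-18)
  sm <- scale_output(-v, v)
  expect_equal(attr(sm, "r"), -1)
  expect_equal(mean((v - sm)^2), 0, tolerance = 1e-18)
  # additive noise of matched SD: r ~ 1/sqrt(2), scaled MSE ~ sigma_v^2 / 2
  sn <- scale_output(v + noise, v)
  expect_equal(attr(sn, "r"), 1 / sqrt(2), tolerance = 0.03)
  expect_equal(mean((v - sn)^2), mean(v^2) * (1 - attr(sn, "r")^2),
               tolerance = 1e-9 * mean(v^2))
  expect_warning(z <- scale_output(rep(0, 10), rnorm(10)), "zero spread")
  expect_equal(as.numeric(z), rep(0, 10))
})

test_that("mirror pairs never straddle a cross-validation fold", {
  pair_id <- rep(1:50, each = 2)
  sp <- flymotion:::split_pairs(pair_id, 9)
  tr_pairs <- unique(pair_id[sp$train])
  te_pairs <- unique(pair_id[sp$test])
  expect_length(intersect(tr_pairs, te_pairs), 0)
  expect_equal(sort(c(tr_pairs, te_pairs)), 1:50)
})

test_that("training accuracy is monotone along the nested hierarchy", {
  chs <- test_channels()
  r_tr <- vapply(c("hrc", "quadrant", "poly4", "poly6"), function(a) {
    fit_estimator(chs, a, n_splits = 1, seed = 2)$r_train
  }, numeric(1))
  expect_true(all(diff(r_tr) >= -1e-12))
})

test_that("lasso limits and planted-model recovery work", {
  withr::with_seed(36, {
    n <- 4000
    X <- matrix(rnorm(n * 50), n, 50)
    w_true <- numeric(50)
    true_idx <- c(3, 11, 22, 37, 48)
    w_true[true_idx] <- c(4, -3, 2.5, -2, 3.5)
    signal <- drop(X %*% w_true)
    v <- signal + rnorm(n, 0, sd(signal))
  })
  pid <- seq_len(n)
  scan <- lasso_scan(X, v, pair_id = pid, seed = 1, baseline_r = 0)
  expect_error(lasso_scan(X, v, penalty_grid = numeric(0)), "Empty penalty")
  # extreme penalty: empty support, r = 0
  big <- lasso_scan(X, v, penalty_grid = c(1e4, 1e3), pair_id = pid)
  expect_equal(big$n_support[1], 0)
  expect_equal(big$r_test[1], 0)
  # tiny penalty: full-ish support matches plain OLS accuracy
  r_ols <- attr(scan, "r_full")
  near0 <- scan$r_test[which.max(scan$n_support)]
  expect_equal(near0, r_ols, tolerance = 0.01)
  # the 5 planted predictors are recovered exactly at some penalty
  hit <- vapply(scan$support, function(s) setequal(s, true_idx), logical(1))
  expect_true(any(hit))
  # gain fractions are on the (0, 1] scale at the full support
  expect_equal(max(scan$gain_fraction, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("tidy and glance expose the fit in broom shape", {
  chs <- test_channels()
  fit <- fit_estimator(chs, "quadrant", n_splits = 2)
  td <- tidy(fit)
  expect_equal(td$term, c("pp", "pm", "mp", "mm"))
  expect_type(td$estimate, "double")
  gl <- glance(fit)
  expect_equal(gl$n_predictors, 4)
  expect_equal(gl$n, nrow(chs))
  expect_true(abs(gl$r_test) <= 1)
  expect_equal(fit$mse_test,
               fit$sigma_v^2 * (1 - mean(fit$splits$r_test^2)),
               tolerance = 0.02 * fit$sigma_v^2)
})
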