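test_that("fuse is plain multiplication with sign preserved", {
  expect_equal(fuse(0.5, 0.8), 0.4)
  expect_equal(fuse(0.73, 1), 0.73)
  expect_equal(fuse(-0.1, 0.3), -0.03)   # VARI can be negative
  expect_error(fuse(Inf, 1), class = "wtvi_contract_error")
  expect_error(fuse(0.5, NA), class = "wtvi_contract_error")
})

test_that("fit_linear recovers a noiseless line and validates inputs", {
  x <- 1:10
  fit <- fit_linear(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-12)
  expect_error(fit_linear(1:2, 1:2), class = "wtvi_degenerate_error")
  expect_error(fit_linear(rep(1, 5), 1:5), class = "wtvi_degenerate_error")
  expect_error(fit_linear(1:5, rep(2, 5)), class = "wtvi_degenerate_error")
})

test_that("fit_linear matches the normal-equations oracle", {
  # fixed 6-point fixture
  x <- c(0.1, 0.4, 0.5, 0.9, 1.3, 2.0)
  y <- c(1.2, 2.1, 1.9, 3.4, 4.1, 6.3)
  fit <- fit_linear(x, y)
  ref <- ols_oracle(x, y)
  expect_equal(fit$intercept, ref[1], tolerance = 1e-10)
  expect_equal(fit$slope, ref[2], tolerance = 1e-10)
  expect_equal(fit$rmse,
               sqrt(mean((y - ref[1] - ref[2] * x)^2)), tolerance = 1e-10)
  expect_equal(fit$rrmse, 100 * fit$rmse / mean(y), tolerance = 1e-10)
  # random datasets
  for (seed in 1:10) {
    d <- withr::with_seed(seed, list(x = runif(30), y = rnorm(30)))
    fit <- fit_linear(d$x, d$y)
    ref <- ols_oracle(d$x, d$y)
    expect_equal(c(fit$intercept, fit$slope), ref, tolerance = 1e-10)
  }
})

test_that("folds are disjoint, exhaustive and near-equal", {
  x <- withr::with_seed(2, runif(20)); y <- 2 * x + 1
  cv <- kfold_evaluate(x, y, k = 10, seed = 5)
  expect_equal(cv$k, 10L)
  expect_equal(sort(unique(cv$folds$n_test)), 2L)  # every fold size 2
  # remainder handling: n = 23, k = 10 -> three folds of 3, seven of 2
  cv2 <- kfold_evaluate(runif(23), rnorm(23) + 1:23, k = 10, seed = 5)
  expect_equal(sort(cv2$folds$n_test), c(rep(2L, 7), rep(3L, 3)))
  expect_equal(sum(cv2$folds$n_test), 23L)
  expect_error(kfold_evaluate(x, y, k = 25, seed = 1),
               class = "wtvi_contract_error")
  expect_error(kfold_evaluate(x, y, k = 1, seed = 1),
               class = "wtvi_contract_error")
})

test_that("aggregates are the exact means of per-fold values", {
  d <- withr::with_seed(11, list(x = runif(57, 0, 5)))
  d$y <- withr::with_seed(12, 3 * d$x + 2 + rnorm(57, sd = 0.5))
  cv <- kfold_evaluate(d$x, d$y, k = 7, seed = 99)
  expect_identical(cv$coef2, mean(cv$folds$slope^2))
  expect_identical(cv$r2, mean(cv$folds$r2))
  expect_identical(cv$rmse, mean(cv$folds$rmse))
  expect_identical(cv$rrmse, mean(cv$folds$rrmse))
})

test_that("identical seeds give identical CV results; seeds matter", {
  d <- withr::with_seed(21, list(x = runif(50), e = rnorm(50, sd = 0.3)))
  y <- 1.5 * d$x + d$e
  a <- kfold_evaluate(d$x, y, k = 5, seed = 123)
  b <- kfold_evaluate(d$x, y, k = 5, seed = 123)
  expect_identical(a$folds, b$folds)
  expect_identical(cv_summary(a), cv_summary(b))
  c <- kfold_evaluate(d$x, y, k = 5, seed = 124)
  expect_false(identical(a$folds, c$folds))
})

test_that("noiseless data give mean R2 = 1 and RMSE = 0 for any k/seed", {
  x <- withr::with_seed(3, runif(40, 0, 3))
  y <- -0.7 * x + 4
  for (k in c(2, 5, 10)) {
    cv <- kfold_evaluate(x, y, k = k, seed = k * 7)
    expect_equal(cv$r2, 1, tolerance = 1e-12)
    expect_equal(cv$rmse, 0, tolerance = 1e-12)
    expect_equal(cv$coef2, 0.49, tolerance = 1e-12)
  }
})

test_that("CV on y = 3x + 2 + N(0, 0.5) behaves as sampling theory predicts", {
  n <- 200
  x <- withr::with_seed(31, runif(n, 0, 5))
  y <- withr::with_seed(32, 3 * x + 2 + rnorm(n, sd = 0.5))
  cv <- kfold_evaluate(x, y, k = 10, seed = 7)
  expect_gt(cv$rmse, 0.4); expect_lt(cv$rmse, 0.6)
  fit <- fit_linear(x, y)
  se_slope <- sqrt(sum((y - fit$slope * x - fit$intercept)^2) / (n - 2) /
                   sum((x - mean(x))^2))
  expect_lt(abs(fit$slope - 3), 3 * se_slope)
  expect_lt(abs(cv$slope - 3), 3 * se_slope)
})

test_that("rank_indices orders by R2 with RMSE/name tie-breaks", {
  n <- 60
  lai <- withr::with_seed(41, runif(n, 0.5, 8))
  tab <- data.frame(
    LAI = lai,
    VI_good = 0.2 * lai + withr::with_seed(42, rnorm(n, sd = 0.05)),
    VI_noise = withr::with_seed(43, rnorm(n)))
  res <- rank_indices(tab, k = 5, seed = 9)
  expect_equal(res[[1]]$name, "VI_good")
  # duplicated feature: identical metrics, name order breaks the tie
  tab$WTVI_copyB <- tab$VI_good
  tab$WTVI_copyA <- tab$VI_good
  res2 <- rank_indices(tab, k = 5, seed = 9)
  nm <- vapply(res2, `[[`, character(1), "name")
  dup <- nm[nm %in% c("VI_good", "WTVI_copyA", "WTVI_copyB")]
  expect_equal(dup, sort(dup))
  r2s <- vapply(res2, `[[`, numeric(1), "r2")
  expect_equal(length(unique(round(r2s[match(dup, nm)], 12))), 1L)
})
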