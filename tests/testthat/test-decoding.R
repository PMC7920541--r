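# d-prime, logistic outcome models, linear SVM decoding.

test_that("d-prime matches the inverse-normal oracle and its conventions", {
  expect_equal(dprime(0.6, 0.6)$dprime, 0)
  res <- dprime(0.975, 0.025)
  oracle <- stats::qnorm(0.975) - stats::qnorm(0.025)
  expect_equal(res$dprime, oracle)
  expect_equal(round(res$dprime, 2), 3.92)
  expect_equal(res$scaled, oracle / 4.65)
  expect_equal(round(res$scaled, 3), 0.843)
  # antisymmetry
  a <- dprime(0.9, 0.3)$dprime
  b <- dprime(0.3, 0.9)$dprime
  expect_equal(a, -b)
  # clipping
  expect_warning(r <- dprime(1, 0.1, n = 50), "clip")
  expect_equal(r$dprime, stats::qnorm(1 - 1 / 100) - stats::qnorm(0.1))
  expect_error(dprime(1, 0.1), "n")
})

test_that("univariate regression recovers a planted feature-outcome link", {
  set.seed(30)
  n <- 40
  y <- rep(c(1, 0), each = n / 2)
  x <- array(stats::rnorm(n * 3 * 4), c(n, 3, 4))
  x[, 2, 3] <- y + stats::rnorm(n, sd = 0.2)
  res <- univariate_outcome_regression(x, y)
  expect_true(res$mask[2, 3])
  expect_gt(res$beta[2, 3], 0)
  # constant feature: beta 0, p 1
  x[, 1, 1] <- 2
  res2 <- univariate_outcome_regression(x, y)
  expect_equal(res2$beta[1, 1], 0)
  expect_equal(res2$p[1, 1], 1)
})

test_that("univariate regression is calibrated on null features", {
  set.seed(31)
  runs <- 60
  nonempty <- 0
  pvals <- c()
  for (i in seq_len(runs)) {
    y <- rep(c(1, 0), each = 12)
    x <- array(stats::rnorm(24 * 4 * 5), c(24, 4, 5))
    res <- univariate_outcome_regression(x, y)
    nonempty <- nonempty + any(res$mask)
    pvals <- c(pvals, as.vector(res$p))
  }
  # BH under the global null flags anything in ~5% of runs; allow MC slack
  expect_lte(nonempty / runs, 0.15)
  # raw p approximately uniform
  expect_lt(stats::ks.test(pvals, "punif")$statistic, 0.05)
})

test_that("pairwise wPLI regression handles zero-difference and planted
           pair features", {
  set.seed(32)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  x <- array(stats::rnorm(n * 5 * 5, sd = 0.1), c(n, 5, 5))
  for (i in 1:5) x[, i, i] <- NA
  x[, 2, 4] <- x[, 4, 2] <- 0.3 * y + stats::rnorm(n, sd = 0.1)
  res <- wpli_outcome_regression(x, y, labels = letters[1:5])
  expect_true(res$mask["b", "d"])
  expect_gt(res$beta["b", "d"], 0)
  expect_lt(mean(res$mask[upper.tri(res$mask)], na.rm = TRUE), 0.3)
  # all-zero differences -> empty mask
  x0 <- array(0, c(n, 3, 3))
  res0 <- wpli_outcome_regression(x0, y)
  expect_false(any(res0$mask, na.rm = TRUE))
})

test_that("multivariate model recovers planted signs and stays null-calibrated", {
  set.seed(33)
  plan <- c(1.5, 1.5, -1.5, rep(0, 7))
  hits <- replicate(50, {
    X <- matrix(stats::rnorm(80 * 10), 80)
    pr <- 1 / (1 + exp(-(X %*% plan)))
    y <- stats::rbinom(80, 1, pr)
    fit <- multivariate_connectivity_model(X, y)
    all(sign(fit$beta[1:3]) == sign(plan[1:3]))
  })
  expect_gte(mean(hits), 0.9)
  # outcome independent of features: pseudo-R2 near zero
  set.seed(34)
  r2 <- replicate(20, {
    X <- matrix(stats::rnorm(60 * 5), 60)
    y <- stats::rbinom(60, 1, 0.5)
    multivariate_connectivity_model(X, y)$pseudo_r2
  })
  expect_lt(stats::median(r2), 0.1)
  # rank-deficient design errors with the collinear feature named
  X <- matrix(stats::rnorm(40 * 3), 40)
  X <- cbind(X, dup = X[, 1])
  colnames(X) <- c("a", "b", "c", "dup")
  y <- stats::rbinom(40, 1, 0.5)
  expect_error(multivariate_connectivity_model(X, y), "dup")
})

test_that("separation triggers the flagged ridge fallback", {
  y <- rep(c(0, 1), each = 10)
  x <- matrix(y * 2 - 1 + stats::rnorm(20, sd = 1e-4), ncol = 1)
  fit <- oscnet:::logistic_fit(x, y)
  expect_true(fit$separated)
  expect_true(is.finite(fit$beta) && fit$beta > 0)
  expect_true(is.finite(fit$p))
})

test_that("SVM decodes separable data perfectly and permuted labels at
           chance", {
  set.seed(35)
  n <- 40
  y <- rep(c(1, 0), n / 2)
  x <- array(stats::rnorm(n * 3 * 6, sd = 0.1), c(n, 3, 6))
  x[, 1, ] <- x[, 1, ] + 2 * (2 * y - 1)         # separable everywhere
  times <- seq(0, 1, length.out = 6)
  res <- svm_timecourse(x, y, times, repeats = 3, seed = 2)
  expect_true(all(res$accuracy == 1))
  expect_gt(res$importance[1], 0.5)
  # permuted labels: chance-level accuracy
  yp <- sample(y)
  null <- array(stats::rnorm(n * 3 * 6), c(n, 3, 6))
  res0 <- svm_timecourse(null, yp, times, repeats = 3, seed = 2)
  expect_lt(abs(mean(res0$accuracy) - 0.5), 0.2)
  expect_error(svm_timecourse(x[1:6, , , drop = FALSE], y[1:6], times),
               "4 rows")
})

test_that("factor importance is invariant to feature scaling", {
  set.seed(36)
  n <- 32
  y <- rep(c(1, 0), n / 2)
  x <- array(stats::rnorm(n * 4 * 3), c(n, 4, 3))
  x[, 2, ] <- x[, 2, ] + (2 * y - 1)
  times <- c(0.5, 0.7, 0.9)
  r1 <- svm_timecourse(x, y, times, repeats = 2, seed = 3)
  xs <- x
  xs[, 2, ] <- xs[, 2, ] * 1000                  # rescaled feature
  r2 <- svm_timecourse(xs, y, times, repeats = 2, seed = 3)
  expect_equal(r1$importance, r2$importance, tolerance = 1e-6)
})

test_that("outcome datasets stack condition summaries row-wise", {
  a <- array(seq_len(12), c(3, 2, 2))
  b <- -a
  ds <- outcome_dataset(a, b)
  expect_equal(dim(ds$x), c(6, 2, 2))
  expect_equal(ds$y, c(1, 1, 1, 0, 0, 0))
  expect_equal(ds$x[1, , ], a[1, , ])
  expect_equal(ds$x[4, , ], b[1, , ])
})
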