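test_that("fence thresholds follow the percentile-fence construction", {
  f <- fence_thresholds(0:10)
  expect_equal(f$p10, 1)
  expect_equal(f$p90, 9)
  expect_equal(f$t_low, -11)
  expect_equal(f$t_high, 21)
  expect_false(f$degenerate)

  # translation equivariance
  f2 <- fence_thresholds(0:10 + 3.7)
  expect_equal(f2$t_low, f$t_low + 3.7)
  expect_equal(f2$t_high, f$t_high + 3.7)

  # constant sample flags degeneracy and yields unit weights
  fc <- fence_thresholds(rep(5, 10))
  expect_true(fc$degenerate)
  expect_equal(fc$t_low, fc$t_high)
  expect_warning(w <- outlier_weight(c(0, 5, 100), fc))
  expect_equal(w, c(1, 1, 1))

  expect_error(fence_thresholds(3), "at least 2")
})

test_that("outlier weight is 1 inside the fences and decays as a Gaussian kernel", {
  f <- fence_thresholds(0:10)
  width <- f$t_high - f$t_low
  inside <- seq(f$t_low, f$t_high, length.out = 23)
  expect_equal(outlier_weight(inside, f), rep(1, 23))

  # half a fence-width beyond a fence: exp(-0.5) under the adopted reading
  expect_equal(outlier_weight(f$t_high + 0.5 * width, f), exp(-0.5))
  expect_equal(outlier_weight(f$t_low - 0.5 * width, f), exp(-0.5))

  # symmetric excursions get equal weights
  for (d in c(0.1, 2, 17, 120)) {
    expect_equal(outlier_weight(f$t_low - d, f),
                 outlier_weight(f$t_high + d, f))
  }

  # monotone decay and continuity at the fence
  d <- seq(0, 50, by = 0.5)
  w <- outlier_weight(f$t_high + d, f)
  expect_true(all(diff(w) <= 0))
  expect_equal(w[1], 1)
  expect_lt(abs(outlier_weight(f$t_high + 1e-9, f) - 1), 1e-12)
  expect_lt(outlier_weight(f$t_high + 1e4, f), 1e-10)
})

test_that("geometric-mean weight combination behaves on the documented cases", {
  expect_equal(combine_weights(c(1, 1)), 1)
  expect_equal(combine_weights(c(0.25, 1)), 0.5)
  expect_equal(combine_weights(c(0.7, 0.7, 0.7)), 0.7)
  expect_equal(combine_weights(numeric(0)), 1)
  m <- rbind(c(0.25, 1), c(1, 1), c(0.5, 0.5))
  expect_equal(combine_weights(m), c(0.5, 1, 0.5))
  expect_true(all(combine_weights(matrix(runif(30, 0.01, 1), 10)) <= 1))
  expect_error(combine_weights(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("weighted linear fit matches the normal-equations oracle and lm", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(8:20, 1)
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n)
    y <- rnorm(n)
    w <- runif(n, 0.2, 1)
    fit <- weighted_linear_fit(y, X, weights = w)
    D <- cbind(1, X)
    oracle <- solve(t(D) %*% diag(w) %*% D, t(D) %*% (w * y))
    expect_lt(max(abs(fit$coefficients - oracle)), 1e-10)
    ref <- lm(y ~ X, weights = w)
    expect_lt(max(abs(fit$coefficients - coef(ref))), 1e-10)
    expect_lt(max(abs(fit$p_value - summary(ref)$coefficients[, 4])), 1e-10)
  }
})

test_that("weighted linear fit reproduces exact relations and replication weights", {
  x <- 1:10
  fit <- weighted_linear_fit(2 * x, x)
  expect_equal(unname(fit$coefficients), c(0, 2), tolerance = 1e-12)
  expect_lt(max(abs(fit$residuals)), 1e-12)

  # integer weight k is equivalent to replicating the row k times
  set.seed(1)
  y <- rnorm(8); x <- rnorm(8)
  k <- c(3L, 1L, 2L, 1L, 1L, 4L, 1L, 2L)
  fw <- weighted_linear_fit(y, x, weights = k)
  frep <- weighted_linear_fit(rep(y, k), rep(x, k))
  expect_equal(fw$coefficients, frep$coefficients, tolerance = 1e-12)
})

test_that("weighted linear fit rejects singular designs naming the columns", {
  x <- rnorm(12)
  X <- cbind(a = x, b = 2 * x)
  expect_error(weighted_linear_fit(rnorm(12), X), "collinear")
})

test_that("weighted logistic fit matches glm and is weight-scale invariant", {
  set.seed(7)
  n <- 80
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * x))
  fit <- weighted_logistic_fit(y, x)
  ref <- glm(y ~ x, family = binomial())
  expect_lt(max(abs(fit$coefficients - coef(ref))), 1e-6)
  expect_lt(max(abs(fit$se - summary(ref)$coefficients[, 2])), 1e-6)

  w <- runif(n, 0.3, 1)
  fw <- weighted_logistic_fit(y, x, weights = w)
  refw <- suppressWarnings(glm(y ~ x, family = binomial(), weights = w))
  expect_lt(max(abs(fw$coefficients - coef(refw))), 1e-6)
  fw2 <- weighted_logistic_fit(y, x, weights = 2 * w)
  expect_equal(fw$coefficients, fw2$coefficients, tolerance = 1e-9)
})

test_that("weighted logistic fit: symmetry, separation, and class checks", {
  # perfectly balanced symmetric data -> intercept 0
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  xs <- c(x, -x); ys <- c(y, 1 - y)
  # jitter breaks complete separation while preserving symmetry
  xs2 <- c(xs, 0.5, -0.5); ys2 <- c(ys, 0, 1)
  fit <- weighted_logistic_fit(ys2, xs2)
  expect_lt(abs(fit$coefficients[1]), 1e-8)

  expect_error(weighted_logistic_fit(as.numeric(x > 0), x), "separat")
  expect_error(weighted_logistic_fit(rep(1, 6), x), "classes")
  expect_error(weighted_logistic_fit(c(0, 1, 2, 1, 0, 1), x), "0/1")
})

test_that("joint F-test agrees with anova on nested weighted models", {
  set.seed(11)
  n <- 40
  x1 <- rnorm(n); x2 <- rnorm(n); y <- 1 + 0.5 * x1 + rnorm(n)
  w <- runif(n, 0.4, 1)
  full <- weighted_linear_fit(y, cbind(x1 = x1, x2 = x2), weights = w)
  red <- weighted_linear_fit(y, x1, weights = w)
  jt <- joint_f_test(full, red)
  ref <- anova(lm(y ~ x1, weights = w), lm(y ~ x1 + x2, weights = w))
  expect_equal(jt$statistic, ref$F[2], tolerance = 1e-10)
  expect_equal(jt$p_value, ref$`Pr(>F)`[2], tolerance = 1e-10)
})
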