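test_that("leverages match direct matrix algebra and the trace identity", {
  X <- cbind(1, c(0, 1, 2))
  expect_equal(leverages(X), c(5/6, 1/3, 5/6), tolerance = 1e-12)
  expect_equal(leverages(matrix(1, 10, 1)), rep(0.1, 10))
  for (i in 1:20) {
    set.seed(300 + i)
    n <- 15 + i; p <- 1 + i %% 4
    X <- cbind(1, matrix(rnorm(n * p), n, p))
    w <- runif(n, 0.5, 2)
    h <- leverages(X, w)
    # direct computation of diag(W^1/2 X (X'WX)^-1 X' W^1/2)
    H <- sqrt(w) * X %*% solve(crossprod(X * sqrt(w))) %*% t(X * sqrt(w))
    expect_equal(h, diag(H), tolerance = 1e-10)
    expect_equal(sum(h), ncol(X), tolerance = 1e-10)
    expect_true(all(h >= 0 & h < 1))
  }
  expect_error(leverages(cbind(1, 1:4, 2 * (1:4))), "singular")
})

test_that("intercept-only dispersion reduces to OLS with sigma2 = RSS/(n-p)", {
  for (i in 1:50) {
    set.seed(400 + i)
    n <- 40 + i
    X <- cbind(1, rnorm(n), rbinom(n, 2, 0.4))
    y <- drop(X %*% c(1, 0.5, 0.2)) + rnorm(n)
    f <- dglm_fit(y, X, matrix(1, n, 1))
    ols <- lm.fit(X, y)
    expect_equal(unname(coef(f)), unname(ols$coefficients), tolerance = 1e-8)
    expect_equal(f$sigma2[1], sum(ols$residuals^2) / (n - 3), tolerance = 1e-8)
    expect_true(f$converged)
  }
})

test_that("fit satisfies its structural invariants", {
  set.seed(21)
  n <- 500
  g <- rbinom(n, 2, 0.4)
  y <- rnorm(n, 0.3 * g, exp(0.5 * 0.3 * g))
  f <- dglm_fit(y, cbind(1, g), cbind(1, g))
  expect_true(all(f$sigma2 > 0))
  expect_true(all(f$leverages >= 0 & f$leverages < 1))
  expect_equal(sum(f$leverages), 2, tolerance = 1e-8)
  expect_true(is.finite(f$loglik))
  # log-likelihood is non-decreasing across outer iterations
  expect_true(all(diff(f$loglik_trace) > -1e-6))
})

test_that("dispersion coefficient is recovered at large n", {
  set.seed(77)
  n <- 50000
  g <- rbinom(n, 2, 0.4)
  y <- rnorm(n, 0, sqrt(exp(0 + 0.2 * g)))
  f <- dglm_fit(y, cbind(1, g), cbind(1, g))
  expect_lt(abs(f$dispersion$coefficients[2] - 0.2), 0.03)
})

test_that("estimation error of the dispersion effect shrinks with n", {
  err <- sapply(c(1000, 10000), function(n) {
    e <- numeric(20)
    for (i in 1:20) {
      set.seed(600 + i)
      g <- rbinom(n, 2, 0.4)
      y <- rnorm(n, 0.1 * g, sqrt(exp(0.25 * g)))
      e[i] <- abs(dglm_fit(y, cbind(1, g), cbind(1, g))$dispersion$coefficients[2] - 0.25)
    }
    median(e)
  })
  expect_lt(err[2], err[1])
})

test_that("the poisson family fits mean and dispersion submodels sensibly", {
  set.seed(31)
  n <- 5000
  g <- rbinom(n, 2, 0.4)
  y <- rpois(n, exp(-1 + 0.3 * g))
  f <- dglm_fit(y, cbind(1, g), cbind(1, g), family = "poisson")
  expect_true(f$converged)
  expect_equal(unname(coef(f)), c(-1, 0.3), tolerance = 0.15)
  # equidispersed data: dispersion near 1, slope near 0
  expect_lt(abs(f$dispersion$coefficients[2]), 0.2)
  expect_error(dglm_fit(y + 0.5, cbind(1, g), cbind(1, g), family = "poisson"),
               "integer")
})

test_that("degenerate designs and inputs are rejected", {
  y <- rnorm(20)
  expect_error(dglm_fit(y, cbind(1, 1:20, 2 * (1:20)), matrix(1, 20, 1)),
               "rank deficient")
  expect_error(dglm_fit(c(y[-1], NA), cbind(1, 1:20), matrix(1, 20, 1)),
               "non-finite")
})

test_that("the formula interface matches the matrix interface and methods work", {
  set.seed(5)
  d <- data.frame(g = rbinom(150, 2, 0.4), x = rnorm(150))
  d$y <- rnorm(150, 0.2 * d$g + 0.1 * d$x, exp(0.15 * d$g))
  fm <- dglm(y ~ x + g, ~ g, data = d)
  fx <- dglm_fit(d$y, cbind(1, d$x, d$g), cbind(1, d$g))
  expect_equal(unname(coef(fm)), unname(coef(fx)), tolerance = 1e-10)
  expect_equal(unname(coef(fm, "dispersion")),
               unname(fx$dispersion$coefficients), tolerance = 1e-10)
  expect_equal(fitted(fm) + residuals(fm), d$y, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(as.numeric(logLik(fm)), fm$loglik)
  s <- summary(fm)
  expect_true(all(dim(s$mean_table) == c(3, 4)))
  pr <- predict(fm, newdata = data.frame(g = 0:2, x = 0), what = "dispersion")
  lam <- coef(fm, "dispersion")
  expect_equal(unname(pr), exp(lam[1] + lam[2] * (0:2)), tolerance = 1e-10,
               ignore_attr = TRUE)
  sims <- simulate(fm, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(150, 2))
})

test_that("the dglm vQTL test isolates the variance effect", {
  set.seed(55)
  n <- 2000
  g <- rbinom(n, 2, 0.4)
  # pure mean effect: dispersion test should not reject strongly
  y_mean <- rnorm(n, 0.5 * g, 1)
  r_mean <- dglm_vqtl_test(y_mean, g)
  expect_lt(r_mean$mean_p, 1e-10)
  expect_gt(r_mean$disp_p, 0.01)
  # pure variance effect: dispersion test rejects, mean does not
  y_var <- rnorm(n, 0, sqrt(exp(0.4 * g)))
  r_var <- dglm_vqtl_test(y_var, g)
  expect_lt(r_var$disp_p, 1e-4)
  expect_gt(r_var$mean_p, 0.001)
  expect_true(r_var$disp_stat >= 0)
  expect_equal(r_var$disp_df, 1)
  # wald and lrt agree on ordering for a clear signal
  r_wald <- dglm_vqtl_test(y_var, g, test = "wald")
  expect_lt(r_wald$disp_p, 1e-4)
  # 2-df genotype-class coding also detects the additive variance signal
  r_fac <- dglm_vqtl_test(y_var, g, coding = "genotype")
  expect_lt(r_fac$disp_p, 1e-3)
  expect_equal(r_fac$disp_df, 2)
  expect_error(dglm_vqtl_test(y_var, rep(1, n)), "monomorphic")
})
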