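test_that("constant squared residuals give a flat stage 2", {
  # residuals alternate +/-1 within every genotype class
  g <- rep(c(0, 1, 2), each = 4)
  y <- 0.5 * g + rep(c(-1, 1), 6)
  r <- svlm_test(y, g)
  expect_equal(r$disp_beta, 0, tolerance = 1e-10)
  expect_equal(r$disp_p, 1, tolerance = 1e-10)
})

test_that("SVLM matches a two-regression matrix-algebra oracle exactly", {
  y <- c(1.2, -0.4, 2.5, 0.3, 1.9, -1.1, 0.8, 2.2)
  g <- c(0, 0, 1, 1, 1, 2, 2, 2)
  r <- svlm_test(y, g)
  X <- cbind(1, g)
  bh <- solve(crossprod(X), crossprod(X, y))
  e <- y - drop(X %*% bh)
  b2 <- solve(crossprod(X), crossprod(X, e^2))
  e2res <- e^2 - drop(X %*% b2)
  s2 <- sum(e2res^2) / (8 - 2)
  se2 <- sqrt(s2 * solve(crossprod(X))[2, 2])
  expect_equal(r$disp_beta, b2[2], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(r$disp_se, se2, tolerance = 1e-10)
  expect_equal(r$disp_p, 2 * pt(abs(b2[2] / se2), 6, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(r$mean_beta, bh[2], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("SVLM p-values are invariant to trait location and scale", {
  d <- rand_grouped(60, 13)
  r0 <- svlm_test(d$y, d$g)
  expect_equal(svlm_test(d$y + 100, d$g)$disp_p, r0$disp_p, tolerance = 1e-10)
  expect_equal(svlm_test(5 * d$y, d$g)$disp_p, r0$disp_p, tolerance = 1e-10)
})

test_that("stage-2 slope is unbiased under the null without stage-1 SNP", {
  trials <- 2000
  sl <- numeric(trials)
  for (i in seq_len(trials)) {
    set.seed(7000 + i)
    g <- rbinom(100, 2, 0.4)
    y <- rnorm(100)
    sl[i] <- svlm_test(y, g, stage1_includes_snp = FALSE)$disp_beta
  }
  expect_lt(abs(mean(sl)), 3 * sd(sl) / sqrt(trials))
})

test_that("gamma and squared-residual variants rank datasets concordantly", {
  trials <- 200
  p_n <- p_g <- numeric(trials)
  for (i in seq_len(trials)) {
    set.seed(8000 + i)
    g <- rbinom(400, 2, 0.4)
    y <- rnorm(400)
    p_n[i] <- svlm_test(y, g)$disp_p
    p_g[i] <- svlm_test(y, g, stage2 = "gamma_sq")$disp_p
  }
  expect_gt(cor(p_n, p_g, method = "spearman"), 0.95)
})

test_that("absolute-residual variant runs and covariates are carried", {
  set.seed(3)
  n <- 300
  g <- rbinom(n, 2, 0.4)
  age <- runif(n, 20, 60)
  y <- 0.02 * age + rnorm(n, 0, sqrt(exp(0.3 * g)))
  r_abs <- svlm_test(y, g, covariates = cbind(age), stage2 = "normal_abs")
  expect_true(r_abs$disp_p >= 0 && r_abs$disp_p <= 1)
  r_c <- svlm_test(y, g, covariates = cbind(age),
                   stage2_includes_covariates = TRUE)
  expect_true(is.finite(r_c$disp_p))
  expect_error(svlm_test(1:4, c(0, 1, 2, 1)), "too few")
})

test_that("hat screen flags high-leverage stage-1 designs", {
  r <- hat_screen(cbind(1, c(0, 1, 2)), threshold = 0.5)
  expect_equal(r$max_hat, 5/6, tolerance = 1e-12)
  expect_equal(r$flagged, c(1L, 3L))
  expect_false(r$pass)
  expect_false(hat_screen(cbind(1, c(0, 1, 2)))$pass)  # default 0.05: all high
  expect_true(hat_screen(cbind(1, c(0, 1, 2)), threshold = 1.0)$pass)
  set.seed(10)
  Xbig <- cbind(1, rbinom(10000, 2, 0.4))
  big <- hat_screen(Xbig)
  expect_true(big$pass)
  expect_lt(big$max_hat, 0.05)
})

test_that("p-value concordance behaves as a correlation", {
  p <- runif(10)
  expect_equal(pvalue_concordance(p, p), 1)
  expect_equal(pvalue_concordance(p, 1 - p), -1)
  expect_error(pvalue_concordance(p, rep(0.5, 10)), "constant")
  expect_error(pvalue_concordance(p, p[-1]), "equal length")
  expect_error(pvalue_concordance(p, p * 2), "\\[0, 1\\]")
})
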