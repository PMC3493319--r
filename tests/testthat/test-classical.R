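test_that("identical absolute deviations give W = 0, p = 1", {
  y <- c(-1, 1, -1, 1)
  g <- factor(c("A", "A", "B", "B"))
  expect_warning(r <- levene_test(y, g, center = "mean"), "deviations equal")
  expect_equal(r$disp_stat, 0)
  expect_equal(r$disp_p, 1)
})

test_that("Levene W matches hand computation on a fixed dataset", {
  y <- c(0, 2, 4, 0, 4, 8)
  g <- factor(rep(c("A", "B"), each = 3))
  r <- levene_test(y, g, center = "mean")
  expect_equal(r$disp_stat, 0.8, tolerance = 1e-12)  # ANOVA F on |y - group mean|
  expect_equal(r$disp_p, pf(0.8, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$disp_df, 1)
})

test_that("Levene equals independent ANOVA-on-deviations oracles on random data", {
  skip_if_not_installed("car")
  for (i in 1:100) {
    d <- rand_grouped(n = 20 + i %% 15, seed = 100 + i)
    f <- factor(d$g)
    for (ctr in c("mean", "median")) {
      r <- levene_test(d$y, f, center = ctr)
      # oracle 1: one-way ANOVA on absolute deviations
      cj <- tapply(d$y, f, if (ctr == "mean") mean else median)
      z <- abs(d$y - cj[as.integer(f)])
      a <- anova(lm(z ~ f))
      expect_equal(r$disp_stat, a$`F value`[1], tolerance = 1e-10)
      expect_equal(r$disp_p, a$`Pr(>F)`[1], tolerance = 1e-10)
      # oracle 2: car's implementation
      cl <- car::leveneTest(d$y, f, center = get(ctr))
      expect_equal(r$disp_stat, cl$`F value`[1], tolerance = 1e-8)
    }
  }
})

test_that("Levene W is invariant to location shifts and positive scaling", {
  d <- rand_grouped(50, 7)
  f <- factor(d$g)
  r0 <- levene_test(d$y, f)
  shift <- c(A = -3, B = 2, C = 11)[as.integer(f)]
  expect_equal(levene_test(d$y + shift, f)$disp_stat, r0$disp_stat,
               tolerance = 1e-10)
  expect_equal(levene_test(3.7 * d$y, f)$disp_stat, r0$disp_stat,
               tolerance = 1e-10)
})

test_that("Fligner-Killeen matches the hand-computed normal-scores statistic", {
  set.seed(9)
  y <- rnorm(12, sd = rep(c(1, 2, 3), each = 4))
  f <- factor(rep(1:3, each = 4))
  r <- fligner_killeen_test(y, f)
  # independent oracle: normal scores of midranked |y - group median|
  N <- length(y)
  a_dev <- abs(y - tapply(y, f, median)[as.integer(f)])
  sc <- qnorm(0.5 + rank(a_dev) / (2 * (N + 1)))
  Abar <- tapply(sc, f, mean)
  nj <- table(f)
  X2 <- sum(nj * (Abar - mean(sc))^2) / var(sc)
  expect_equal(r$disp_stat, unname(X2), tolerance = 1e-10)
  expect_equal(r$disp_p, pchisq(X2, 2, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("Fligner-Killeen is scale invariant and degenerates gracefully", {
  d <- rand_grouped(40, 11)
  f <- factor(d$g)
  expect_equal(fligner_killeen_test(2 * d$y, f)$disp_stat,
               fligner_killeen_test(d$y, f)$disp_stat, tolerance = 1e-12)
  expect_warning(r <- fligner_killeen_test(rep(5, 10), factor(rep(1:2, 5))),
                 "deviations zero")
  expect_equal(r$disp_p, 1)
})

test_that("both classical tests are calibrated under a Gaussian null", {
  trials <- 2000
  p_lev <- p_fk <- numeric(trials)
  for (i in seq_len(trials)) {
    set.seed(5000 + i)
    y <- rnorm(300)
    f <- factor(rep(0:2, each = 100))
    p_lev[i] <- levene_test(y, f)$disp_p
    p_fk[i] <- fligner_killeen_test(y, f)$disp_p
  }
  band <- 3 * sqrt(0.05 * 0.95 / trials)
  expect_lt(abs(mean(p_lev < 0.05) - 0.05), band)
  expect_lt(abs(mean(p_fk < 0.05) - 0.05), band)
})

test_that("dosage hard-calling rounds half to even and flags fractional dosages", {
  expect_equal(as.character(dosage_to_groups(c(0, 1, 2, 1))),
               c("0", "1", "2", "1"))
  expect_warning(f <- dosage_to_groups(c(0, 0.5, 2)), "hard-called")
  expect_equal(as.character(f), c("0", "0", "2"))  # 0.5 rounds to even 0
  expect_error(dosage_to_groups(c(0.96, 1.04)), "monomorphic")
  expect_error(dosage_to_groups(c(0, 3)), "within \\[0, 2\\]")
})

test_that("small genotype classes are dropped before testing", {
  y <- c(rnorm(10), rnorm(10, sd = 3), 99)
  f <- factor(c(rep("0", 10), rep("1", 10), "2"))
  expect_warning(r <- levene_test(y, f), "fewer than 2 observations")
  expect_equal(r$n_used, 20L)
  expect_equal(r$disp_df, 1)
})

test_that("group summaries report n, variance and guarded CV", {
  gs <- group_summary(c(2, 4, 5, 5, 5, -1, 1),
                      factor(c("a", "a", "b", "b", "b", "c", "c")))
  expect_equal(gs$mean, c(3, 5, 0))
  expect_equal(gs$variance, c(2, 0, 2))
  expect_equal(gs$cv[1], sqrt(2) / 3)
  expect_equal(gs$cv[2], 0)
  expect_false(gs$cv_defined[3])
  expect_true(is.na(gs$cv[3]))
})
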