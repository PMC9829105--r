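test_that("paired t matches closed-form arithmetic and stats::t.test", {
  s <- paired_series(c(1, 2, 3), c(0, 0, 0))
  tt <- paired_t(s)
  expect_equal(tt$mean, 2)
  expect_equal(tt$sd, 1)
  expect_equal(tt$se, 1 / sqrt(3))
  expect_equal(tt$t, 2 * sqrt(3))
  expect_identical(tt$df, 2L)
  expect_equal(tt$p, 2 * pt(-2 * sqrt(3), 2))
  ref <- t.test(s$values_a, s$values_b, paired = TRUE)
  expect_equal(tt$t, unname(ref$statistic))
  expect_equal(tt$p, ref$p.value)
  expect_equal(c(tt$ci_low, tt$ci_high), unname(ref$conf.int),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("degenerate difference vectors are flagged, not raised", {
  zero <- paired_t(paired_series(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(zero$t, 0)
  expect_equal(zero$p, 1)
  const <- paired_t(paired_series(c(2, 3, 4), c(1, 2, 3)))
  expect_true(const$t_infinite)
  expect_equal(const$p, 0)
  expect_error(paired_series(1, 2, "x"), "length >= 2")
})

test_that("paired-t p-values are uniform under the null", {
  set.seed(404)
  d <- matrix(rnorm(10 * 2000), nrow = 10)
  p <- apply(d, 2, function(x)
    paired_t(paired_series(x, numeric(10)))$p)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
})

test_that("Shapiro-Wilk wrapper behaves across regimes", {
  set.seed(7)
  expect_lt(shapiro_normality(runif(5000))$p, 0.001)
  rej <- vapply(1:100, function(s) {
    set.seed(s)
    shapiro_normality(rnorm(50))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
  expect_error(shapiro_normality(c(1, 2)), "3 <= n")
  expect_error(shapiro_normality(rep(1, 10)), "constant")
})

test_that("identical raters give ICC 1", {
  x <- c(0.3, 1.7, -2.2, 5.0)
  expect_equal(icc_agreement(cbind(x, x))$icc, 1)
})

test_that("ICC(A,1) equals the ANOVA mean-squares oracle", {
  # oracle: mean squares from stats::aov on the long table
  icc_oracle <- function(x) {
    long <- data.frame(y = as.vector(x),
                       subject = factor(rep(seq_len(nrow(x)), ncol(x))),
                       rater = factor(rep(seq_len(ncol(x)),
                                          each = nrow(x))))
    ms <- summary(stats::aov(y ~ subject + rater, data = long))[[1]][
      , "Mean Sq"]
    n <- nrow(x); k <- ncol(x)
    (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + k / n * (ms[2] - ms[3]))
  }
  shifted <- cbind(1:4, 2:5)  # rater 2 reads +1 higher everywhere
  expect_equal(icc_agreement(shifted)$icc, icc_oracle(shifted),
               tolerance = 1e-12)
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    k <- sample(2:3, 1)
    x <- matrix(rnorm(n * k, sd = 2) + rep(rnorm(n, sd = 3), k), n, k)
    expect_equal(icc_agreement(x)$icc,
                 max(-1, min(1, icc_oracle(x))), tolerance = 1e-9)
  }
})

test_that("unrelated raters give ICC near zero, constant subjects flag", {
  set.seed(5)
  x <- cbind(rnorm(100), rnorm(100))
  expect_lt(abs(icc_agreement(x)$icc), 0.2)
  same <- cbind(rep(1, 5), rep(1, 5))
  expect_true(icc_agreement(same)$degenerate)
  expect_true(is.na(icc_agreement(same)$icc))
})

test_that("Bland-Altman limits follow the closed form", {
  z <- bland_altman(paired_series(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(c(z$mean_diff, z$loa_low, z$loa_high), c(0, 0, 0))
  expect_equal(z$coverage, 1)

  s <- bland_altman(paired_series(c(1, -1), c(0, 0)))
  expect_equal(s$mean_diff, 0)
  expect_equal(s$sd_diff, sqrt(2))
  expect_equal(s$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(s$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)
  # self-consistency: limits recompute from the stored differences
  d <- s$plot_data$difference
  expect_equal(s$loa_high, mean(d) + 1.96 * sd(d))
})

test_that("LoA coverage approaches 95 percent for normal differences", {
  set.seed(31)
  a <- rnorm(10000, sd = 0.1)
  z <- bland_altman(paired_series(a, numeric(10000)))
  expect_lt(abs(z$coverage - 0.95), 0.01)
})

test_that("paired sample size dominates the normal approximation", {
  for (case in list(c(0.4, 0.4), c(0.5, 1.0), c(0.2, 0.3))) {
    n <- required_n_paired(case[1], case[2], power = 0.95, alpha = 0.05)
    z_bound <- ((qnorm(0.975) + qnorm(0.95)) * case[2] / case[1])^2
    expect_gte(n, z_bound)
  }
})

test_that("sample size matches the noncentral-t solver in stats", {
  n <- required_n_paired(0.4, 0.4, power = 0.95, alpha = 0.05)
  ref <- stats::power.t.test(delta = 0.4, sd = 0.4, power = 0.95,
                             sig.level = 0.05, type = "paired")
  expect_identical(n, as.integer(ceiling(ref$n)))
  # simulation oracle: achieved power at n within 1 percent of target
  set.seed(202)
  reps <- 50000
  d <- matrix(rnorm(n * reps, mean = 0.4, sd = 0.4), nrow = n)
  tstat <- colMeans(d) / (apply(d, 2, sd) / sqrt(n))
  achieved <- mean(abs(tstat) > qt(0.975, n - 1))
  expect_gte(achieved, 0.95 - 0.01)
})

test_that("quadrupling the variance roughly quadruples n", {
  n1 <- required_n_paired(0.2, 0.4, power = 0.9, alpha = 0.05)
  n2 <- required_n_paired(0.2, 0.8, power = 0.9, alpha = 0.05)
  expect_lt(abs(n2 / n1 - 4), 4 * 0.15)
})
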