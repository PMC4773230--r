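# Descriptives, group comparisons, correlation, regression, agreement.

# sort-based type-7 percentile, written out independently
.pctl <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

test_that("descriptives match a sort-based oracle", {
  co <- data.frame(v = c(1, 2, 3, 4, 5))
  s <- cohort_describe(co, "v")
  expect_equal(s$mean, 3)
  expect_equal(s$median, 3)
  expect_equal(cohort_describe(data.frame(v = rep(7, 5)), "v")$sd, 0)
  expect_error(cohort_describe(data.frame(v = c(1, NA)), "v"), "at least 2")

  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(sample(5:60, 1))
    s <- cohort_describe(data.frame(v = x), "v")
    expect_equal(s$mean, sum(x) / length(x))
    expect_equal(s$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
    expect_equal(s$median, .pctl(x, 0.5))
    expect_equal(s$iqr_low, .pctl(x, 0.25))
    expect_equal(s$iqr_high, .pctl(x, 0.75))
  }
})

test_that("group comparisons reduce to t and chi-squared correctly", {
  co <- data.frame(v = c(1, 2, 3, 1, 2, 3),
                   g = rep(c("a", "b"), each = 3))
  r <- compare_groups(co, "v", "g")
  expect_equal(r$test, "t")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # identical proportions -> chi2 = 0
  co2 <- data.frame(v = rep(c(TRUE, FALSE, TRUE, FALSE), 5),
                    g = rep(c("a", "a", "b", "b"), 5))
  r2 <- compare_groups(co2, "v", "g")
  expect_equal(r2$test, "chi2")
  expect_equal(r2$statistic, 0)

  # constructed 2x2 table vs hand-computed sum (O-E)^2/E
  co3 <- data.frame(v = rep(c(TRUE, FALSE), c(30, 50)),
                    g = rep(c("a", "b", "a", "b"), c(20, 10, 15, 35)))
  tab <- table(co3$v, co3$g)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(compare_groups(co3, "v", "g")$statistic,
               sum((tab - E)^2 / E))

  expect_error(compare_groups(data.frame(v = rep(1, 6),
                                         g = rep(c("a", "b"), 3)),
                              "v", "g"), "zero variance")
})

test_that("Pearson correlation matches the covariance-formula oracle", {
  co <- data.frame(x = 1:10, y = 2 * (1:10) + 1, z = -(1:10))
  expect_equal(cohort_pearson(co, "x", "y")$r, 1)
  expect_equal(cohort_pearson(co, "x", "z")$r, -1)
  expect_error(cohort_pearson(data.frame(x = 1:5, y = rep(2, 5)), "x", "y"),
               "zero variance")

  set.seed(42)
  for (i in 1:10) {
    n <- sample(5:80, 1)
    d <- data.frame(x = rnorm(n), y = rnorm(n))
    r_hat <- cohort_pearson(d, "x", "y")
    r_oracle <- sum((d$x - mean(d$x)) * (d$y - mean(d$y))) /
      sqrt(sum((d$x - mean(d$x))^2) * sum((d$y - mean(d$y))^2))
    expect_lt(abs(r_hat$r - r_oracle), 1e-12)
    t_or <- r_oracle * sqrt((n - 2) / (1 - r_oracle^2))
    expect_equal(r_hat$p_two_sided, 2 * pt(-abs(t_or), n - 2))
  }
})

test_that("regression recovers noiseless coefficients exactly", {
  set.seed(43)
  d <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  d$y <- 3 + 2 * d$x1 - d$x2
  fit <- fit_multivariate(d, "y", c("x1", "x2"))
  expect_equal(fit$coefficients$coefficient, c(2, -1), tolerance = 1e-10)
  expect_equal(fit$model$r2, 1, tolerance = 1e-12)
})

test_that("regression matches a normal-equations oracle", {
  set.seed(44)
  for (i in 1:10) {
    n <- sample(20:60, 1); k <- sample(2:4, 1)
    X <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("x", 1:k)))
    d <- as.data.frame(X)
    d$y <- rnorm(n)
    fit <- fit_multivariate(d, "y", colnames(X))
    Xi <- cbind(1, X)
    beta <- solve(t(Xi) %*% Xi, t(Xi) %*% d$y)
    resid <- d$y - Xi %*% beta
    s2 <- sum(resid^2) / (n - k - 1)
    se <- sqrt(diag(s2 * solve(t(Xi) %*% Xi)))
    expect_lt(max(abs(fit$coefficients$coefficient - beta[-1])), 1e-10)
    expect_lt(max(abs(fit$coefficients$std_error - se[-1])), 1e-10)
    # adjusted R2 from its definition
    r2 <- 1 - sum(resid^2) / sum((d$y - mean(d$y))^2)
    expect_equal(fit$model$r2_adjusted,
                 1 - (1 - r2) * (n - 1) / (n - k - 1), tolerance = 1e-10)
  }
})

test_that("a single-covariate partial correlation equals the Pearson r", {
  set.seed(45)
  d <- data.frame(x = rnorm(40))
  d$y <- 0.6 * d$x + rnorm(40)
  fit <- fit_multivariate(d, "y", "x")
  expect_equal(fit$coefficients$r_partial, cohort_pearson(d, "x", "y")$r,
               tolerance = 1e-12)
})

test_that("partial r carries the sign of t and is affine invariant", {
  set.seed(46)
  d <- data.frame(a = rnorm(50), b = rnorm(50))
  d$y <- 1 + d$a - 2 * d$b + rnorm(50)
  fit <- fit_multivariate(d, "y", c("a", "b"))
  expect_equal(sign(fit$coefficients$r_partial), sign(fit$coefficients$t))
  d2 <- transform(d, a = 100 * a + 7, b = b / 3 - 2)
  fit2 <- fit_multivariate(d2, "y", c("a", "b"))
  expect_equal(fit2$coefficients$r_partial, fit$coefficients$r_partial,
               tolerance = 1e-10)
  expect_equal(cohort_pearson(d2, "a", "y")$r, cohort_pearson(d, "a", "y")$r,
               tolerance = 1e-10)
})

test_that("collinear covariates are refused by name", {
  set.seed(47)
  d <- data.frame(borg = rnorm(30))
  d$vas <- 10 * d$borg           # exact collinearity
  d$y <- d$borg + rnorm(30)
  expect_error(fit_multivariate(d, "y", c("borg", "vas")),
               "rank deficient.*vas")
})

test_that("ICC(2,1) behaves at its anchor points and matches an ANOVA oracle", {
  # identical rater columns, varying subjects -> exactly 1
  m <- cbind(c(1, 5, 9, 13), c(1, 5, 9, 13))
  expect_equal(icc_absolute_agreement(m)$icc, 1)
  expect_error(icc_absolute_agreement(matrix(3, 4, 2)),
               "no between-subject variance")

  # a second rater that is pure noise -> ICC near 0
  set.seed(48)
  r1 <- rnorm(400, sd = 1)
  m2 <- cbind(r1, r1 + rnorm(400, sd = 20))
  expect_lt(abs(icc_absolute_agreement(m2)$icc), 0.1)

  # mean squares against aov() on the long layout
  set.seed(49)
  for (i in 1:5) {
    g <- matrix(rnorm(8 * 3, mean = rep(1:8, 3)), 8, 3)
    long <- data.frame(y = as.vector(g),
                       subject = factor(rep(1:8, 3)),
                       rater = factor(rep(1:3, each = 8)))
    ms <- summary(aov(y ~ subject + rater, data = long))[[1]][["Mean Sq"]]
    n <- 8; k <- 3
    icc_oracle <- (ms[1] - ms[3]) /
      (ms[1] + (k - 1) * ms[3] + k / n * (ms[2] - ms[3]))
    expect_equal(icc_absolute_agreement(g)$icc, icc_oracle,
                 tolerance = 1e-12)
  }
})

test_that("Bland-Altman limits follow mean difference +/- 1.96 SD", {
  r <- bland_altman(c(3, 7, 9), c(3, 7, 9))
  expect_equal(c(r$loa_low, r$loa_high, r$mean_diff), c(0, 0, 0))
  r2 <- bland_altman(c(4, 5, 6), c(2, 3, 4))   # constant difference 2
  expect_equal(c(r2$loa_low, r2$loa_high), c(2, 2))
  set.seed(50)
  a <- rnorm(40); b <- rnorm(40)
  r3 <- bland_altman(a, b)
  d <- a - b
  s <- sqrt(sum((d - mean(d))^2) / (length(d) - 1))
  expect_equal(r3$mean_diff, mean(d))
  expect_equal(r3$loa_low, mean(d) - 1.96 * s, tolerance = 1e-12)
  expect_equal(r3$loa_high, mean(d) + 1.96 * s, tolerance = 1e-12)
  expect_error(bland_altman(1, 1), "at least 2")
})
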