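test_that("pearson correlation matches closed forms and brute force", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6))$r, 1)

  orth <- pearson_cor(c(-1, 0, 1) + 5, c(1, -2, 1) + 3)
  expect_equal(orth$r, 0, tolerance = 1e-12)
  expect_equal(orth$p_value, 1, tolerance = 1e-12)

  set.seed(51)
  x <- rnorm(20); y <- 0.4 * x + rnorm(20)
  res <- pearson_cor(x, y)
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_brute, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)

  expect_error(pearson_cor(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
})

test_that("pearson is symmetric and affine-invariant", {
  set.seed(52)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(pearson_cor(x, y)$r, pearson_cor(y, x)$r)
  expect_equal(pearson_cor(3 * x + 2, y)$r, pearson_cor(x, y)$r, tolerance = 1e-12)
})

test_that("partial correlation follows the one-covariate formula", {
  # r_xy = r_xz = r_yz = 0.5 gives 0.25 / 0.75
  r <- (0.5 - 0.5 * 0.5) / sqrt((1 - 0.25) * (1 - 0.25))
  expect_equal(r, 1 / 3)

  set.seed(53)
  x <- rnorm(30); y <- rnorm(30); z <- rnorm(30)
  res <- partial_cor(x, y, z)
  oracle <- (cor(x, y) - cor(x, z) * cor(y, z)) /
    sqrt((1 - cor(x, z)^2) * (1 - cor(y, z)^2))
  expect_equal(res$r, oracle, tolerance = 1e-12)
  expect_equal(res$df, 27)

  # z uncorrelated with both arguments: partial equals marginal
  zr <- residuals(lm(z ~ x + y))
  expect_equal(partial_cor(x, y, zr)$r, cor(x, y), tolerance = 1e-10)

  expect_error(partial_cor(x, y, x), "collinear")
})

test_that("simple main effects reduce to cell-mean differences and match regression", {
  # zero residual variance: effect of A at B = b1 is exactly a - b
  df <- expand.grid(a = c("a0", "a1"), b = c("b0", "b1"), rep = 1:3)
  mu <- c(a0.b0 = 1, a1.b0 = 4, a0.b1 = 2, a1.b1 = 2.5)
  df$y <- mu[paste(df$a, df$b, sep = ".")]
  se <- two_way_simple_effects(df$y, df$a, df$b)
  expect_equal(se$simple$estimate[se$simple$level_b == "b0"], 3)
  expect_equal(se$simple$estimate[se$simple$level_b == "b1"], 0.5)

  # unbalanced data: against a normal-equations oracle
  set.seed(54)
  n <- c(7, 11, 5, 9)
  a <- rep(rep(c("a0", "a1"), 2), n)
  b <- rep(c("b0", "b0", "b1", "b1"), n)
  y <- rnorm(sum(n), mean = as.numeric(factor(a)) + 2 * as.numeric(factor(b)))
  res <- two_way_simple_effects(y, a, b)
  X <- model.matrix(~ 0 + interaction(a, b))
  beta <- solve(t(X) %*% X, t(X) %*% y)  # cell means
  rss <- sum((y - X %*% beta)^2)
  sigma2 <- rss / (length(y) - 4)
  est_b0 <- beta[2] - beta[1]
  se_b0 <- sqrt(sigma2 * (1 / n[1] + 1 / n[2]))
  row_b0 <- res$simple[res$simple$level_b == "b0", ]
  expect_equal(row_b0$estimate, est_b0, tolerance = 1e-10)
  expect_equal(row_b0$se, se_b0, tolerance = 1e-10)
  expect_equal(row_b0$p_value,
               2 * pt(-abs(est_b0 / se_b0), length(y) - 4), tolerance = 1e-10)

  expect_error(two_way_simple_effects(1:4, c("a0", "a0", "a1", "a1"),
                                      c("b0", "b0", "b0", "b0")),
               "two levels")
  expect_error(two_way_simple_effects(1:6, c("a0", "a0", "a0", "a1", "a1", "a1"),
                                      c("b0", "b1", "b0", "b0", "b0", "b0")),
               "empty cell")
})

test_that("percent change is plain group-mean arithmetic", {
  set.seed(55)
  ref <- rnorm(10, 100, 1e-9); alt <- rnorm(10, 167, 1e-9)
  expect_equal(percent_change(ref, alt)$pct_change_rounded, 67)
  expect_equal(percent_change(ref, rnorm(10, 75, 1e-9))$pct_change_rounded, -25)
  expect_equal(percent_change(ref, ref)$pct_change_rounded, 0)
  expect_error(percent_change(c(-1, 1), alt), "zero")
})

test_that("Kaplan-Meier estimates match hand-computed product-limit tables", {
  # no censoring: survival steps are 1 - ECDF
  km <- km_estimate(1:5, rep(TRUE, 5))
  expect_equal(km$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median, 3)

  # all censored: flat at one, median undefined
  km2 <- km_estimate(1:4, rep(FALSE, 4))
  expect_true(all(km2$surv == 1))
  expect_true(is.na(km2$median))

  # mixed censoring, hand-computed:
  # times 1, 2+, 3, 4+, 5, 6 with events at 1, 3, 5, 6:
  # S(1) = 5/6, S(3) = 5/6 * 3/4 = 0.625, S(5) = 0.625 * 1/2 = 0.3125, S(6) = 0
  km3 <- km_estimate(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 0, 1, 1))
  ev <- km3$surv[km3$n_event > 0]
  expect_equal(ev, c(5 / 6, 0.625, 0.3125, 0))
  expect_equal(km3$median, 5)
  expect_true(all(diff(km3$surv) <= 0))

  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank test is null at identical patterns and label-symmetric", {
  t0 <- c(1, 2, 3, 4, 5); e0 <- c(1, 1, 0, 1, 1)
  lr <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 5))
  expect_equal(lr$chi_square, 0, tolerance = 1e-10)
  expect_equal(lr$p_value, 1, tolerance = 1e-10)

  set.seed(56)
  tA <- rexp(50, 1); tB <- rexp(50, 5)
  tm <- c(tA, tB); ev <- rep(1, 100); g <- rep(c("A", "B"), each = 50)
  strong <- logrank_test(tm, ev, g)
  expect_lt(strong$p_value, 0.001)
  flipped <- logrank_test(tm, ev, ifelse(g == "A", "B", "A"))
  expect_equal(strong$chi_square, flipped$chi_square, tolerance = 1e-10)

  expect_error(logrank_test(t0, e0, rep("a", 5)), "two groups")
})
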