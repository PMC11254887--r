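# Agreement statistics against independent brute-force oracles.

brute_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- 0; sy2 <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx2 <- sx2 + (x[i] - mx)^2
    sy2 <- sy2 + (y[i] - my)^2
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
  }
  2 * (sxy / n) / (sx2 / n + sy2 / n + (mx - my)^2)
}

test_that("dice handles identity, disjoint, partial overlap and empty masks", {
  a <- matrix(0L, 8, 8); a[2:3, 2:3] <- 1L
  b <- matrix(0L, 8, 8); b[2:3, 3:4] <- 1L   # |a|=|b|=4, overlap 2
  expect_equal(as.numeric(dice(a, a)), 1)
  d <- matrix(0L, 8, 8); d[6:7, 6:7] <- 1L
  expect_equal(as.numeric(dice(a, d)), 0)
  expect_equal(as.numeric(dice(a, b)), 0.5)
  expect_equal(dice(a, b), dice(b, a))
  e <- matrix(0L, 8, 8)
  expect_equal(as.numeric(dice(e, e)), 1)
  expect_true(isTRUE(attr(dice(e, e), "both_empty")))
  expect_error(dice(a, matrix(0L, 4, 4)), "grid")
})

test_that("dice complements soft_dice_loss as epsilon -> 0 on binary inputs", {
  a <- disc_mask(r = 5); b <- disc_mask(centre = c(32, 35), r = 5)
  expect_equal(1 - soft_dice_loss(a + 0, b + 0, epsilon = 1e-12),
               as.numeric(dice(a, b)), tolerance = 1e-9)
})

test_that("lin_ccc matches the brute-force oracle and closed forms", {
  x <- withr::with_seed(42, rnorm(200, 50, 15))
  y <- withr::with_seed(43, x + rnorm(200, 2, 5))
  res <- lin_ccc(x, y)
  expect_equal(res$ccc, brute_ccc(x, y), tolerance = 1e-10)
  expect_true(res$ci_low <= res$ccc && res$ccc <= res$ci_high)

  # identity and sign symmetry
  expect_equal(lin_ccc(x, x)$ccc, 1)
  z <- x - mean(x)
  expect_equal(lin_ccc(z, -z)$ccc, -1)

  # constant shift: ccc = 2 s2 / (2 s2 + c^2), population moments
  s2 <- mean((x - mean(x))^2)
  expect_equal(lin_ccc(x, x + 10)$ccc, 2 * s2 / (2 * s2 + 100), tolerance = 1e-12)

  # |CCC| <= |Pearson r| over random inputs
  for (s in 1:10) {
    a <- withr::with_seed(s, rnorm(50))
    b <- withr::with_seed(s + 100, 0.5 * a + rnorm(50, 1, 0.7))
    expect_lte(abs(lin_ccc(a, b)$ccc), abs(cor(a, b)) + 1e-12)
  }
})

test_that("ols_slope agrees with the normal-equation oracle (lm)", {
  x <- withr::with_seed(7, runif(200, 10, 150))
  y <- withr::with_seed(8, 0.95 * x + 3 + rnorm(200, 0, 4))
  res <- ols_slope(x, y)
  fit <- lm(y ~ x)
  expect_equal(res$slope, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(res$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  ci <- confint(fit, "x", 0.95)
  expect_equal(res$ci_low, ci[1], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$ci_high, ci[2], tolerance = 1e-8, ignore_attr = TRUE)

  # exact fit: slope 2, zero-width CI up to numerics
  res2 <- ols_slope(x, 2 * x + 3)
  expect_equal(res2$slope, 2, tolerance = 1e-12)
  expect_lt(res2$ci_high - res2$ci_low, 1e-9)
  expect_error(ols_slope(rep(1, 10), rnorm(10)), "variance")
})

test_that("bland_altman: constant shift, identity, and sampling oracle", {
  x <- withr::with_seed(9, runif(50, 20, 120))
  expect_equal(bland_altman(x, x), list(bias = 0, loa_low = 0, loa_high = 0,
                                        sd = 0, n = 50))
  res <- bland_altman(x, x - 2)
  expect_equal(res$bias, 2)
  expect_equal(res$loa_low, 2)
  expect_equal(res$loa_high, 2)

  d <- withr::with_seed(10, rnorm(10000, 0.5, 2))
  gt <- withr::with_seed(11, runif(10000, 40, 100))
  res <- bland_altman(gt, gt - d)
  expect_equal(res$bias, 0.5, tolerance = 0.08)
  expect_equal(res$loa_low, 0.5 - 1.96 * 2, tolerance = 0.15)
  expect_equal(res$loa_high, 0.5 + 1.96 * 2, tolerance = 0.15)
})

test_that("agreement_fractions applies strict thresholds and excludes gt == 0", {
  r <- agreement_fractions(100, 96, abs_threshold = 5, rel_thresholds = 10)
  expect_equal(r$frac_abs_lt, 1)
  expect_equal(unname(r$frac_rel_lt), 1)
  r2 <- agreement_fractions(100, 94, abs_threshold = 5, rel_thresholds = c(10, 20))
  expect_equal(r2$frac_abs_lt, 0)          # |diff| = 6 >= 5
  expect_equal(unname(r2$frac_rel_lt), c(1, 1))  # 6% < 10%
  x <- c(100, 50, 0)
  r3 <- agreement_fractions(x, x, abs_threshold = 5, rel_thresholds = 10)
  expect_equal(r3$frac_abs_lt, 1)
  expect_equal(r3$n_rel_excluded, 1)
  # strictness at the boundary
  r4 <- agreement_fractions(100, 95, abs_threshold = 5, rel_thresholds = 5)
  expect_equal(r4$frac_abs_lt, 0)
  expect_equal(unname(r4$frac_rel_lt), 0)
})

test_that("statistics are invariant to pair order", {
  x <- withr::with_seed(12, rnorm(100, 60, 20))
  y <- withr::with_seed(13, x + rnorm(100))
  perm <- withr::with_seed(14, sample(100))
  expect_equal(lin_ccc(x, y)$ccc, lin_ccc(x[perm], y[perm])$ccc)
  expect_equal(ols_slope(x, y)$slope, ols_slope(x[perm], y[perm])$slope)
  expect_equal(bland_altman(x, y)$bias, bland_altman(x[perm], y[perm])$bias)
})
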