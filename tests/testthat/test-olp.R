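test_that("pearson correlation with Fisher interval behaves at the edges", {
  x <- 1:10
  r1 <- pearson_ci(x, x * 2 + 1)
  expect_equal(r1$r, 1)
  set.seed(1)
  xn <- rnorm(500); yn <- rnorm(500)
  r0 <- pearson_ci(xn, yn)
  expect_lt(abs(r0$r), 0.15)
  expect_lt(r0$ci[1L], 0)
  expect_gt(r0$ci[2L], 0)
  expect_error(pearson_ci(1:5, rep(2, 5)), "variance")
  expect_error(pearson_ci(1:3, 1:3), "at least 4")
})

test_that("Fisher interval at r = 0.66, n = 13 matches the closed form", {
  # closed form computed independently here
  z <- atanh(0.66); se <- 1 / sqrt(13 - 3)
  lo <- tanh(z - qnorm(0.975) * se); hi <- tanh(z + qnorm(0.975) * se)
  set.seed(4)
  # manufacture 13 pairs with exactly r = 0.66 via orthogonalisation
  x <- rnorm(13); e <- rnorm(13)
  e <- residuals(lm(e ~ x)); e <- e / sd(e) * sd(x)
  y <- 0.66 * x + sqrt(1 - 0.66^2) * e
  ci <- pearson_ci(x, y)
  expect_equal(ci$r, 0.66, tolerance = 1e-10)
  expect_equal(ci$ci, c(lo, hi), tolerance = 1e-10)
  expect_equal(round(c(lo, hi), 2), c(0.17, 0.89))
})

test_that("ordinary least products fits exact affine relations", {
  x <- c(1, 2, 4, 7, 9)
  f1 <- olp_fit(x, x, n_boot = 50, seed = 1)
  expect_equal(f1$intercept, 0, tolerance = 1e-12)
  expect_equal(f1$slope, 1, tolerance = 1e-12)
  f2 <- olp_fit(x, 2 * x + 1, n_boot = 50, seed = 1)
  expect_equal(f2$intercept, 1, tolerance = 1e-12)
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  expect_equal(f2$residual_sd, 0, tolerance = 1e-12)
  expect_error(olp_fit(rep(1, 5), 1:5), "variance")
})

test_that("olp slope is the geometric mean of the two ols slopes", {
  set.seed(2)
  x <- rnorm(40, 10, 3)
  y <- 1 + 0.8 * x + rnorm(40, 0, 1.5)
  f <- olp_fit(x, y, n_boot = 50, seed = 1)
  b_yx <- coef(lm(y ~ x))[2L]
  b_xy <- coef(lm(x ~ y))[2L]
  expect_equal(f$slope, unname(sign(f$r) * sqrt(b_yx / b_xy)),
               tolerance = 1e-10)
})

test_that("olp is symmetric under axis exchange and scale-equivariant", {
  set.seed(3)
  x <- rnorm(30, 15, 4)
  y <- -0.5 + 1.1 * x + rnorm(30, 0, 0.8)
  f_xy <- olp_fit(x, y, n_boot = 50, seed = 1)
  f_yx <- olp_fit(y, x, n_boot = 50, seed = 1)
  expect_equal(f_yx$slope, 1 / f_xy$slope, tolerance = 1e-10)
  expect_equal(f_yx$intercept, -f_xy$intercept / f_xy$slope, tolerance = 1e-9)
  for (k in c(0.5, 3)) {
    fk <- olp_fit(x, k * y, n_boot = 50, seed = 1)
    expect_equal(fk$slope, k * f_xy$slope, tolerance = 1e-10)
    expect_equal(fk$intercept, k * f_xy$intercept, tolerance = 1e-9)
  }
})

test_that("olp recovers the generating calibration over many replicates", {
  set.seed(2024)
  n_rep <- 500
  ints <- numeric(n_rep); slps <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rnorm(20, 15.5, 6)
    y <- -0.8 + 1.03 * x + rnorm(20, 0, 0.7)
    f <- olp_fit(x, y, n_boot = 10, seed = r)
    ints[r] <- f$intercept; slps[r] <- f$slope
  }
  expect_lt(abs(mean(ints) - (-0.8)), 0.15)
  expect_lt(abs(mean(slps) - 1.03), 0.02)
})

test_that("bootstrap intervals cover the population olp slope", {
  # population OLP slope for this generator: the functional
  # sign(r) * sd(y)/sd(x) evaluated at the population moments
  sx <- 6; sigma <- 0.7; beta <- 1.03
  slope_pop <- sqrt(beta^2 * sx^2 + sigma^2) / sx
  set.seed(99)
  n_rep <- 500
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rnorm(20, 15.5, sx)
    y <- -0.8 + beta * x + rnorm(20, 0, sigma)
    f <- olp_fit(x, y, n_boot = 2000, seed = 1e6 + r)
    covered[r] <- f$ci_slope[1L] <= slope_pop && slope_pop <= f$ci_slope[2L]
  }
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("olp predictions reproduce worked calibration arithmetic", {
  new_line <- olp_calibration(-0.803, 1.030)
  old_line <- olp_calibration(-1.591, 0.992)
  expect_equal(olp_predict(new_line, 15.5)$fit, 15.16, tolerance = 0.005)
  expect_equal(olp_predict(old_line, 15.5)$fit, 13.78, tolerance = 0.006)
  # with the published 1.52 W/kg half-width
  yhat <- olp_predict(new_line, 15.5)$fit
  expect_equal(yhat - 1.52, 13.64, tolerance = 0.005)
  expect_equal(yhat + 1.52, 16.68, tolerance = 0.005)
})

test_that("prediction intervals follow the n - 2 t form", {
  set.seed(5)
  x <- rnorm(15, 15, 3)
  y <- -0.8 + 1.03 * x + rnorm(15, 0, 0.7)
  f <- olp_fit(x, y, n_boot = 50, seed = 1)
  pr <- olp_predict(f, 16)
  half <- qt(0.975, 13) * f$residual_sd *
    sqrt(1 + 1 / 15 + (16 - mean(x))^2 / sum((x - mean(x))^2))
  expect_equal(pr$upr - pr$fit, half, tolerance = 1e-10)
  expect_equal(pr$fit - pr$lwr, half, tolerance = 1e-10)
})

test_that("repeated-measures anova handles null, shifted and paired cases", {
  set.seed(7)
  base <- rnorm(13, 15, 2)
  y_null <- cbind(a = base, b = base, c = base)
  r0 <- rm_anova(y_null)
  expect_equal(r0$F, 0)
  expect_equal(r0$p_reported, 1)
  expect_true(all(r0$pairwise == 1, na.rm = TRUE))
  # one condition shifted by 10 within-subject sd
  wsd <- 0.5
  y1 <- cbind(a = base + rnorm(13, 0, wsd),
              b = base + rnorm(13, 0, wsd),
              c = base + 10 * wsd + rnorm(13, 0, wsd))
  r1 <- rm_anova(y1)
  expect_lt(r1$p_reported, 0.001)
  expect_lt(r1$pairwise["c", "a"], 0.05)
  expect_lt(r1$pairwise["c", "b"], 0.05)
  expect_gt(r1$pairwise["b", "a"], 0.05)
  # two conditions reduce to the paired t-test: F = t^2
  y2 <- y1[, 1:2]
  r2 <- rm_anova(y2)
  tt <- t.test(y2[, 1L], y2[, 2L], paired = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
  # missing cells are rejected
  y3 <- y1; y3[2, 2] <- NA
  expect_error(rm_anova(y3), "missing")
})

test_that("heteroscedasticity statistic is reported alongside the fit", {
  set.seed(8)
  x <- rnorm(40, 15, 4)
  y <- -0.8 + 1.03 * x + rnorm(40, 0, 0.7)
  f <- olp_fit(x, y, n_boot = 50, seed = 1)
  expect_true(is.finite(f$bp$statistic))
  expect_gte(f$bp$p, 0)
  expect_lte(f$bp$p, 1)
})
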