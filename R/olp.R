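#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y Paired numeric vectors (n >= 4, non-zero variance).
#' @param conf Confidence level, default 0.95.
#' @return A list with `r`, `ci` (length 2), `n`.
#' @examples
#' with(mtcars, pearson_ci(wt, mpg))
#' @export
pearson_ci <- function(x, y, conf = 0.95) {
  check_pairs(x, y, min_n = 4L)
  n <- length(x)
  r <- stats::cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  list(r = r, ci = tanh(c(z - q * se, z + q * se)), n = n)
}

check_pairs <- function(x, y, min_n = 3L) {
  if (length(x) != length(y)) stop("`x`/`y` lengths differ", call. = FALSE)
  if (length(x) < min_n) stop("need at least ", min_n, " pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("pairs must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in `x` or `y`", call. = FALSE)
  }
  invisible(TRUE)
}

#' Ordinary least products (geometric-mean) regression
#'
#' Method-comparison calibration of a test measure `y` against a reference
#' `x`: the OLP slope is `sign(r) * sd(y)/sd(x)` — the geometric mean of the
#' OLS slope of y on x and the reciprocal of the OLS slope of x on y — and
#' estimates proportional bias; the intercept `mean(y) - slope * mean(x)`
#' estimates fixed bias. Confidence intervals come from a seeded percentile
#' bootstrap over pair (case) resamples. Residual scatter is retained for
#' 95% prediction intervals (see [olp_predict()]), and a Breusch-Pagan-style
#' statistic (n R^2 of squared residuals on x, chi-square df 1) is reported
#' as a heteroscedasticity check — informative, not gating.
#'
#' @param x Reference values (e.g. direct metabolic power, W/kg).
#' @param y Test values (e.g. GPS metabolic power, W/kg).
#' @param n_boot Bootstrap resamples, default 2000.
#' @param seed Optional RNG seed for the bootstrap.
#' @param conf Confidence level, default 0.95.
#' @return An object of class `olp_fit`: list with `intercept`, `slope`,
#'   `ci_intercept`, `ci_slope`, `residual_sd` (n - 2 df), `residuals`,
#'   `fitted`, `n`, `x_mean`, `x_ss`, `r`, `bp` (list `statistic`, `p`).
#' @examples
#' set.seed(1)
#' x <- rnorm(20, 15, 2); y <- -0.8 + 1.03 * x + rnorm(20, 0, 0.7)
#' olp_fit(x, y, n_boot = 200, seed = 1)
#' @export
olp_fit <- function(x, y, n_boot = 2000, seed = NULL, conf = 0.95) {
  check_pairs(x, y, min_n = 3L)
  n <- length(x)
  r <- stats::cor(x, y)
  if (r == 0) {
    stop("correlation is exactly zero: OLP slope sign is ambiguous; ",
         "collect more data", call. = FALSE)
  }
  slope <- sign(r) * stats::sd(y) / stats::sd(x)
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  res <- y - fitted
  residual_sd <- sqrt(sum(res^2) / (n - 2))
  ci <- olp_boot_ci(x, y, n_boot = n_boot, seed = seed, conf = conf)
  ## Heteroscedasticity: n R^2 of squared residuals regressed on x.
  r2 <- if (stats::sd(res^2) > 0) stats::cor(res^2, x)^2 else 0
  bp_stat <- n * r2
  structure(
    list(intercept = intercept, slope = slope,
         ci_intercept = ci$intercept, ci_slope = ci$slope,
         residual_sd = residual_sd, residuals = res, fitted = fitted,
         n = n, x_mean = mean(x), x_ss = sum((x - mean(x))^2), r = r,
         conf = conf,
         bp = list(statistic = bp_stat,
                   p = stats::pchisq(bp_stat, df = 1, lower.tail = FALSE))),
    class = "olp_fit"
  )
}

## Vectorised percentile bootstrap over pair resamples.
olp_boot_ci <- function(x, y, n_boot, seed = NULL, conf = 0.95) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- length(x)
  idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), nrow = n_boot)
  X <- matrix(x[idx], nrow = n_boot)
  Y <- matrix(y[idx], nrow = n_boot)
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- rowMeans(X^2) - mx^2
  vy <- rowMeans(Y^2) - my^2
  cxy <- rowMeans(X * Y) - mx * my
  ok <- vx > 0 & vy > 0 & cxy != 0
  b <- sign(cxy[ok]) * sqrt(vy[ok] / vx[ok])
  a <- my[ok] - b * mx[ok]
  p <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  list(slope = unname(stats::quantile(b, p)),
       intercept = unname(stats::quantile(a, p)),
       n_effective = sum(ok))
}

#' @export
print.olp_fit <- function(x, ...) {
  lab <- sprintf("%.3f (%.3f to %.3f)", x$intercept,
                 x$ci_intercept[1L], x$ci_intercept[2L])
  lab2 <- sprintf("%.3f (%.3f to %.3f)", x$slope,
                  x$ci_slope[1L], x$ci_slope[2L])
  cat("<olp_fit>  n =", x$n, "\n")
  cat("  fixed bias (intercept)       :", lab, "\n")
  cat("  proportional bias (slope)    :", lab2, "\n")
  cat(sprintf("  residual sd (n - 2 df)       : %.3f\n", x$residual_sd))
  cat(sprintf("  Pearson r                    : %.3f\n", x$r))
  cat(sprintf("  Breusch-Pagan chi2(1), p     : %.2f, %.3f\n",
              x$bp$statistic, x$bp$p))
  invisible(x)
}

#' Build an OLP calibration line from published coefficients
#'
#' Creates a minimal `olp_fit` carrying only intercept and slope, e.g. to
#' apply a published calibration to new data. Prediction intervals are
#' unavailable unless `residual_sd`, `n`, `x_mean` and `x_ss` are supplied.
#'
#' @param intercept,slope Calibration coefficients.
#' @param residual_sd,n,x_mean,x_ss Optional scatter moments.
#' @return An `olp_fit`.
#' @examples
#' olp_calibration(-0.803, 1.030)
#' @export
olp_calibration <- function(intercept, slope, residual_sd = NA_real_,
                            n = NA_integer_, x_mean = NA_real_,
                            x_ss = NA_real_) {
  structure(
    list(intercept = intercept, slope = slope,
         ci_intercept = c(NA_real_, NA_real_), ci_slope = c(NA_real_, NA_real_),
         residual_sd = residual_sd, residuals = numeric(0), fitted = numeric(0),
         n = n, x_mean = x_mean, x_ss = x_ss, r = NA_real_, conf = 0.95,
         bp = list(statistic = NA_real_, p = NA_real_)),
    class = "olp_fit"
  )
}

#' Predict from an OLP calibration with a 95% prediction interval
#'
#' Point prediction `yhat = intercept + slope * x0`; the prediction interval
#' adapts the classical OLS form to the OLP residuals with n - 2 degrees of
#' freedom: `yhat +- t * s * sqrt(1 + 1/n + (x0 - x_mean)^2 / x_ss)`.
#'
#' @param fit An [olp_fit()] (or [olp_calibration()]).
#' @param x0 Reference value(s) at which to predict.
#' @param conf Interval level, default 0.95.
#' @return A tibble with `x0`, `fit`, `lwr`, `upr` (bounds `NA` when the fit
#'   carries no residual scatter).
#' @examples
#' olp_predict(olp_calibration(-0.803, 1.030), 15.5)
#' @export
olp_predict <- function(fit, x0, conf = 0.95) {
  stopifnot(inherits(fit, "olp_fit"))
  yhat <- fit$intercept + fit$slope * x0
  if (!is.na(fit$residual_sd) && !is.na(fit$n) && fit$n >= 3) {
    tq <- stats::qt(1 - (1 - conf) / 2, df = fit$n - 2)
    half <- tq * fit$residual_sd *
      sqrt(1 + 1 / fit$n + (x0 - fit$x_mean)^2 / fit$x_ss)
  } else {
    half <- NA_real_
  }
  tibble::tibble(x0 = x0, fit = yhat, lwr = yhat - half, upr = yhat + half)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' One within-subject factor on a complete subjects-by-conditions matrix.
#' Sphericity is assessed with Mauchly's test; when it fails (p < 0.05, or
#' always when `gg = "always"`) the F-test degrees of freedom are scaled by
#' the Greenhouse-Geisser epsilon. Pairwise post hoc comparisons are paired
#' t-tests with Bonferroni adjustment.
#'
#' @param y A numeric matrix (subjects in rows, conditions in columns) or a
#'   long data frame with columns `subject`, `condition`, `value`.
#' @param gg `"auto"` (apply when Mauchly p < 0.05), `"always"` or `"never"`.
#' @return A list of class `rm_anova`: `F`, `df` (uncorrected), `df_gg`,
#'   `epsilon_gg`, `p`, `p_gg`, `mauchly` (list `W`, `p`), `pairwise`
#'   (matrix of Bonferroni-adjusted p-values), `means`.
#' @examples
#' y <- cbind(a = rnorm(10, 10), b = rnorm(10, 10), c = rnorm(10, 12))
#' rm_anova(y)
#' @export
rm_anova <- function(y, gg = c("auto", "always", "never")) {
  gg <- match.arg(gg)
  if (is.data.frame(y) && all(c("subject", "condition", "value") %in% names(y))) {
    tab <- tapply(y$value, list(y$subject, y$condition), identity)
    y <- matrix(unlist(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  }
  y <- as.matrix(y)
  if (anyNA(y)) stop("unbalanced/missing cells; no imputation is attempted",
                     call. = FALSE)
  n <- nrow(y); k <- ncol(y)
  if (k < 2L) stop("need at least 2 conditions", call. = FALSE)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (is.null(colnames(y))) colnames(y) <- paste0("cond", seq_len(k))
  grand <- mean(y)
  cond_means <- colMeans(y)
  subj_means <- rowMeans(y)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  if (ss_cond <= .Machine$double.eps * max(1, ss_tot)) {
    ## conditions identical up to rounding: no effect to test
    Fv <- 0
    p <- 1
  } else {
    Fv <- (ss_cond / df1) / (ss_err / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }

  ## Greenhouse-Geisser epsilon from the orthonormal-contrast covariance.
  M <- contr_orthonormal(k)
  S <- stats::cov(y)
  TT <- t(M) %*% S %*% M
  lam <- eigen(TT, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(lam)^2 / (df1 * sum(lam^2))
  if (!is.finite(eps)) eps <- 1
  ## Mauchly's sphericity test (undefined for k = 2).
  if (k > 2L && all(lam > .Machine$double.eps * max(lam) * 1e3)) {
    W <- prod(lam) / (mean(lam))^df1
    f <- (2 * df1^2 + df1 + 2) / (6 * df1 * (n - 1))
    chi2 <- -(1 - f) * (n - 1) * log(W)
    df_m <- k * (k - 1) / 2 - 1
    mauchly <- list(W = W,
                    p = stats::pchisq(chi2, df_m, lower.tail = FALSE))
  } else {
    mauchly <- list(W = 1, p = 1)
  }
  apply_gg <- switch(gg, always = TRUE, never = FALSE,
                     auto = is.finite(mauchly$p) && mauchly$p < 0.05)
  df_gg <- c(df1, df2) * eps
  p_gg <- stats::pf(Fv, df_gg[1L], df_gg[2L], lower.tail = FALSE)

  long_val <- as.vector(y)
  long_cond <- factor(rep(colnames(y), each = n), levels = colnames(y))
  pw <- suppressWarnings(
    stats::pairwise.t.test(long_val, long_cond, paired = TRUE,
                           p.adjust.method = "bonferroni")$p.value
  )
  pw[is.nan(pw)] <- 1  # identical paired samples: no evidence of difference
  structure(
    list(F = Fv, df = c(df1, df2), df_gg = df_gg, epsilon_gg = eps,
         p = p, p_gg = p_gg, p_reported = if (apply_gg) p_gg else p,
         gg_applied = apply_gg, mauchly = mauchly,
         pairwise = pw, means = cond_means, n = n),
    class = "rm_anova"
  )
}

contr_orthonormal <- function(k) {
  M <- stats::contr.helmert(k)
  sweep(M, 2, sqrt(colSums(M^2)), "/")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova>  F(%.2f, %.2f) = %.3f, p = %.4g%s\n",
              if (x$gg_applied) x$df_gg[1L] else x$df[1L],
              if (x$gg_applied) x$df_gg[2L] else x$df[2L],
              x$F, x$p_reported,
              if (x$gg_applied) " (Greenhouse-Geisser)" else ""))
  cat(sprintf("  Mauchly W = %.3f, p = %.3f; epsilon GG = %.3f\n",
              x$mauchly$W, x$mauchly$p, x$epsilon_gg))
  cat("  condition means:", paste(sprintf("%s=%.2f", names(x$means), x$means),
                                  collapse = ", "), "\n")
  cat("  Bonferroni pairwise p-values:\n")
  print(round(x$pairwise, 4))
  invisible(x)
}
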