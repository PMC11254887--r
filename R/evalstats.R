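# Agreement statistics used to evaluate automated against ground-truth GFR:
# Dice overlap, Lin's concordance correlation coefficient, regression slope,
# Bland-Altman bias with 95% limits of agreement, and threshold agreement
# fractions.

#' Dice similarity coefficient between two binary masks
#'
#' DSC = 2|A∩B| / (|A| + |B|). Two empty masks agree perfectly by convention
#' (both annotators found nothing); that case is flagged via the
#' `both_empty` attribute.
#'
#' @param a,b 0/1 integer matrices on the same grid.
#' @return scalar in [0, 1].
#' @export
dice <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!all(dim(a) == dim(b))) stop("masks must share a grid", call. = FALSE)
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 && sb == 0) {
    return(structure(1, both_empty = TRUE))
  }
  2 * sum(a * b) / (sa + sb)
}

check_pairs <- function(gt, dl, min_n = 2L) {
  if (length(gt) != length(dl)) stop("paired series must have equal length", call. = FALSE)
  if (length(gt) < min_n) stop(sprintf("need at least %d pairs", min_n), call. = FALSE)
  if (!all(is.finite(gt)) || !all(is.finite(dl))) stop("non-finite values in paired series", call. = FALSE)
  invisible(NULL)
}

#' Lin's concordance correlation coefficient with confidence interval
#'
#' CCC = 2 cov(x,y) / (var(x) + var(y) + (mean(x) - mean(y))^2), computed
#' with population (1/n) moments. The confidence interval uses the
#' asymptotic variance of the Fisher z-transformed CCC (Lin 1989,
#' Biometrics 45:255-268).
#'
#' @param gt,dl equal-length numeric vectors (e.g. ground-truth-ROI and
#'   deep-learning-ROI GFR).
#' @param ci_level confidence level (default 0.95).
#' @return list with `ccc`, `ci_low`, `ci_high`, `n`.
#' @export
lin_ccc <- function(gt, dl, ci_level = 0.95) {
  check_pairs(gt, dl, min_n = 3L)
  n <- length(gt)
  mx <- mean(gt); my <- mean(dl)
  sx2 <- mean((gt - mx)^2); sy2 <- mean((dl - my)^2)
  sxy <- mean((gt - mx) * (dl - my))
  if (sx2 == 0 && sy2 == 0) stop("both series are constant", call. = FALSE)
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else NA_real_
  ci_low <- ci_high <- NA_real_
  if (is.finite(r) && abs(r) > 0 && abs(ccc) < 1) {
    u <- (mx - my) / (sx2 * sy2)^0.25
    z <- atanh(ccc)
    sez2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
               4 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
               2 * ccc^4 * u^4 / (r^2 * (1 - ccc^2)^2)) / (n - 2)
    if (is.finite(sez2) && sez2 >= 0) {
      q <- qnorm(1 - (1 - ci_level) / 2)
      ci_low <- tanh(z - q * sqrt(sez2))
      ci_high <- tanh(z + q * sqrt(sez2))
    }
  } else if (abs(ccc) == 1) {
    ci_low <- ci_high <- ccc
  }
  list(ccc = ccc, ci_low = ci_low, ci_high = ci_high, n = n)
}

#' Ordinary-least-squares slope of dl on gt with confidence interval
#'
#' Fits dl = a + b * gt; the CI uses the slope standard error and the
#' t-distribution with n - 2 degrees of freedom.
#'
#' @inheritParams lin_ccc
#' @return list with `slope`, `intercept`, `ci_low`, `ci_high`, `n`.
#' @export
ols_slope <- function(gt, dl, ci_level = 0.95) {
  check_pairs(gt, dl, min_n = 3L)
  n <- length(gt)
  mx <- mean(gt); my <- mean(dl)
  sxx <- sum((gt - mx)^2)
  if (sxx == 0) stop("zero predictor variance", call. = FALSE)
  sxy <- sum((gt - mx) * (dl - my))
  b <- sxy / sxx
  a <- my - b * mx
  resid <- dl - (a + b * gt)
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tq <- qt(1 - (1 - ci_level) / 2, df = n - 2)
  list(slope = b, intercept = a, ci_low = b - tq * se, ci_high = b + tq * se, n = n)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are taken as gt - dl (so a positive bias means the automated
#' value underestimates). LOA = bias +/- 1.96 * sd(d) with the sample (n-1)
#' standard deviation.
#'
#' @inheritParams lin_ccc
#' @return list with `bias`, `loa_low`, `loa_high`, `sd`, `n`.
#' @export
bland_altman <- function(gt, dl) {
  check_pairs(gt, dl, min_n = 2L)
  d <- gt - dl
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd = s, n = length(d))
}

#' Fractions of pairs meeting absolute / relative agreement thresholds
#'
#' Computes the fraction of pairs with |gt - dl| strictly below
#' `abs_threshold`, and for each entry of `rel_thresholds` the fraction with
#' 100 * |gt - dl| / gt strictly below it. Pairs with gt == 0 are excluded
#' from the relative fractions and counted in `n_rel_excluded`.
#'
#' @inheritParams lin_ccc
#' @param abs_threshold absolute difference threshold (same units as the
#'   series, e.g. mL/min/1.73 m^2).
#' @param rel_thresholds numeric vector of percent thresholds.
#' @return list with `frac_abs_lt`, `frac_rel_lt` (named by threshold),
#'   `n`, `n_rel_excluded`.
#' @export
agreement_fractions <- function(gt, dl, abs_threshold = 5, rel_thresholds = c(10, 20)) {
  check_pairs(gt, dl, min_n = 1L)
  d <- abs(gt - dl)
  frac_abs <- mean(d < abs_threshold)
  ok <- gt != 0
  rel <- 100 * d[ok] / abs(gt[ok])
  frac_rel <- vapply(rel_thresholds, function(th) {
    if (!any(ok)) NA_real_ else mean(rel < th)
  }, numeric(1))
  names(frac_rel) <- paste0("lt_", rel_thresholds, "pct")
  list(frac_abs_lt = frac_abs, frac_rel_lt = frac_rel,
       n = length(gt), n_rel_excluded = sum(!ok))
}

#' Full agreement report for a paired series
#'
#' Bundles Lin's CCC, OLS slope, Bland-Altman bias/LOA and threshold
#' agreement fractions for one ground-truth vs automated series.
#'
#' @inheritParams agreement_fractions
#' @param ci_level confidence level for CCC and slope intervals.
#' @return object of class `agreement_report`.
#' @export
agreement_report <- function(gt, dl, abs_threshold = 5, rel_thresholds = c(10, 20),
                             ci_level = 0.95) {
  out <- list(
    ccc = lin_ccc(gt, dl, ci_level),
    slope = ols_slope(gt, dl, ci_level),
    bland_altman = bland_altman(gt, dl),
    fractions = agreement_fractions(gt, dl, abs_threshold, rel_thresholds),
    n = length(gt)
  )
  class(out) <- "agreement_report"
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (n = %d)\n", x$n))
  cat(sprintf("  CCC   %.4f (95%% CI %.4f-%.4f)\n", x$ccc$ccc, x$ccc$ci_low, x$ccc$ci_high))
  cat(sprintf("  slope %.4f (95%% CI %.4f-%.4f)\n", x$slope$slope, x$slope$ci_low, x$slope$ci_high))
  cat(sprintf("  bias  %.3f (95%% LOA %.3f to %.3f)\n",
              x$bland_altman$bias, x$bland_altman$loa_low, x$bland_altman$loa_high))
  cat(sprintf("  frac |diff| < %s: %.3f\n",
              "abs threshold", x$fractions$frac_abs_lt))
  for (nm in names(x$fractions$frac_rel_lt)) {
    cat(sprintf("  frac rel diff %s: %.3f\n", nm, x$fractions$frac_rel_lt[[nm]]))
  }
  invisible(x)
}
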