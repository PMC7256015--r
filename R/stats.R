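# Method-agreement statistics: closed-form OLS calibration regression and
# Bland-Altman analysis, implemented from their defining formulas.

#' Ordinary least-squares calibration regression
#'
#' Closed-form simple linear regression of estimated vs reference masses:
#' slope, intercept and `R^2 = 1 - SS_res/SS_tot`.
#'
#' @param x Reference values (e.g. ICP-OES gold mass, ug); must not be
#'   constant.
#' @param y Estimated values (e.g. K-edge image gold mass, ug).
#' @return Object of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
#' @examples
#' linreg(c(0, 1, 2), c(0, 2, 4))  # slope 2, R^2 = 1
linreg <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 2) stop("need at least 2 points")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("x is constant: regression undefined")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  # a flat response carries no explained variance
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(slope = slope, intercept = intercept,
                 r_squared = max(0, min(1, r2)), n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<linreg> y = %.4g + %.4g x, R^2 = %.4f (n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`; bias = mean(d); limits of agreement = bias
#' +/- 1.96 SD (sample SD, n-1 denominator).
#'
#' @param a Estimates (e.g. K-edge image gold mass, ug).
#' @param b References (e.g. ICP-OES gold mass, ug).
#' @return Object of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and the `differences`/`means` vectors for
#'   plotting.
#' @export
#' @examples
#' bland_altman(c(12, 19, 33), c(10, 20, 30))
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b lengths differ")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = n, differences = d, means = (a + b) / 2),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f, 95%% limits of agreement [%.3f, %.3f] (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Agreement report: regression with and without outliers
#'
#' Combines [linreg()] and [bland_altman()]; pairs whose difference falls
#' outside the 95% limits of agreement are flagged as outliers and the
#' regression is re-fitted without them. Both fits are always reported
#' (neither is "the" result; the exclusion mirrors the post-hoc practice of
#' excluding animals outside the limits of agreement).
#'
#' @param estimate Estimated masses, ug.
#' @param reference Reference masses, ug.
#' @return List with `regression_all`, `regression_no_outliers`,
#'   `bland_altman`, `outliers` (logical vector).
#' @export
agreement_report <- function(estimate, reference) {
  ba <- bland_altman(estimate, reference)
  out <- ba$differences < ba$loa_low | ba$differences > ba$loa_high
  reg_all <- linreg(reference, estimate)
  reg_no <- if (any(out) && sum(!out) >= 2 &&
                length(unique(reference[!out])) > 1) {
    linreg(reference[!out], estimate[!out])
  } else reg_all
  list(regression_all = reg_all, regression_no_outliers = reg_no,
       bland_altman = ba, outliers = out)
}
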