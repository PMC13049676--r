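#' Power of the overall F test in fixed-model multiple regression
#'
#' For a linear model with `n_predictors` regressors and effect size
#' `f2 = R^2 / (1 - R^2)`, the overall F test has `(p, N - p - 1)` degrees
#' of freedom and noncentrality `f2 * N` under the alternative.
#'
#' @param n Total sample size.
#' @param n_predictors Number of regressors `p`.
#' @param f2 Cohen's effect size.
#' @param alpha Type I error rate.
#' @return Power in `[0, 1]` (vectorised over `n`).
#' @export
regression_power <- function(n, n_predictors, f2, alpha = 0.05) {
  p <- n_predictors
  df2 <- n - p - 1
  ifelse(df2 >= 1,
         pf(qf(1 - alpha, p, df2), p, df2, ncp = f2 * n, lower.tail = FALSE),
         0)
}

#' Minimal sample size for a target regression power
#'
#' Scans N upward and returns the smallest total sample size at which the
#' overall F test of a fixed-model multiple regression reaches the target
#' power. With 7 regressors, `f2 = 0.33`, `alpha = 0.05` and 80 % power
#' this gives N = 51.
#'
#' @param n_predictors Number of regressors.
#' @param f2 Effect size (> 0).
#' @param alpha Type I error rate in (0, 1).
#' @param power Target power in (0, 1).
#' @param n_max Upper bound of the scan.
#' @return Integer minimal N.
#' @examples
#' power_regression_n(7, 0.33, 0.05, 0.80)  # 51
#' @export
power_regression_n <- function(n_predictors, f2, alpha = 0.05, power = 0.80,
                               n_max = 100000L) {
  if (!is_count_(n_predictors)) abort("`n_predictors` must be a positive integer.")
  if (!is.finite(f2) || f2 <= 0) abort("`f2` must be > 0.")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("`alpha` and `power` must lie in (0, 1).")
  }
  for (n in seq(n_predictors + 2L, n_max)) {
    if (regression_power(n, n_predictors, f2, alpha) >= power) return(n)
  }
  abort("Target power not attainable within `n_max`.")
}

#' Convert a coefficient of determination to Cohen's f2
#'
#' `f2 = R^2 / (1 - R^2)`; an expected `R^2` of 0.25 corresponds to
#' `f2 = 0.33`.
#'
#' @param r2 Coefficient of determination in `[0, 1)`.
#' @return Effect size f2.
#' @examples
#' f2_from_r2(0.25)
#' @export
f2_from_r2 <- function(r2) {
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 >= 1)) {
    abort("`r2` must lie in [0, 1).")
  }
  r2 / (1 - r2)
}
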