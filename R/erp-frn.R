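#' Condition-wise ERPs and the success-minus-failure difference wave
#'
#' Averages single-channel feedback-locked epochs separately over trials
#' labelled `success` and `failure` and forms the difference wave
#' (success minus failure), the contrast from which the FRN amplitude is
#' read out.
#'
#' @param epochs A single-channel feedback-locked [epoched_eeg()]
#'   (baseline-corrected; pool the fronto-central cluster with
#'   [cluster_average()] first).
#' @param labels Optional per-trial labels overriding
#'   `epochs$trial_labels`; must contain both classes.
#' @return An object of class `vmr_erpset`: `times`, `success_erp`,
#'   `failure_erp`, `difference_wave` (microvolt series), `n_success`,
#'   `n_failure`.
#' @export
condition_erps <- function(epochs, labels = NULL) {
  stopifnot(inherits(epochs, "vmr_epochs"))
  if (dim(epochs$data)[2] != 1) {
    abort("`condition_erps()` expects single-channel epochs; use cluster_average() first.")
  }
  labs <- as.character(labels %||% epochs$trial_labels)
  if (length(labs) != dim(epochs$data)[1]) {
    abort("Need one outcome label per trial.")
  }
  if (!all(labs %in% c("success", "failure"))) {
    abort("Labels must be 'success' or 'failure'.")
  }
  ns <- sum(labs == "success")
  nf <- sum(labs == "failure")
  if (ns == 0 || nf == 0) {
    abort("Both outcome classes must be present; the difference wave is undefined otherwise.")
  }
  mat <- matrix(epochs$data[, 1, ], nrow = dim(epochs$data)[1])
  s_erp <- colMeans(mat[labs == "success", , drop = FALSE])
  f_erp <- colMeans(mat[labs == "failure", , drop = FALSE])
  structure(list(times = epoch_times(epochs), success_erp = s_erp,
                 failure_erp = f_erp, difference_wave = s_erp - f_erp,
                 n_success = ns, n_failure = nf),
            class = "vmr_erpset")
}

#' @export
print.vmr_erpset <- function(x, ...) {
  cat(sprintf("<vmr_erpset> %d success / %d failure trials, %g to %g s\n",
              x$n_success, x$n_failure, min(x$times), max(x$times)))
  invisible(x)
}

#' FRN amplitude from a difference wave
#'
#' Mean voltage of the success-minus-failure difference wave in a fixed
#' post-feedback window (200-350 ms, endpoints inclusive).
#'
#' @param erps A [condition_erps()] result.
#' @param window Length-2 numeric, window in seconds after feedback onset.
#' @return FRN amplitude in microvolts (typically negative).
#' @export
frn_amplitude <- function(erps, window = c(0.2, 0.35)) {
  stopifnot(inherits(erps, "vmr_erpset"))
  sel <- erps$times >= window[1] - 1e-9 & erps$times <= window[2] + 1e-9
  if (!any(sel) || window[1] < min(erps$times) - 1e-9 ||
      window[2] > max(erps$times) + 1e-9) {
    abort("FRN window lies outside the epoch.")
  }
  mean(erps$difference_wave[sel])
}

#' Flag group-level outliers at k standard deviations
#'
#' Single-pass rule: values beyond `mean +/- k * SD` of the full sample
#' (sample SD, n - 1 denominator) are flagged. The mean and SD are not
#' recomputed after removal. With zero variance nothing is flagged. `NA`
#' values are ignored in the statistics and stay `NA` in the mask.
#'
#' @param values Numeric vector (n >= 3 non-missing).
#' @param k Number of SDs (default 2).
#' @return Logical vector, `TRUE` = retained, `FALSE` = flagged as outlier.
#' @examples
#' exclude_outliers(c(0, 0, 0, 0, 100))
#' @export
exclude_outliers <- function(values, k = 2) {
  ok <- !is.na(values)
  if (sum(ok) < 3) abort("Need at least 3 non-missing values.")
  m <- mean(values[ok])
  s <- sd(values[ok])
  keep <- rep(NA, length(values))
  keep[ok] <- if (s == 0) TRUE else abs(values[ok] - m) <= k * s
  keep
}
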