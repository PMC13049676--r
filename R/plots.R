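#' Trial-by-trial reach directions
#'
#' Mean reach direction per trial with a ribbon of +/-1 SD across
#' participants, split by feedback condition; block boundaries are marked.
#'
#' @param trials A trial table with `trial`, `theta_deg`, `condition` (and
#'   optionally `id`) columns -- e.g. the bound rows of
#'   [simulate_cohort()]'s `trials` list column or the pipeline's
#'   `trials.csv`.
#' @param schedule A [task_schedule()] for the block boundaries.
#' @return A ggplot object.
#' @export
plot_reach_directions <- function(trials, schedule = task_schedule()) {
  summ <- trials |>
    dplyr::group_by(.data$condition, .data$trial) |>
    dplyr::summarise(m = mean(.data$theta_deg),
                     s = sd(.data$theta_deg), .groups = "drop")
  summ$s[is.na(summ$s)] <- 0
  edges <- vapply(schedule$ranges, min, integer(1))[-1]
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$trial, y = .data$m,
                                     colour = .data$condition,
                                     fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$s,
                                      ymax = .data$m + .data$s),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = edges - 0.5, linetype = "dotted") +
    ggplot2::labs(x = "Trial", y = "Reach direction (deg)",
                  colour = "Condition", fill = "Condition")
}

#' @method autoplot vmr_erd_map
#' @export
autoplot.vmr_erd_map <- function(object, ...) {
  df <- tidyr::expand_grid(time_s = object$times, freq_hz = object$freqs)
  df$erd_pct <- as.vector(object$erd_pct)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = .data$erd_pct)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)", fill = "ERD (%)")
}

#' @method autoplot vmr_erpset
#' @export
autoplot.vmr_erpset <- function(object, ...) {
  df <- tibble::tibble(
    time_s = rep(object$times, 3),
    uv = c(object$success_erp, object$failure_erp, object$difference_wave),
    wave = rep(c("success", "failure", "difference"),
               each = length(object$times))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$uv,
                                   colour = .data$wave)) +
    ggplot2::annotate("rect", xmin = 0.2, xmax = 0.35, ymin = -Inf,
                      ymax = Inf, alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Amplitude (uV)", colour = NULL)
}

#' @method autoplot vmr_lasso
#' @export
autoplot.vmr_lasso <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = log(.data$lambda),
                                   y = .data$cv_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cv_mean - .data$cv_se,
                                      ymax = .data$cv_mean + .data$cv_se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(c(object$lambda_min,
                                           object$lambda_1se)),
                        linetype = c("dashed", "dotted")) +
    ggplot2::labs(x = "log(lambda)", y = "CV mean squared error")
}
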