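#' Phase definition for behavioral and EEG feature windows
#'
#' The adaptation and no-vision blocks are split into early and late halves.
#' Late adaptation (trials 201-300) and the full no-vision block (trials
#' 301-500) are the windows entering the learning and retention amounts; the
#' early/late halves feed the four-phase ANOVA and the early/late EEG
#' features.
#'
#' @param early_adapt,late_adapt,early_no_vision,late_no_vision Integer
#'   trial ranges.
#' @return A list of class `vmr_phases` with the four ranges plus
#'   `full_no_vision`.
#' @export
phase_definition <- function(early_adapt = 101:200,
                             late_adapt = 201:300,
                             early_no_vision = 301:400,
                             late_no_vision = 401:500) {
  ranges <- list(early_adapt = as.integer(early_adapt),
                 late_adapt = as.integer(late_adapt),
                 early_no_vision = as.integer(early_no_vision),
                 late_no_vision = as.integer(late_no_vision))
  if (anyDuplicated(unlist(ranges))) abort("Phase ranges must not overlap.")
  ranges$full_no_vision <- c(ranges$early_no_vision, ranges$late_no_vision)
  structure(ranges, class = "vmr_phases")
}

#' Signed angular reach direction from endpoint coordinates
#'
#' The reach direction is the angular difference between the hand endpoint
#' and the target direction, measured where the movement crosses the
#' invisible 8 cm circle around the start. The sign convention makes
#' clockwise deviation from the target positive, so full compensation of
#' the -30 degree (counterclockwise) cursor rotation reads +30.
#'
#' @param endpoint_xy Numeric length-2 (or n x 2 matrix) of endpoint
#'   coordinates, cm.
#' @param start_xy Numeric length-2 start position, cm.
#' @param target_angle_deg Direction of the target from the start, degrees
#'   counterclockwise from the +x axis (default 90: straight ahead).
#' @return Signed reach direction(s) in degrees.
#' @examples
#' reach_direction(c(0, 8), c(0, 0))                 # on target: 0
#' reach_direction(c(4, 8 * sqrt(3) / 2), c(0, 0))   # 30 deg clockwise: +30
#' @export
reach_direction <- function(endpoint_xy, start_xy = c(0, 0),
                            target_angle_deg = 90) {
  m <- if (is.matrix(endpoint_xy)) endpoint_xy else matrix(endpoint_xy, ncol = 2)
  dx <- m[, 1] - start_xy[1]
  dy <- m[, 2] - start_xy[2]
  if (any(dx == 0 & dy == 0)) abort("Endpoint coincides with the start position.")
  hand_deg <- atan2(dy, dx) * 180 / pi
  d <- target_angle_deg - hand_deg  # clockwise positive
  ((d + 180) %% 360) - 180
}

pick_phase_ <- function(trials, range, what) {
  idx <- trials$trial %in% range
  th <- trials$theta_deg[idx]
  th <- th[is.finite(th)]
  if (length(th) == 0) abort(paste0("No trials available in the ", what, " range."))
  th
}

#' Mean reach direction per phase
#'
#' @param trials A trial tibble as produced by [simulate_participant()] (or
#'   any table with `trial` and `theta_deg` columns).
#' @param phases A [phase_definition()].
#' @return A tibble with columns `phase` and `mean_theta_deg` for the four
#'   early/late adaptation and no-vision phases.
#' @export
phase_means <- function(trials, phases = phase_definition()) {
  ph <- c("early_adapt", "late_adapt", "early_no_vision", "late_no_vision")
  tibble::tibble(
    phase = factor(ph, levels = ph),
    mean_theta_deg = unname(vapply(
      ph, function(p) mean(pick_phase_(trials, phases[[p]], p)), numeric(1)
    ))
  )
}

#' Learning amount (% of the applied rotation)
#'
#' Mean reach direction over late adaptation (trials 201-300), divided by
#' the 30 degree rotation and expressed in percent: 100 % means the average
#' late-adaptation reach fully compensated the rotation.
#'
#' @inheritParams phase_means
#' @param rotation_deg Magnitude of the rotation being compensated.
#' @return Learning amount in percent.
#' @export
learning_amount <- function(trials, phases = phase_definition(),
                            rotation_deg = 30) {
  mean(pick_phase_(trials, phases$late_adapt, "late adaptation")) /
    rotation_deg * 100
}

#' Retention amount (% of the applied rotation)
#'
#' Mean reach direction over the whole no-vision block (trials 301-500) as
#' a percentage of the rotation -- the behavioral index of motor memory
#' persistence once feedback is removed.
#'
#' @inheritParams learning_amount
#' @return Retention amount in percent.
#' @export
retention_amount <- function(trials, phases = phase_definition(),
                             rotation_deg = 30) {
  mean(pick_phase_(trials, phases$full_no_vision, "no-vision")) /
    rotation_deg * 100
}

#' Per-participant behavioral summary
#'
#' @inheritParams learning_amount
#' @return A one-row tibble: the four phase means (wide), `learning_pct`,
#'   `retention_pct`, and `total_score` (final cumulative points, `NA` if
#'   the table has no `cum_points` column).
#' @export
behavior_summary <- function(trials, phases = phase_definition(),
                             rotation_deg = 30) {
  pm <- phase_means(trials, phases)
  wide <- tidyr::pivot_wider(pm, names_from = "phase",
                             values_from = "mean_theta_deg")
  wide$learning_pct <- learning_amount(trials, phases, rotation_deg)
  wide$retention_pct <- retention_amount(trials, phases, rotation_deg)
  wide$total_score <- if ("cum_points" %in% names(trials)) {
    tail(trials$cum_points, 1)
  } else {
    NA_integer_
  }
  wide
}
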