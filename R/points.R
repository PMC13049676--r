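#' Per-trial points under the reward / punishment incentive scheme
#'
#' Maps a trial outcome to the points shown to the participant. The reward
#' group earns 4 points for a target hit and 3/2/1/0 points for endpoint
#' errors of <10, <20, <30 and >=30 degrees; the punishment group loses
#' points on the mirrored scale (0 for a hit down to -4 for >=30 degrees).
#' Trials labelled "slow" or "fast" are treated as equivalent to a >=30
#' degree error regardless of accuracy: 0 points under reward, -4 under
#' punishment.
#'
#' @param endpoint_error_deg Absolute angular miss of the cursor from the
#'   target, in degrees (non-negative). Vectorised.
#' @param hit Logical; did the cursor hit the target?
#' @param speed_label One of `"ok"`, `"slow"`, `"fast"`.
#' @param condition One of `"reward"`, `"punishment"`.
#' @return Integer points, one per input trial.
#' @examples
#' assign_points(0, hit = TRUE, speed_label = "ok", condition = "reward")   # 4
#' assign_points(15, FALSE, "ok", "punishment")                             # -2
#' assign_points(5, FALSE, "fast", "punishment")                            # -4
#' @export
assign_points <- function(endpoint_error_deg, hit, speed_label, condition) {
  n <- max(length(endpoint_error_deg), length(hit),
           length(speed_label), length(condition))
  endpoint_error_deg <- rep_len(endpoint_error_deg, n)
  hit <- rep_len(hit, n)
  speed_label <- rep_len(as.character(speed_label), n)
  condition <- rep_len(as.character(condition), n)

  if (!all(speed_label %in% c("ok", "slow", "fast"))) {
    abort("`speed_label` must be one of 'ok', 'slow', 'fast'.")
  }
  if (!all(condition %in% c("reward", "punishment"))) {
    abort("`condition` must be 'reward' or 'punishment'.")
  }
  if (any(!is.finite(endpoint_error_deg)) || any(endpoint_error_deg < 0)) {
    abort("`endpoint_error_deg` must be finite and non-negative.")
  }

  # bin 0 = hit, 1 = <10 deg, 2 = <20 deg, 3 = <30 deg, 4 = >=30 deg
  bin <- ifelse(hit, 0L,
         ifelse(endpoint_error_deg < 10, 1L,
         ifelse(endpoint_error_deg < 20, 2L,
         ifelse(endpoint_error_deg < 30, 3L, 4L))))
  bin[speed_label != "ok"] <- 4L
  as.integer(ifelse(condition == "reward", 4L - bin, -bin))
}

#' Classify a trial outcome as success or failure from its points
#'
#' A trial counts as a success when it earned the best possible outcome for
#' its condition: 4 points in the reward group, 0 points in the punishment
#' group. Everything else (reward 3..0; punishment -1..-4) is a failure.
#' This is the labelling used to form the feedback-locked ERP contrast.
#'
#' @param points Integer points awarded on the trial (vectorised).
#' @param condition `"reward"` or `"punishment"`.
#' @return Factor with levels `success`, `failure`.
#' @examples
#' classify_outcome(c(4, 3, 0), "reward")
#' classify_outcome(c(0, -1, -4), "punishment")
#' @export
classify_outcome <- function(points, condition) {
  n <- max(length(points), length(condition))
  points <- rep_len(as.integer(points), n)
  condition <- rep_len(as.character(condition), n)
  if (!all(condition %in% c("reward", "punishment"))) {
    abort("`condition` must be 'reward' or 'punishment'.")
  }
  ok <- (condition == "reward" & points %in% 0:4) |
        (condition == "punishment" & points %in% -4:0)
  if (!all(ok)) {
    abort("`points` out of range for the stated condition.")
  }
  success <- ifelse(condition == "reward", points == 4L, points == 0L)
  factor(ifelse(success, "success", "failure"),
         levels = c("success", "failure"))
}
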