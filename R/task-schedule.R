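#' Task schedule for the four-block visuomotor rotation session
#'
#' Describes the 550-trial session layout: a baseline block (trials 1-100),
#' an adaptation block (101-300) during which a 30 degree counterclockwise
#' rotation is applied to the cursor, a no-vision block (301-500) with all
#' visual feedback removed, and a washout block (501-550). Also carries the
#' task geometry (8 cm target distance) and the movement-speed thresholds
#' used to label trials as "slow" or "fast".
#'
#' @param n_trials Total number of trials in the session.
#' @param baseline,adaptation,no_vision,washout Integer vectors of trial
#'   indices for each block. The four ranges must partition `1:n_trials`.
#' @param rotation_deg Rotation applied to the cursor during the adaptation
#'   block, in degrees. Negative is counterclockwise; the default -30
#'   requires a +30 degree (clockwise) compensatory reach.
#' @param endpoint_radius_cm Radius of the invisible circle on which the
#'   endpoint is measured, in cm.
#' @param slow_threshold_mm_s,fast_threshold_mm_s Maximum-speed cutoffs
#'   (mm/s): below the first the trial is labelled "slow", above the second
#'   "fast".
#'
#' @return An object of class `vmr_schedule`: a list with the fields above
#'   plus `blocks`, a tibble with one row per trial giving its block.
#' @examples
#' sched <- task_schedule()
#' table(sched$blocks$block)
#' @export
task_schedule <- function(n_trials = 550L,
                          baseline = 1:100,
                          adaptation = 101:300,
                          no_vision = 301:500,
                          washout = 501:550,
                          rotation_deg = -30,
                          endpoint_radius_cm = 8,
                          slow_threshold_mm_s = 312,
                          fast_threshold_mm_s = 469) {
  n_trials <- as.integer(n_trials)
  ranges <- list(baseline = as.integer(baseline),
                 adaptation = as.integer(adaptation),
                 no_vision = as.integer(no_vision),
                 washout = as.integer(washout))
  all_idx <- sort(unlist(ranges, use.names = FALSE))
  if (!identical(all_idx, seq_len(n_trials))) {
    abort("Block ranges must partition 1..n_trials without gaps or overlap.")
  }
  if (slow_threshold_mm_s >= fast_threshold_mm_s) {
    abort("`slow_threshold_mm_s` must be below `fast_threshold_mm_s`.")
  }
  blocks <- tibble::tibble(
    trial = seq_len(n_trials),
    block = factor(
      dplyr::case_when(
        trial %in% ranges$baseline ~ "baseline",
        trial %in% ranges$adaptation ~ "adaptation",
        trial %in% ranges$no_vision ~ "no_vision",
        TRUE ~ "washout"
      ),
      levels = c("baseline", "adaptation", "no_vision", "washout")
    )
  )
  structure(
    list(n_trials = n_trials, ranges = ranges, blocks = blocks,
         rotation_deg = rotation_deg,
         endpoint_radius_cm = endpoint_radius_cm,
         slow_threshold_mm_s = slow_threshold_mm_s,
         fast_threshold_mm_s = fast_threshold_mm_s),
    class = "vmr_schedule"
  )
}

#' @export
print.vmr_schedule <- function(x, ...) {
  cat("<vmr_schedule> ", x$n_trials, " trials\n", sep = "")
  for (b in names(x$ranges)) {
    r <- x$ranges[[b]]
    cat(sprintf("  %-10s trials %d-%d\n", b, min(r), max(r)))
  }
  cat(sprintf("  rotation %g deg during adaptation; endpoint radius %g cm\n",
              x$rotation_deg, x$endpoint_radius_cm))
  cat(sprintf("  speed labels: slow < %g mm/s, fast > %g mm/s\n",
              x$slow_threshold_mm_s, x$fast_threshold_mm_s))
  invisible(x)
}

#' Rotation applied on a given trial
#'
#' @param schedule A [task_schedule()] object.
#' @param trial Trial index (vectorised).
#' @return Rotation in degrees (nonzero only during adaptation).
#' @keywords internal
#' @noRd
rotation_on_trial <- function(schedule, trial) {
  ifelse(trial %in% schedule$ranges$adaptation, schedule$rotation_deg, 0)
}
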