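#' Epoched multichannel EEG
#'
#' A light container for epoched EEG: a numeric array
#' `[n_trials x n_channels x n_samples]` in microvolts plus sampling rate,
#' the time of sample 1 relative to the event, channel labels, the event
#' the epochs are locked to, and per-trial labels (outcome or phase tags).
#'
#' @param data Numeric array `[trials x channels x samples]`, microvolts.
#' @param srate Sampling rate, Hz.
#' @param t0_offset_s Time of the first sample relative to the event, s
#'   (-3 for go-cue epochs, -0.2 for feedback epochs).
#' @param channels Character vector of channel labels (length = dim 2).
#' @param event_kind `"go_cue"` or `"feedback"`.
#' @param trial_labels Optional character/factor vector (length = dim 1).
#' @param ground_truth Optional [eeg_ground_truth()] carried for reference.
#' @return An object of class `vmr_epochs`.
#' @export
epoched_eeg <- function(data, srate, t0_offset_s, channels,
                        event_kind = c("go_cue", "feedback"),
                        trial_labels = NULL, ground_truth = NULL) {
  event_kind <- match.arg(event_kind)
  if (!is.array(data) || length(dim(data)) != 3) {
    abort("`data` must be a 3-d array [trials x channels x samples].")
  }
  if (length(channels) != dim(data)[2]) {
    abort("`channels` length must match dim(data)[2].")
  }
  if (!is.null(trial_labels) && length(trial_labels) != dim(data)[1]) {
    abort("`trial_labels` length must match dim(data)[1].")
  }
  structure(
    list(data = data, srate = srate, t0_offset_s = t0_offset_s,
         channels = as.character(channels), event_kind = event_kind,
         trial_labels = trial_labels, ground_truth = ground_truth),
    class = "vmr_epochs"
  )
}

#' @export
print.vmr_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vmr_epochs> %s-locked: %d trials x %d channels x %d samples @ %g Hz\n",
              x$event_kind, d[1], d[2], d[3], x$srate))
  cat(sprintf("  time %g .. %g s\n", x$t0_offset_s,
              x$t0_offset_s + (d[3] - 1) / x$srate))
  invisible(x)
}

#' Sample times of an epoch set
#' @param epochs A [epoched_eeg()] object.
#' @return Numeric vector of sample times in seconds relative to the event.
#' @export
epoch_times <- function(epochs) {
  epochs$t0_offset_s + (seq_len(dim(epochs$data)[3]) - 1) / epochs$srate
}

n_trials_of_ <- function(epochs) dim(epochs$data)[1]

#' Default synthetic montage and channel clusters
#'
#' The synthetic montage covers the left sensorimotor cluster used for ERD
#' (C3 and its six surrounding channels), the fronto-central cluster used
#' for the FRN (FCz and its surrounding seven electrodes), the mastoids for
#' re-referencing, and a few far-field channels.
#'
#' @return Character vectors of channel labels.
#' @export
default_montage <- function() {
  unique(c(c3_cluster(), fcz_cluster(), c("C4", "P3", "P4", "Pz", "Oz"),
           mastoid_channels()))
}

#' @rdname default_montage
#' @export
c3_cluster <- function() c("C3", "FC5", "FC3", "C5", "C1", "CP5", "CP3")

#' @rdname default_montage
#' @export
fcz_cluster <- function() c("FCz", "Fz", "F1", "F2", "FC1", "FC2", "Cz", "FC4")

#' @rdname default_montage
#' @export
mastoid_channels <- function() c("M1", "M2")

#' Write / read an epoch set as a flat binary array plus JSON sidecar
#'
#' The samples are stored as row-major float32 (trial, then channel, then
#' sample fastest) in `<prefix>.f32`; all metadata (dimensions, sampling
#' rate, epoch timing, channel labels, trial labels, event kind, and any
#' ground truth) goes to `<prefix>.json`.
#'
#' @param epochs A [epoched_eeg()] object.
#' @param prefix Path prefix (without extension).
#' @return `write_epochs()` returns `prefix` invisibly; `read_epochs()`
#'   returns a [epoched_eeg()].
#' @export
write_epochs <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "vmr_epochs"))
  d <- dim(epochs$data)
  con <- file(paste0(prefix, ".f32"), "wb")
  on.exit(close(con))
  # row-major: reverse dims so the sample index runs fastest
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con, size = 4L)
  meta <- list(
    dims = d, srate = epochs$srate, t0_offset_s = epochs$t0_offset_s,
    channels = epochs$channels, event_kind = epochs$event_kind,
    trial_labels = epochs$trial_labels,
    ground_truth = unclass(epochs$ground_truth)
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  con <- file(paste0(prefix, ".f32"), "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "numeric", n = prod(d), size = 4L)
  data <- aperm(array(raw, dim = rev(d)), c(3, 2, 1))
  gt <- meta$ground_truth
  if (!is.null(gt)) gt <- structure(gt, class = "vmr_ground_truth")
  epoched_eeg(data, srate = meta$srate, t0_offset_s = meta$t0_offset_s,
              channels = meta$channels, event_kind = meta$event_kind,
              trial_labels = meta$trial_labels, ground_truth = gt)
}
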