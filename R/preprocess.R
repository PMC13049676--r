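#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass to every trial and channel with
#' forward-backward (zero-phase) filtering. The band is realised as a
#' high-pass / low-pass cascade, which stays numerically well behaved even
#' for very low cut-offs such as the 0.1 Hz edge used before ERP analysis.
#' Standard settings: 1-60 Hz before ERD analysis, 0.1-30 Hz before FRN
#' analysis.
#'
#' @param epochs A [epoched_eeg()].
#' @param low_hz,high_hz Band edges, Hz; `0 < low < high < srate / 2`.
#' @param order Butterworth order of each cascade section (default 4).
#' @return Filtered [epoched_eeg()].
#' @export
eeg_bandpass <- function(epochs, low_hz, high_hz, order = 4) {
  stopifnot(inherits(epochs, "vmr_epochs"))
  nyq <- epochs$srate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    abort("Need 0 < low_hz < high_hz < srate/2.")
  }
  hp <- signal::butter(order, low_hz / nyq, type = "high")
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  out <- epochs
  d <- dim(epochs$data)
  n <- d[3]
  pad <- n - 1L  # mirror padding suppresses filtfilt edge transients
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- epochs$data[tr, ch, ]
      xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
      xp <- signal::filtfilt(hp, xp)
      xp <- signal::filtfilt(lp, xp)
      out$data[tr, ch, ] <- xp[(pad + 1):(pad + n)]
    }
  }
  out
}

#' Re-reference epoched EEG
#'
#' `common_average` subtracts the instantaneous mean across all channels
#' (used for ERD analysis); `linked_mastoids` subtracts the mean of the two
#' mastoid channels (used before ERP/FRN analysis to emphasise
#' fronto-central components).
#'
#' @param epochs A [epoched_eeg()].
#' @param scheme `"common_average"` or `"linked_mastoids"`.
#' @param mastoids Labels of the mastoid channels.
#' @return Re-referenced [epoched_eeg()].
#' @export
eeg_rereference <- function(epochs,
                            scheme = c("common_average", "linked_mastoids"),
                            mastoids = mastoid_channels()) {
  stopifnot(inherits(epochs, "vmr_epochs"))
  scheme <- match.arg(scheme)
  d <- dim(epochs$data)
  out <- epochs
  if (scheme == "linked_mastoids") {
    idx <- match(mastoids, epochs$channels)
    if (anyNA(idx)) abort("Mastoid channels not present in the montage.")
  }
  for (tr in seq_len(d[1])) {
    slab <- epochs$data[tr, , , drop = FALSE][1, , ]  # channels x samples
    ref <- if (scheme == "common_average") colMeans(slab) else colMeans(slab[idx, , drop = FALSE])
    out$data[tr, , ] <- sweep(slab, 2, ref)
  }
  out
}

#' Average an epoch set over a channel cluster
#'
#' Sample-wise mean over the listed channels, returning a single-channel
#' epoch set (used to pool the C3-centered sensorimotor cluster before ERD
#' analysis and the FCz-centered cluster before FRN analysis).
#'
#' @param epochs A [epoched_eeg()].
#' @param channel_list Channel labels to average; all must be present.
#' @param label Name given to the pooled channel.
#' @return A single-channel [epoched_eeg()].
#' @export
cluster_average <- function(epochs, channel_list, label = "cluster") {
  stopifnot(inherits(epochs, "vmr_epochs"))
  idx <- match(channel_list, epochs$channels)
  if (anyNA(idx)) {
    abort(paste0("Unknown channel label(s): ",
                 paste(channel_list[is.na(idx)], collapse = ", ")))
  }
  d <- dim(epochs$data)
  pooled <- array(0, dim = c(d[1], 1L, d[3]))
  for (tr in seq_len(d[1])) {
    slab <- matrix(epochs$data[tr, idx, ], nrow = length(idx), ncol = d[3])
    pooled[tr, 1, ] <- colMeans(slab)
  }
  out <- epochs
  out$data <- pooled
  out$channels <- label
  out
}

#' Baseline-correct epoched EEG
#'
#' Subtracts, per trial and channel, the mean voltage over the baseline
#' interval (default the 200 ms immediately preceding the event).
#'
#' @param epochs A [epoched_eeg()].
#' @param baseline Length-2 numeric, interval in seconds relative to the
#'   event (inclusive).
#' @return Baseline-corrected [epoched_eeg()].
#' @export
baseline_correct <- function(epochs, baseline = c(-0.2, 0)) {
  stopifnot(inherits(epochs, "vmr_epochs"))
  t <- epoch_times(epochs)
  sel <- t >= baseline[1] - 1e-9 & t <= baseline[2] + 1e-9
  if (!any(sel)) abort("Baseline interval lies outside the epoch.")
  out <- epochs
  d <- dim(epochs$data)
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      out$data[tr, ch, ] <- epochs$data[tr, ch, ] -
        mean(epochs$data[tr, ch, sel])
    }
  }
  out
}
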