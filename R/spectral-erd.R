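#' Sliding-window Hanning-tapered power spectrum
#'
#' Short-time power spectral density of single-channel epochs: a Hanning-
#' tapered window of `win_s` seconds slides in `step_s` steps; per window
#' the one-sided periodogram is computed and power is averaged across
#' trials. Windows whose full support does not fit inside the epoch are
#' dropped rather than zero-padded, so the first usable center lies half a
#' window after epoch onset. With the default 1 s window the frequency
#' resolution is 1 Hz.
#'
#' @param epochs A single-channel [epoched_eeg()] (pool clusters with
#'   [cluster_average()] first).
#' @param win_s Window length, s.
#' @param step_s Step between window centers, s (default 0.1 s = 90 %
#'   overlap).
#' @return An object of class `vmr_tfr`: `power` (`[n_freqs x n_times]`,
#'   uV^2/Hz, trial-averaged), `freqs` (Hz), `times` (window centers, s),
#'   `srate`, `n_trials`.
#' @export
tf_power <- function(epochs, win_s = 1, step_s = 0.1) {
  stopifnot(inherits(epochs, "vmr_epochs"))
  if (dim(epochs$data)[2] != 1) {
    abort("`tf_power()` expects single-channel epochs; use cluster_average() first.")
  }
  srate <- epochs$srate
  nwin <- round(win_s * srate)
  d <- dim(epochs$data)
  if (nwin > d[3]) abort("Epoch too short for one full analysis window.")
  t <- epoch_times(epochs)

  # window centers on a step_s grid, full support inside the epoch
  t_lo <- t[1] + win_s / 2
  t_hi <- t[d[3]] - win_s / 2
  first <- ceiling((t_lo - 1e-9) / step_s)
  last <- floor((t_hi + 1e-9) / step_s)
  centers <- seq(first, last) * step_s
  if (length(centers) == 0) abort("Epoch too short for one full analysis window.")

  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nwin) - 1) / nwin)  # periodic Hann
  scale <- 2 / (srate * sum(w^2))
  n_freq <- nwin %/% 2 + 1
  freqs <- (seq_len(n_freq) - 1) / win_s

  power <- matrix(0, n_freq, length(centers))
  for (ci in seq_along(centers)) {
    i0 <- round((centers[ci] - win_s / 2 - t[1]) * srate) + 1
    seg <- epochs$data[, 1, i0:(i0 + nwin - 1), drop = FALSE]
    seg <- matrix(seg, nrow = d[1], ncol = nwin)        # trials x samples
    X <- mvfft(t(seg * rep(w, each = d[1])))            # fft per trial
    P <- scale * Mod(X[seq_len(n_freq), , drop = FALSE])^2
    P[1, ] <- P[1, ] / 2                                # DC is one-sided
    if (nwin %% 2 == 0) P[n_freq, ] <- P[n_freq, ] / 2  # Nyquist too
    power[, ci] <- rowMeans(P)
  }
  structure(list(power = power, freqs = freqs, times = centers,
                 srate = srate, n_trials = d[1]),
            class = "vmr_tfr")
}

#' @export
print.vmr_tfr <- function(x, ...) {
  cat(sprintf("<vmr_tfr> %d freqs (%g-%g Hz) x %d times (%g to %g s), %d trials\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times), x$n_trials))
  invisible(x)
}

#' Event-related desynchronization map
#'
#' Converts a trial-averaged time-frequency power map `A(f, t)` into
#' percent ERD relative to the reference spectrum `R(f)`, the mean power
#' over the reference window: `ERD(f, t) = (R(f) - A(f, t)) / R(f) * 100`.
#' Positive values are power decreases (desynchronization).
#'
#' @param tfr A [tf_power()] result.
#' @param ref_window Length-2 numeric, reference interval in s (window
#'   centers falling inside it, inclusive, define `R(f)`).
#' @return An object of class `vmr_erd_map`: `erd_pct` (`[freq x time]`),
#'   `power`, `freqs`, `times`, `ref_power`, `ref_window`.
#' @export
erd_map <- function(tfr, ref_window = c(-2, -1)) {
  stopifnot(inherits(tfr, "vmr_tfr"))
  sel <- tfr$times >= ref_window[1] - 1e-9 & tfr$times <= ref_window[2] + 1e-9
  if (!any(sel)) abort("Reference window is not covered by the time axis.")
  ref <- rowMeans(tfr$power[, sel, drop = FALSE])
  if (any(ref == 0)) {
    abort("Reference power is zero at some frequency; ERD is undefined there.")
  }
  erd <- sweep(-sweep(tfr$power, 1, ref), 1, ref, "/") * 100
  structure(list(erd_pct = erd, power = tfr$power, freqs = tfr$freqs,
                 times = tfr$times, ref_power = ref, ref_window = ref_window),
            class = "vmr_erd_map")
}

#' Peak ERD feature in a frequency band
#'
#' Finds the maximum ERD value inside `band` x `search_window` (the
#' preparatory interval, -1 to 0 s by default), then averages ERD over a
#' +/-0.2 s by +/-2 Hz neighbourhood centered on that peak, truncated at
#' the map edges. The neighbourhood average absorbs inter-individual
#' variability in the exact time and frequency of the peak. Ties at the
#' maximum resolve to the first cell in column-major (frequency fastest)
#' scan order.
#'
#' @param map A [erd_map()] result.
#' @param band Length-2 numeric, band edges in Hz (inclusive); use
#'   `c(8, 13)` for alpha, `c(15, 30)` for beta.
#' @param search_window Length-2 numeric, time interval searched for the
#'   peak, s.
#' @param avg_halfwidth_s,avg_halfwidth_hz Half-widths of the averaging
#'   neighbourhood.
#' @return A one-row tibble: `band_lo_hz`, `band_hi_hz`, `peak_time_s`,
#'   `peak_freq_hz`, `value_pct`.
#' @export
extract_peak_erd <- function(map, band, search_window = c(-1, 0),
                             avg_halfwidth_s = 0.2, avg_halfwidth_hz = 2) {
  stopifnot(inherits(map, "vmr_erd_map"))
  fsel <- map$freqs >= band[1] - 1e-9 & map$freqs <= band[2] + 1e-9
  tsel <- map$times >= search_window[1] - 1e-9 &
    map$times <= search_window[2] + 1e-9
  if (!any(fsel) || !any(tsel)) {
    abort("Empty search region: band or window lies outside the map axes.")
  }
  sub <- map$erd_pct[fsel, tsel, drop = FALSE]
  k <- which.max(sub)  # column-major: frequency index varies fastest
  fi <- (k - 1) %% nrow(sub) + 1
  ti <- (k - 1) %/% nrow(sub) + 1
  peak_f <- map$freqs[fsel][fi]
  peak_t <- map$times[tsel][ti]

  nf <- abs(map$freqs - peak_f) <= avg_halfwidth_hz + 1e-9
  nt <- abs(map$times - peak_t) <= avg_halfwidth_s + 1e-9
  value <- mean(map$erd_pct[nf, nt])

  tibble::tibble(band_lo_hz = band[1], band_hi_hz = band[2],
                 peak_time_s = peak_t, peak_freq_hz = peak_f,
                 value_pct = value)
}
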