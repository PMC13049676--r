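#' Planted EEG ground truth for the synthetic generators
#'
#' Specifies, per adaptation phase, the preparatory-window desynchronization
#' of the alpha and beta rhythms over the sensorimotor cluster and the
#' amplitude of the feedback difference wave at the fronto-central cluster.
#' ERD is expressed with the field's sign convention: positive percentages
#' are power decreases relative to the reference window, and 100 % means
#' complete suppression (values above 100 are impossible -- the modulated
#' amplitude would be imaginary).
#'
#' @param alpha_erd_pct,beta_erd_pct Named numeric (`early`, `late`):
#'   preparatory-window ERD in percent, `<= 100`.
#' @param frn_uv Named numeric (`early`, `late`): mean success-minus-failure
#'   difference-wave amplitude in the 200-350 ms window, microvolts
#'   (typically negative).
#' @param alpha_hz,beta_hz Center frequencies of the planted rhythms; must
#'   lie inside the 8-13 Hz and 15-30 Hz analysis bands.
#' @return An object of class `vmr_ground_truth`.
#' @examples
#' eeg_ground_truth(alpha_erd_pct = c(early = 40, late = 60))
#' @export
eeg_ground_truth <- function(alpha_erd_pct = c(early = 45, late = 55),
                             beta_erd_pct = c(early = 35, late = 45),
                             frn_uv = c(early = -4, late = -2.5),
                             alpha_hz = 10, beta_hz = 22) {
  for (v in list(alpha_erd_pct, beta_erd_pct)) {
    if (any(v > 100)) abort("ERD percentages cannot exceed 100.")
  }
  if (alpha_hz < 8 || alpha_hz > 13) abort("`alpha_hz` must lie in 8-13 Hz.")
  if (beta_hz < 15 || beta_hz > 30) abort("`beta_hz` must lie in 15-30 Hz.")
  structure(list(alpha_erd_pct = alpha_erd_pct, beta_erd_pct = beta_erd_pct,
                 frn_uv = frn_uv, alpha_hz = alpha_hz, beta_hz = beta_hz),
            class = "vmr_ground_truth")
}

# 1/f ("pink") background noise, sd scaled to `sd_uv`, via FFT shaping of
# white noise with spectral exponent `exponent` (power ~ 1/f^exponent).
pink_noise_ <- function(n, sd_uv, exponent = 1) {
  if (sd_uv == 0) return(numeric(n))
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))            # avoid 1/0 at DC
  f <- pmin(f, n - f + 1)              # mirror for negative frequencies
  W <- W / f^(exponent / 2)
  x <- Re(fft(W, inverse = TRUE)) / n
  x <- x - mean(x)
  x / sd(x) * sd_uv
}

# Raised-cosine step from 0 to 1 centered at `at`, ramp width `ramp_s`.
rc_step_ <- function(t, at, ramp_s = 0.1) {
  u <- clamp_((t - at) / ramp_s + 0.5, 0, 1)
  0.5 - 0.5 * cos(pi * u)
}

# Amplitude envelope implementing the planted ERD: unity in the reference
# window, dropping smoothly to sqrt(1 - erd/100) from `onset_s` until
# `offset_s` (desynchronization builds up late in the preparatory delay and
# persists through movement execution).
erd_envelope_ <- function(t, erd_pct, onset_s = -0.9, offset_s = 1.5,
                          ramp_s = 0.1) {
  a <- sqrt(1 - erd_pct / 100)
  gate <- rc_step_(t, onset_s, ramp_s) * (1 - rc_step_(t, offset_s, ramp_s))
  1 + (a - 1) * gate
}

# Multi-sine band carrier: one component per integer frequency in
# [lo, hi] at `amp_uv` each, with the supplied phases. Spanning the whole
# band gives every in-band frequency bin reference power, so the ERD ratio
# is defined (and equal to the planted value) across the full band mask.
band_carrier_ <- function(t, lo, hi, amp_uv, phases) {
  freqs <- seq(ceiling(lo), floor(hi))
  x <- numeric(length(t))
  for (i in seq_along(freqs)) {
    x <- x + amp_uv * sin(2 * pi * freqs[i] * t + phases[i])
  }
  x
}

#' Generate go-cue-locked epochs with planted ERD
#'
#' Builds 7 s epochs (-3 to +4 s around the go cue) in which the
#' sensorimotor-cluster channels carry band-limited alpha and beta rhythms:
#' one sinusoidal component per integer frequency in 6-13 Hz and 15-32 Hz
#' (slightly wider than the analysis bands, so every analysed bin holds
#' rhythm power) plus a stationary 14 Hz component buffering the two
#' bands. From 0.9 s before the go cue until 1.5 s after it the rhythm
#' amplitude is scaled by `sqrt(1 - ERD/100)` with smooth raised-cosine
#' ramps, so band power in the preparatory window (-1 to 0 s) sits `ERD`
#' percent below the reference window (-2 to -1 s); the suppression is
#' deepest at the rhythm's center frequency. Component phases are fixed
#' within an epoch set and the carrier cycles through eight 1/8 s time
#' shifts across trials, which cancels window-leakage interference in the
#' trial-averaged power (see the source for the argument). A 1/f
#' background is added to every channel; channels outside the cluster
#' carry background only.
#'
#' @param gt A [eeg_ground_truth()].
#' @param phase `"early"` or `"late"`: which planted ERD values to use.
#' @param n_trials Number of epochs (>= 1).
#' @param noise_sd_uv SD of the 1/f background, microvolts (0 = clean).
#' @param seed Integer seed or `NULL`.
#' @param srate Sampling rate, Hz.
#' @param channels Montage labels.
#' @param cluster Channels that carry the planted rhythms.
#' @param amp_uv Amplitude per sinusoidal component, microvolts
#'   (named `alpha`, `beta`).
#' @param erd_taper_pct_per_hz How much the planted suppression depth
#'   falls off per Hz of distance from the rhythm's center frequency
#'   (percentage points); makes the ERD peak at `alpha_hz` / `beta_hz`.
#' @return A go-cue-locked [epoched_eeg()] with the ground truth attached.
#' @export
generate_go_epochs <- function(gt, phase = c("early", "late"),
                               n_trials = 30, noise_sd_uv = 1, seed = NULL,
                               srate = 1000, channels = default_montage(),
                               cluster = c3_cluster(),
                               amp_uv = c(alpha = 4, beta = 2),
                               erd_taper_pct_per_hz = 0.5) {
  stopifnot(inherits(gt, "vmr_ground_truth"))
  phase <- match.arg(phase)
  if (!is_count_(n_trials)) abort("`n_trials` must be a positive integer.")
  a_erd <- gt$alpha_erd_pct[[phase]]
  b_erd <- gt$beta_erd_pct[[phase]]
  if (a_erd > 100 || b_erd > 100) abort("ERD percentages cannot exceed 100.")
  if (!all(cluster %in% channels)) abort("`cluster` must be a subset of `channels`.")

  with_seed_(seed, {
    n_samp <- as.integer(7 * srate)
    t <- -3 + (seq_len(n_samp) - 1) / srate
    n_ch <- length(channels)
    in_cluster <- channels %in% cluster

    # Component phases are fixed per epoch set; across trials the carrier
    # cycles through eight 1/8 s time shifts. Within the 1 s Hanning
    # windows comb components leak into shared frequency bins and their
    # interference terms carry a factor exp(i 2 pi (delta f) shift);
    # averaging over shifts {0, 1/8, ..., 7/8} s cancels every
    # interference term with |delta f| in 1..7 exactly, so the
    # trial-averaged bin power equals the sum of component powers and the
    # planted ERD ratio is recovered bin by bin. Fixtures are cleanest
    # with n_trials a multiple of 8.
    # Combs extend past the analysis-band edges so that the +/-2 Hz
    # neighbourhood averaged around any in-band peak carries planted ERD
    # rather than noise-only bins (real mu/beta rhythms do not stop at the
    # band boundary). The suppression depth tapers mildly away from the
    # rhythm's center frequency, which anchors the extractor's argmax at
    # the center bin instead of letting spectral ripple push it to a band
    # edge. A stationary (unmodulated) 14 Hz component buffers the two
    # bands: Hann leakage spans +/-1 bin, so with it in place neither
    # band's modulation leaks into bins the other band's mask analyses.
    f_alpha <- seq(6, 13)
    f_beta <- seq(15, 32)
    freqs_all <- c(f_alpha, 14, f_beta)
    amps_all <- c(rep(amp_uv[["alpha"]], length(f_alpha) + 1),
                  rep(amp_uv[["beta"]], length(f_beta)))
    phases_all <- runif(length(freqs_all), 0, 2 * pi)
    env_of <- function(erd, dist) {
      erd_envelope_(t, max(erd - erd_taper_pct_per_hz * dist, 0))
    }
    envs <- c(
      lapply(f_alpha, function(f) env_of(a_erd, abs(f - gt$alpha_hz))),
      list(rep(1, n_samp)),  # stationary boundary buffer
      lapply(f_beta, function(f) env_of(b_erd, abs(f - gt$beta_hz)))
    )
    sigs <- lapply(0:7, function(j) {
      ts <- t + j / 8
      x <- numeric(n_samp)
      for (i in seq_along(freqs_all)) {
        x <- x + amps_all[i] *
          sin(2 * pi * freqs_all[i] * ts + phases_all[i]) * envs[[i]]
      }
      x
    })
    data <- array(0, dim = c(n_trials, n_ch, n_samp))
    for (tr in seq_len(n_trials)) {
      sig <- sigs[[(tr - 1) %% 8 + 1]]
      for (ch in seq_len(n_ch)) {
        x <- pink_noise_(n_samp, noise_sd_uv)
        if (in_cluster[ch]) x <- x + sig
        data[tr, ch, ] <- x
      }
    }
    epoched_eeg(data, srate = srate, t0_offset_s = -3, channels = channels,
                event_kind = "go_cue",
                trial_labels = rep(phase, n_trials), ground_truth = gt)
  })
}

# Difference-wave template: unit windowed mean over [0.2, 0.35] s, smooth
# Gaussian bump peaking at 275 ms, negligible mass before feedback onset.
frn_template_ <- function(t, window = c(0.2, 0.35)) {
  g <- exp(-(t - 0.275)^2 / (2 * 0.04^2))
  in_win <- t >= window[1] & t <= window[2]
  g / mean(g[in_win])
}

#' Generate feedback-locked epochs with a planted difference wave
#'
#' Builds 0.8 s epochs (-200 to +600 ms around score feedback). All trials
#' at the fronto-central cluster receive a common evoked waveform; trials
#' labelled `success` additionally receive a smooth component peaking
#' between 200 and 350 ms, scaled so the noiseless success-minus-failure
#' difference wave has mean amplitude `frn_uv` in the 200-350 ms window and
#' zero mean in the baseline interval.
#'
#' @inheritParams generate_go_epochs
#' @param outcome_labels Character/factor of `"success"` / `"failure"`, one
#'   per trial; both classes must be present.
#' @param cluster Channels carrying the evoked components.
#' @return A feedback-locked [epoched_eeg()].
#' @export
generate_feedback_epochs <- function(gt, outcome_labels,
                                     phase = c("early", "late"),
                                     noise_sd_uv = 1, seed = NULL,
                                     srate = 1000,
                                     channels = default_montage(),
                                     cluster = fcz_cluster()) {
  stopifnot(inherits(gt, "vmr_ground_truth"))
  phase <- match.arg(phase)
  labs <- as.character(outcome_labels)
  if (length(labs) == 0) abort("`outcome_labels` must be nonempty.")
  if (!all(labs %in% c("success", "failure"))) {
    abort("`outcome_labels` must be 'success' or 'failure'.")
  }
  if (length(unique(labs)) < 2) {
    abort("Both outcome classes must be present; the difference wave is undefined otherwise.")
  }
  if (!all(cluster %in% channels)) abort("`cluster` must be a subset of `channels`.")
  frn <- gt$frn_uv[[phase]]

  with_seed_(seed, {
    n_trials <- length(labs)
    n_samp <- as.integer(0.8 * srate)
    t <- -0.2 + (seq_len(n_samp) - 1) / srate
    diff_wave <- frn * frn_template_(t)
    common <- 3 * exp(-(t - 0.18)^2 / (2 * 0.03^2))  # shared evoked response
    n_ch <- length(channels)
    in_cluster <- channels %in% cluster

    data <- array(0, dim = c(n_trials, n_ch, n_samp))
    for (tr in seq_len(n_trials)) {
      evoked <- common + if (labs[tr] == "success") diff_wave else 0
      for (ch in seq_len(n_ch)) {
        x <- pink_noise_(n_samp, noise_sd_uv)
        if (in_cluster[ch]) x <- x + evoked
        data[tr, ch, ] <- x
      }
    }
    epoched_eeg(data, srate = srate, t0_offset_s = -0.2, channels = channels,
                event_kind = "feedback", trial_labels = labs,
                ground_truth = gt)
  })
}
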