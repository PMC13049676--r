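test_that("the band-pass preserves in-band tones and rejects out-of-band ones", {
  ep <- make_sine_epochs(freqs = 10, amps = 1, srate = 250, n_trials = 1)
  f <- eeg_bandpass(ep, 1, 60)
  t <- epoch_times(ep)
  mid <- t > -2 & t < 3  # away from epoch edges
  expect_equal(sd(f$data[1, 1, mid]) / sd(ep$data[1, 1, mid]), 1,
               tolerance = 0.01)
  ep80 <- make_sine_epochs(freqs = 80, amps = 1, srate = 250, n_trials = 1)
  f80 <- eeg_bandpass(ep80, 1, 60)
  expect_lt(sd(f80$data[1, 1, mid]) / sd(ep80$data[1, 1, mid]), 0.1)
  epdc <- make_sine_epochs(freqs = 10, amps = 1, srate = 250, n_trials = 1)
  epdc$data <- epdc$data + 5
  fdc <- eeg_bandpass(epdc, 1, 60)
  expect_lt(abs(mean(fdc$data[1, 1, mid])), 0.05)
  expect_error(eeg_bandpass(ep, 0, 60), "low_hz")
  expect_error(eeg_bandpass(ep, 1, 200), "srate/2")
})

test_that("re-referencing subtracts the right reference and is idempotent", {
  set.seed(3)
  data <- array(rnorm(2 * 4 * 50), dim = c(2, 4, 50))
  ep <- epoched_eeg(data, 100, 0, c("a", "b", "M1", "M2"), "feedback")
  car <- eeg_rereference(ep, "common_average")
  for (tr in 1:2) {
    expect_lt(max(abs(colMeans(car$data[tr, , ]))), 1e-12)
  }
  expect_equal(eeg_rereference(car, "common_average")$data, car$data)
  # linked mastoids equals manual subtraction on a toy set
  lm_ref <- eeg_rereference(ep, "linked_mastoids")
  manual <- ep$data[1, 1, ] - (ep$data[1, 3, ] + ep$data[1, 4, ]) / 2
  expect_equal(lm_ref$data[1, 1, ], manual)
  expect_equal(eeg_rereference(lm_ref, "linked_mastoids")$data, lm_ref$data)
  ep2 <- epoched_eeg(data, 100, 0, c("a", "b", "c", "d"), "feedback")
  expect_error(eeg_rereference(ep2, "linked_mastoids"), "Mastoid")
})

test_that("cluster averaging is the samplewise mean of the listed channels", {
  set.seed(4)
  data <- array(rnorm(3 * 3 * 20), dim = c(3, 3, 20))
  data[, 2, ] <- data[, 1, ]               # identical pair
  ep <- epoched_eeg(data, 100, 0, c("x", "y", "z"), "go_cue")
  same <- cluster_average(ep, c("x", "y"))
  expect_equal(same$data[2, 1, ], data[2, 1, ])
  opp <- ep
  opp$data[, 2, ] <- -opp$data[, 1, ]      # opposite signs cancel
  expect_equal(max(abs(cluster_average(opp, c("x", "y"))$data)), 0)
  hand <- (data[1, 1, ] + data[1, 3, ]) / 2
  expect_equal(cluster_average(ep, c("x", "z"))$data[1, 1, ], hand)
  expect_error(cluster_average(ep, c("x", "nope")), "Unknown channel")
})

test_that("tf_power localises tones, scales quadratically, matches a periodogram", {
  ep <- make_sine_epochs(freqs = 10, amps = 1, srate = 250, n_trials = 2)
  tfr <- tf_power(ep)
  expect_equal(diff(tfr$times)[1], 0.1)
  expect_equal(tfr$freqs[which.max(rowMeans(tfr$power))], 10)
  ep2 <- make_sine_epochs(freqs = 10, amps = 2, srate = 250, n_trials = 2)
  tfr2 <- tf_power(ep2)
  i10 <- which(tfr$freqs == 10)
  expect_equal(mean(tfr2$power[i10, ]) / mean(tfr$power[i10, ]), 4,
               tolerance = 1e-6)
  # white noise: flat trial-averaged spectrum, level matching a direct
  # Hanning periodogram of the same segments
  ep_n <- make_sine_epochs(freqs = numeric(0), amps = numeric(0),
                           srate = 250, n_trials = 30, noise_sd = 1,
                           seed = 11)
  tfr_n <- tf_power(ep_n)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:249) / 250)
  seg <- ep_n$data[1, 1, 126:375] * w
  pd <- 2 * Mod(fft(seg))^2 / (250 * sum(w^2))
  i_mid <- which(tfr_n$freqs >= 20 & tfr_n$freqs <= 100)
  expect_equal(mean(tfr_n$power[i_mid, ]),
               mean(pd[seq_along(tfr_n$freqs)][i_mid]), tolerance = 0.3)
  expect_error(tf_power(epoched_eeg(array(0, c(1, 1, 100)), 250, 0, "c",
                                    "go_cue")),
               "too short|full analysis window")
})

test_that("the ERD map implements (R - A)/R x 100 with its guards", {
  tfr <- structure(list(power = matrix(2, 3, 21,
                                       dimnames = NULL),
                        freqs = c(5, 10, 15),
                        times = seq(-2.5, -0.5, 0.1), srate = 250,
                        n_trials = 1), class = "vmr_tfr")
  m <- erd_map(tfr, ref_window = c(-2, -1))
  expect_true(all(m$erd_pct == 0))
  tfr$power[, 15:21] <- 1                   # A = 0.5 R in late windows
  m2 <- erd_map(tfr, ref_window = c(-2.5, -1.6))
  expect_true(all(abs(m2$erd_pct[, 15:21] - 50) < 1e-12))
  # average ERD over the reference window is ~0 by construction
  ref_cols <- m2$times >= -2.5 & m2$times <= -1.6
  expect_equal(mean(m2$erd_pct[, ref_cols]), 0, tolerance = 1e-12)
  tfr$power[2, 1:10] <- 0
  expect_error(erd_map(tfr, ref_window = c(-2.5, -1.6)), "zero")
  expect_error(erd_map(erd_map <- structure(list(power = matrix(1, 2, 2),
                                                 freqs = 1:2,
                                                 times = c(0, 0.1)),
                                            class = "vmr_tfr"),
                       ref_window = c(-2, -1)), "not covered")
})

test_that("peak extraction takes the argmax then a truncated neighbourhood mean", {
  freqs <- 5:20
  times <- seq(-1.5, 0.5, 0.1)
  erd <- matrix(0, length(freqs), length(times))
  erd[freqs == 10, which.min(abs(times + 0.5))] <- 60
  m <- structure(list(erd_pct = erd, power = erd, freqs = freqs,
                      times = times, ref_power = rep(1, length(freqs)),
                      ref_window = c(-2, -1)), class = "vmr_erd_map")
  ft <- extract_peak_erd(m, band = c(8, 13))
  expect_equal(ft$peak_freq_hz, 10)
  expect_equal(ft$peak_time_s, -0.5)
  expect_equal(ft$value_pct, 60 / (5 * 5))  # single spike averaged over 5x5
  # constant map: the value equals the constant wherever the tie resolves
  m$erd_pct[] <- 7
  expect_equal(extract_peak_erd(m, band = c(8, 13))$value_pct, 7)
  # adding a constant moves the value, not the argmax location
  m2 <- m
  m2$erd_pct <- erd + 5
  ft2 <- extract_peak_erd(m2, band = c(8, 13))
  expect_equal(c(ft2$peak_freq_hz, ft2$peak_time_s), c(10, -0.5))
  # truncation: peak at the frequency edge of the map
  m3 <- m
  m3$erd_pct <- matrix(0, length(freqs), length(times))
  m3$erd_pct[1, 3] <- 50
  ft3 <- extract_peak_erd(m3, band = c(5, 8), search_window = c(-1.5, 0))
  expect_equal(ft3$peak_freq_hz, 5)
  expect_equal(ft3$value_pct, 50 / (3 * 5))  # only 3 freq rows available
  expect_error(extract_peak_erd(m, band = c(50, 60)), "Empty search region")
})

test_that("ERD is invariant to global amplitude scaling and near zero when stationary", {
  gt <- eeg_ground_truth(alpha_erd_pct = c(early = 0, late = 0),
                         beta_erd_pct = c(early = 0, late = 0))
  go <- generate_go_epochs(gt, "early", n_trials = 8, noise_sd_uv = 0.05,
                           seed = 13, srate = 250,
                           channels = c3_cluster(), cluster = c3_cluster())
  pooled <- cluster_average(go, c3_cluster())
  m <- erd_map(tf_power(pooled))
  in_band <- m$freqs >= 6 & m$freqs <= 32
  win <- m$times >= -1 & m$times <= 0
  expect_lt(max(abs(m$erd_pct[in_band, win])), 2)
  scaled <- pooled
  scaled$data <- scaled$data * 3.7
  m2 <- erd_map(tf_power(scaled))
  expect_equal(m2$erd_pct, m$erd_pct, tolerance = 1e-9)
})

test_that("trial-averaged power then ERD differs from per-trial ERD then averaging", {
  # two trials with different amplitudes: the implemented order weights
  # trials by power, the per-trial order weights ratios equally
  srate <- 250
  t <- -3 + (0:(7 * srate - 1)) / srate
  env <- ifelse(t > -1 & t < 0, sqrt(0.5), 1)
  mk <- function(amp) amp * sin(2 * pi * 10 * t) * env
  data <- array(0, dim = c(2, 1, length(t)))
  data[1, 1, ] <- mk(1)
  data[2, 1, ] <- mk(3)
  ep <- epoched_eeg(data, srate, -3, "cluster", "go_cue")
  m <- erd_map(tf_power(ep))
  i10 <- which(m$freqs == 10)
  j <- which.min(abs(m$times + 0.5))
  implemented <- m$erd_pct[i10, j]
  per_trial <- mean(vapply(1:2, function(tr) {
    epi <- epoched_eeg(data[tr, , , drop = FALSE], srate, -3, "cluster",
                       "go_cue")
    mi <- erd_map(tf_power(epi))
    mi$erd_pct[i10, j]
  }, numeric(1)))
  expect_equal(implemented, 50, tolerance = 2)
  expect_equal(per_trial, 50, tolerance = 2)
  # equal-amplitude check that the orders genuinely differ
  data[2, 1, ] <- mk(3) + 0.5 * sin(2 * pi * 10 * t)  # trial with less ERD
  ep2 <- epoched_eeg(data, srate, -3, "cluster", "go_cue")
  m2 <- erd_map(tf_power(ep2))
  imp2 <- m2$erd_pct[i10, j]
  pt2 <- mean(vapply(1:2, function(tr) {
    epi <- epoched_eeg(data[tr, , , drop = FALSE], srate, -3, "cluster",
                       "go_cue")
    erd_map(tf_power(epi))$erd_pct[i10, j]
  }, numeric(1)))
  expect_gt(abs(imp2 - pt2), 0.5)
})
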