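test_that("epoch containers respect the timing contracts", {
  gt <- eeg_ground_truth()
  go <- generate_go_epochs(gt, "early", n_trials = 2, noise_sd_uv = 0.1,
                           seed = 1, srate = 200)
  expect_equal(dim(go$data)[3], 7 * 200)        # 7 s epochs
  expect_equal(range(epoch_times(go)), c(-3, 4 - 1 / 200))
  fb <- generate_feedback_epochs(gt, c("success", "failure"), "early",
                                 noise_sd_uv = 0.1, seed = 1, srate = 200)
  expect_equal(dim(fb$data)[3], 0.8 * 200)      # 0.8 s epochs
  expect_equal(range(epoch_times(fb)), c(-0.2, 0.6 - 1 / 200))
  expect_error(eeg_ground_truth(alpha_erd_pct = c(early = 120, late = 50)),
               "exceed 100")
  expect_error(generate_feedback_epochs(gt, c("success", "success"), "early"),
               "Both outcome classes")
})

test_that("binary container write / read round-trips data and metadata", {
  gt <- eeg_ground_truth()
  fb <- generate_feedback_epochs(gt, rep(c("success", "failure"), 3), "late",
                                 noise_sd_uv = 1, seed = 9, srate = 200)
  pre <- file.path(withr::local_tempdir(), "ep")
  write_epochs(fb, pre)
  back <- read_epochs(pre)
  expect_equal(back$data, fb$data, tolerance = 1e-6)  # float32 storage
  expect_identical(back$channels, fb$channels)
  expect_identical(back$trial_labels, fb$trial_labels)
  expect_equal(back$srate, fb$srate)
  expect_equal(back$t0_offset_s, fb$t0_offset_s)
})

test_that("planted ERD scales in-band preparatory power as 1 - ERD/100", {
  gt <- eeg_ground_truth(alpha_erd_pct = c(early = 80, late = 100),
                         beta_erd_pct = c(early = 80, late = 100))
  # eight trials so the generator's carrier-shift scheme cancels window
  # leakage interference in trial-averaged power
  go <- generate_go_epochs(gt, "early", n_trials = 8, noise_sd_uv = 0,
                           seed = 4, srate = 250, erd_taper_pct_per_hz = 0)
  t <- epoch_times(go)
  ch <- match("C3", go$channels)
  # trial-averaged one-sided Hann periodogram band power of a 1 s segment
  band_pow <- function(ep, sel, lo, hi) {
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(sum(sel) - 1)) / sum(sel))
    mean(vapply(seq_len(dim(ep$data)[1]), function(tr) {
      p <- Mod(fft(ep$data[tr, ch, sel] * w))^2
      sum(p[(lo:hi) + 1])
    }, numeric(1)))
  }
  ref <- t >= -2 & t < -1
  prep <- t >= -0.6 & t < 0.4              # fully suppressed plateau
  # bins adjacent to the stationary 14 Hz buffer component (13, 15) pick
  # up its unmodulated leakage, so the clean ratio is read off the bins
  # driven purely by the modulated combs
  expect_equal(band_pow(go, prep, 8, 12) / band_pow(go, ref, 8, 12), 0.2,
               tolerance = 0.02)
  expect_equal(band_pow(go, prep, 16, 30) / band_pow(go, ref, 16, 30), 0.2,
               tolerance = 0.02)
  # 100 % ERD: the in-band preparatory oscillation is fully suppressed
  go2 <- generate_go_epochs(gt, "late", n_trials = 8, noise_sd_uv = 0,
                            seed = 4, srate = 250, erd_taper_pct_per_hz = 0)
  expect_lt(band_pow(go2, prep, 8, 12) / band_pow(go2, ref, 8, 12), 1e-3)
  # non-cluster channels carry background only (none here)
  expect_equal(var(go$data[1, match("Oz", go$channels), ]), 0)
})

test_that("the planted difference wave has the stated windowed mean and clean baseline", {
  gt <- eeg_ground_truth(frn_uv = c(early = -3, late = 0))
  labs <- rep(c("success", "failure"), each = 8)
  fb <- generate_feedback_epochs(gt, labs, "early", noise_sd_uv = 0,
                                 seed = 2, srate = 250)
  t <- epoch_times(fb)
  ch <- match("FCz", fb$channels)
  s <- colMeans(fb$data[labs == "success", ch, ])
  f <- colMeans(fb$data[labs == "failure", ch, ])
  d <- s - f
  expect_equal(mean(d[t >= 0.2 & t <= 0.35]), -3, tolerance = 1e-9)
  expect_lt(max(abs(d[t < 0])), 1e-6)          # baseline interval clean
  # zero planted amplitude: flat difference wave
  fb0 <- generate_feedback_epochs(gt, labs, "late", noise_sd_uv = 0,
                                  seed = 2, srate = 250)
  d0 <- colMeans(fb0$data[labs == "success", ch, ]) -
    colMeans(fb0$data[labs == "failure", ch, ])
  expect_lt(max(abs(d0)), 1e-9)
})

test_that("noiseless fixtures round-trip through the extractors", {
  gt <- eeg_ground_truth(alpha_erd_pct = c(early = 50, late = 80),
                         beta_erd_pct = c(early = 50, late = 80),
                         frn_uv = c(early = -3, late = -1))
  go <- generate_go_epochs(gt, "late", n_trials = 16, noise_sd_uv = 0.05,
                           seed = 6, srate = 250)
  erd <- extract_erd_features(go)
  expect_equal(erd$value_pct, c(80, 80), tolerance = 0.025)
  labs <- rep(c("success", "failure"), 8)
  fb <- generate_feedback_epochs(gt, labs, "early", noise_sd_uv = 0,
                                 seed = 6, srate = 250)
  expect_equal(extract_frn_feature(fb), -3, tolerance = 0.1)
})

test_that("FRN recovery error shrinks with the number of trials", {
  gt <- eeg_ground_truth(frn_uv = c(early = -3, late = -3))
  chans <- c(fcz_cluster(), mastoid_channels())
  err <- function(n_trials, seed) {
    labs <- rep(c("success", "failure"), n_trials / 2)
    fb <- generate_feedback_epochs(gt, labs, "early", noise_sd_uv = 4,
                                   seed = seed, srate = 250,
                                   channels = chans)
    abs(extract_frn_feature(fb) + 3)
  }
  e_small <- vapply(1:10, function(s) err(8L, s), numeric(1))
  e_large <- vapply(1:10, function(s) err(48L, s), numeric(1))
  expect_lt(mean(e_large), mean(e_small))
})
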