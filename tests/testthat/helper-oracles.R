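# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit sums, closed forms) so they cannot share a
# code path with the implementations they check.

# Two-way mixed ANOVA by direct sums of squares, balanced groups only.
oracle_mixed_anova <- function(y, id, w, b) {
  id <- as.character(id); w <- as.character(w); b <- as.character(b)
  ids <- unique(id); ws <- sort(unique(w)); bs <- sort(unique(b))
  n <- length(ids); k <- length(ws); g <- length(bs)
  grand <- mean(y)
  subj_mean <- sapply(ids, function(i) mean(y[id == i]))
  grp_of <- sapply(ids, function(i) b[id == i][1])
  grp_mean <- sapply(bs, function(gr) mean(subj_mean[grp_of == gr]))
  n_g <- sapply(bs, function(gr) sum(grp_of == gr))

  ss_b <- k * sum(n_g * (grp_mean - grand)^2)
  ss_subj <- k * sum((subj_mean - grp_mean[match(grp_of, bs)])^2)

  w_mean <- sapply(ws, function(l) mean(y[w == l]))
  ss_w <- n * sum((w_mean - grand)^2)

  cell <- outer(bs, ws, Vectorize(function(gr, l) mean(y[b == gr & w == l])))
  ss_cells <- sum(rep(n_g, k) * (as.vector(cell) -
    rep(grp_mean, k) - rep(w_mean, each = g) + grand)^2)

  ss_tot_within <- sum((y - subj_mean[match(id, ids)])^2)
  ss_err <- ss_tot_within - ss_w - ss_cells
  list(
    F = c(
      between = (ss_b / (g - 1)) / (ss_subj / (n - g)),
      within = (ss_w / (k - 1)) / (ss_err / ((n - g) * (k - 1))),
      interaction = (ss_cells / ((g - 1) * (k - 1))) /
        (ss_err / ((n - g) * (k - 1)))
    ),
    ss = c(ss_b, ss_w, ss_cells)
  )
}

# Greenhouse-Geisser epsilon from the double-centered covariance.
oracle_gg_epsilon <- function(Y) {
  S <- cov(Y)
  k <- ncol(S)
  Sc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

# Holm step-down adjustment written out longhand.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Pooled-variance two-sample t statistic and p by the textbook formula.
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Regression power by direct noncentral-F CDF evaluation.
oracle_regression_power <- function(n, p, f2, alpha = 0.05) {
  crit <- qf(1 - alpha, p, n - p - 1)
  1 - pf(crit, p, n - p - 1, ncp = f2 * n)
}

# A minimal stationary test epoch set: single channel, sum of sinusoids.
make_sine_epochs <- function(freqs, amps, srate = 250, n_trials = 4,
                             dur = 7, t0 = -3, noise_sd = 0,
                             event_kind = "go_cue", seed = 1) {
  n_samp <- dur * srate
  t <- t0 + (seq_len(n_samp) - 1) / srate
  set.seed(seed)
  data <- array(0, dim = c(n_trials, 1, n_samp))
  for (tr in seq_len(n_trials)) {
    x <- rnorm(n_samp, 0, noise_sd)
    for (i in seq_along(freqs)) x <- x + amps[i] * sin(2 * pi * freqs[i] * t)
    data[tr, 1, ] <- x
  }
  epoched_eeg(data, srate = srate, t0_offset_s = t0, channels = "cluster",
              event_kind = event_kind)
}
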