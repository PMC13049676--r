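#' Extract alpha and beta peak ERD features from go-cue epochs
#'
#' Full sensorimotor ERD chain for one epoch set: band-pass 1-60 Hz,
#' common-average reference, average over the C3-centered cluster,
#' sliding-window Hanning spectrogram, ERD map against the -2 to -1 s
#' reference, and peak ERD (with +/-0.2 s x +/-2 Hz averaging) in the
#' preparatory window for the alpha (8-13 Hz) and beta (15-30 Hz) bands.
#'
#' @param epochs A go-cue-locked [epoched_eeg()].
#' @param cluster Sensorimotor cluster labels.
#' @param bandpass Length-2 band edges for the pre-filter, Hz.
#' @param ref_window,search_window ERD reference and peak-search windows, s.
#' @param bands Named list of band edges.
#' @return A tibble with one row per band: `band`, `value_pct`,
#'   `peak_time_s`, `peak_freq_hz`.
#' @export
extract_erd_features <- function(epochs, cluster = c3_cluster(),
                                 bandpass = c(1, 60),
                                 ref_window = c(-2, -1),
                                 search_window = c(-1, 0),
                                 bands = list(alpha = c(8, 13),
                                              beta = c(15, 30))) {
  x <- eeg_bandpass(epochs, bandpass[1], bandpass[2])
  x <- eeg_rereference(x, "common_average")
  x <- cluster_average(x, cluster)
  map <- erd_map(tf_power(x), ref_window = ref_window)
  purrr::imap_dfr(bands, function(b, nm) {
    ft <- extract_peak_erd(map, band = b, search_window = search_window)
    tibble::tibble(band = nm, value_pct = ft$value_pct,
                   peak_time_s = ft$peak_time_s, peak_freq_hz = ft$peak_freq_hz)
  })
}

#' Extract the FRN amplitude from feedback epochs
#'
#' Full FRN chain for one epoch set: band-pass 0.1-30 Hz, linked-mastoid
#' reference, average over the fronto-central cluster, baseline correction
#' over the 200 ms before feedback, condition-wise ERPs, and the mean of
#' the success-minus-failure difference wave in the 200-350 ms window.
#'
#' @param epochs A feedback-locked [epoched_eeg()] with outcome trial
#'   labels (or `labels` supplied).
#' @param cluster Fronto-central cluster labels.
#' @param bandpass Length-2 band edges, Hz; `NULL` skips filtering.
#' @param labels Optional per-trial outcome labels.
#' @param rereference Apply the linked-mastoid reference (disable for
#'   montages without mastoids).
#' @return FRN amplitude in microvolts.
#' @export
extract_frn_feature <- function(epochs, cluster = fcz_cluster(),
                                bandpass = c(0.1, 30), labels = NULL,
                                rereference = TRUE) {
  x <- epochs
  if (!is.null(bandpass)) x <- eeg_bandpass(x, bandpass[1], bandpass[2])
  if (rereference) x <- eeg_rereference(x, "linked_mastoids")
  x <- cluster_average(x, cluster)
  x <- baseline_correct(x, c(-0.2, 0))
  frn_amplitude(condition_erps(x, labels = labels))
}

#' Assemble the cohort feature table for regression
#'
#' Takes per-participant features and outcomes, codes the feedback
#' condition numerically (reward = 1, punishment = 0) and appends the
#' condition-by-feature interaction columns, giving the 13-column design
#' (condition + 6 EEG features + 6 interactions) used by the Lasso step.
#'
#' @param features A tibble with columns `id`, `condition`
#'   (`"reward"` / `"punishment"`), `frn_early`, `frn_late`,
#'   `alpha_erd_early`, `alpha_erd_late`, `beta_erd_early`,
#'   `beta_erd_late`, `learning_pct`, `retention_pct` (e.g. from
#'   [simulate_cohort()] or [run_features()]).
#' @return A tibble with `id`, outcomes, `condition` (0/1) and the 12
#'   feature/interaction predictor columns.
#' @export
cohort_feature_table <- function(features) {
  eeg_cols <- c("frn_early", "frn_late", "alpha_erd_early", "alpha_erd_late",
                "beta_erd_early", "beta_erd_late")
  need <- c("id", "condition", eeg_cols, "learning_pct", "retention_pct")
  miss <- setdiff(need, names(features))
  if (length(miss)) {
    abort(paste0("Missing feature column(s): ", paste(miss, collapse = ", ")))
  }
  out <- tibble::tibble(
    id = features$id,
    learning_pct = features$learning_pct,
    retention_pct = features$retention_pct,
    condition = as.numeric(features$condition == "reward")
  )
  for (col in eeg_cols) out[[col]] <- features[[col]]
  for (col in eeg_cols) {
    out[[paste0("condition_x_", col)]] <- out$condition * out[[col]]
  }
  out
}

#' Predictor column names of a cohort feature table
#' @return Character vector of the 13 regressor names.
#' @export
feature_predictors <- function() {
  eeg_cols <- c("frn_early", "frn_late", "alpha_erd_early", "alpha_erd_late",
                "beta_erd_early", "beta_erd_late")
  c("condition", eeg_cols, paste0("condition_x_", eeg_cols))
}

#' Lasso-then-OLS fit of individual differences
#'
#' The two-stage inference chain linking EEG features to a behavioral
#' outcome: rows with any missing predictor or outcome are dropped
#' listwise, the 13-column design (condition, six EEG features, six
#' condition-by-feature interactions) is cross-validated through the Lasso
#' with the 1SE rule, and the selected regressors are refit by OLS on
#' their original scale for inference.
#'
#' @param features A feature table (see [cohort_feature_table()]; raw
#'   tables with a character `condition` column are converted
#'   automatically).
#' @param outcome `"retention_pct"` or `"learning_pct"`.
#' @param k CV folds.
#' @param seed Fold-assignment seed.
#' @return An object of class `vmr_idfit`: `lasso` ([cv_lasso_1se()]
#'   result), `ols` ([ols_final()] result), `outcome`, `n_used`,
#'   `n_dropped`.
#' @export
individual_differences_fit <- function(features,
                                       outcome = c("retention_pct",
                                                   "learning_pct"),
                                       k = 5, seed = NULL) {
  outcome <- match.arg(outcome)
  tab <- if (is.character(features$condition) ||
             is.factor(features$condition)) {
    cohort_feature_table(features)
  } else {
    features
  }
  preds <- feature_predictors()
  keep <- complete.cases(tab[, c(preds, outcome)])
  tab <- tab[keep, ]
  X <- as.matrix(tab[, preds])
  y <- tab[[outcome]]
  lasso <- cv_lasso_1se(X, y, k = min(k, nrow(X)), seed = seed)
  ols <- ols_final(X, y, selected = lasso$selected)
  structure(list(lasso = lasso, ols = ols, outcome = outcome,
                 n_used = sum(keep), n_dropped = sum(!keep)),
            class = "vmr_idfit")
}

#' @method print vmr_idfit
#' @export
print.vmr_idfit <- function(x, ...) {
  cat(sprintf("Individual-differences fit for %s (n = %d, %d dropped)\n",
              x$outcome, x$n_used, x$n_dropped))
  print(x$lasso)
  print(x$ols)
  invisible(x)
}

#' @method tidy vmr_idfit
#' @export
tidy.vmr_idfit <- function(x, ...) tidy(x$ols)

#' @method glance vmr_idfit
#' @export
glance.vmr_idfit <- function(x, ...) {
  dplyr::bind_cols(glance(x$ols), glance(x$lasso))
}
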