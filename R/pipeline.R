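#' Pipeline run configuration
#'
#' Bundles every knob of a simulate -> features -> stats run: cohort size,
#' master seed, the planted effect, EEG fixture parameters and the output
#' directory. A resolved copy of the configuration is written next to the
#' outputs of every stage, and identical config + seed gives identical
#' outputs.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; all stage-level seeds derive from it.
#' @param n_per_group Participants per condition.
#' @param eeg Generate and analyse epoched EEG (set `FALSE` for a
#'   behavior-only run that uses the feature-level cohort columns).
#' @param srate EEG sampling rate, Hz.
#' @param n_go_trials,n_fb_trials Epochs per phase for the go-cue and
#'   feedback fixtures.
#' @param noise_sd_uv SD of the 1/f EEG background, microvolts.
#' @param effect A [cohort_effect()].
#' @return A list of class `vmr_config`.
#' @export
run_config <- function(out_dir = file.path(tempdir(), "vmrlearn-run"),
                       seed = 1, n_per_group = 32, eeg = TRUE,
                       srate = 1000, n_go_trials = 30, n_fb_trials = 60,
                       noise_sd_uv = 1, effect = cohort_effect()) {
  stopifnot(inherits(effect, "vmr_effect"))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_per_group = as.integer(n_per_group), eeg = isTRUE(eeg),
                 srate = srate, n_go_trials = as.integer(n_go_trials),
                 n_fb_trials = as.integer(n_fb_trials),
                 noise_sd_uv = noise_sd_uv, effect = effect),
            class = "vmr_config")
}

#' @rdname run_config
#' @param config A `vmr_config`.
#' @param path File path for the key-value (YAML) serialization.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "vmr_config"))
  lst <- unclass(config)
  lst$effect <- unclass(lst$effect)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  eff <- lst$effect
  pair <- function(x) {
    v <- unlist(x)
    if (is.null(names(v))) names(v) <- c("early", "late")
    v
  }
  eff$alpha_erd_mean <- pair(eff$alpha_erd_mean)
  eff$beta_erd_mean <- pair(eff$beta_erd_mean)
  eff$frn_mean <- pair(eff$frn_mean)
  lst$effect <- do.call(cohort_effect, eff)
  do.call(run_config, lst)
}

# Deterministic sub-seeds for the pipeline stages.
stage_seed_ <- function(config, offset) (config$seed * 1000L + offset) %% .Machine$integer.max

ensure_both_classes_ <- function(labs) {
  if (length(unique(labs)) >= 2) return(labs)
  message("Single-class outcome labels in a phase; inserting minority trials.")
  labs[seq(1, length(labs), by = 4)] <-
    if (labs[1] == "success") "failure" else "success"
  labs
}

#' Simulate a cohort and write behavior tables and EEG containers
#'
#' Stage 1 of the pipeline. Writes `trials.csv` (one row per trial per
#' participant), `cohort.csv` (ground truth, measured features, outcomes)
#' and, when `config$eeg` is `TRUE`, one binary+JSON epoch container per
#' participant, phase and event kind under `eeg/`. The feedback-epoch
#' outcome labels come from the participant's own simulated points.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `cohort` (tibble) and `dir`.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "vmr_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(config$out_dir, "config.yaml"))

  cohort <- simulate_cohort(config$n_per_group, config$effect,
                            seed = stage_seed_(config, 1L))
  trials <- dplyr::bind_rows(
    setNames(cohort$trials, cohort$id), .id = "id"
  )
  readr::write_csv(trials, file.path(config$out_dir, "trials.csv"))
  readr::write_csv(dplyr::select(cohort, -"trials"),
                   file.path(config$out_dir, "cohort.csv"))

  if (config$eeg) {
    eeg_dir <- file.path(config$out_dir, "eeg")
    dir.create(eeg_dir, showWarnings = FALSE)
    phases <- phase_definition()
    for (i in seq_len(nrow(cohort))) {
      gt <- eeg_ground_truth(
        alpha_erd_pct = c(early = cohort$gt_alpha_erd_early[i],
                          late = cohort$gt_alpha_erd_late[i]),
        beta_erd_pct = c(early = cohort$gt_beta_erd_early[i],
                         late = cohort$gt_beta_erd_late[i]),
        frn_uv = c(early = cohort$gt_frn_early[i],
                   late = cohort$gt_frn_late[i])
      )
      tr <- cohort$trials[[i]]
      for (ph in c("early", "late")) {
        sd_go <- stage_seed_(config, 100L + 4L * i + (ph == "late"))
        go <- generate_go_epochs(gt, phase = ph,
                                 n_trials = config$n_go_trials,
                                 noise_sd_uv = config$noise_sd_uv,
                                 seed = sd_go, srate = config$srate)
        write_epochs(go, file.path(eeg_dir,
                                   sprintf("%s_go_%s", cohort$id[i], ph)))

        rng <- phases[[paste0(ph, "_adapt")]]
        pts <- tr$points[tr$trial %in% rng]
        pts <- pts[seq_len(min(config$n_fb_trials, length(pts)))]
        labs <- as.character(classify_outcome(pts, cohort$condition[i]))
        labs <- ensure_both_classes_(labs)
        fb <- generate_feedback_epochs(gt, labs, phase = ph,
                                       noise_sd_uv = config$noise_sd_uv,
                                       seed = sd_go + 7L,
                                       srate = config$srate)
        write_epochs(fb, file.path(eeg_dir,
                                   sprintf("%s_fb_%s", cohort$id[i], ph)))
      }
    }
  }
  invisible(list(cohort = cohort, dir = config$out_dir))
}

#' Extract per-participant EEG features into the cohort feature table
#'
#' Stage 2. Reads the epoch containers written by [run_simulate()], runs
#' the ERD and FRN extraction chains for both adaptation phases, applies
#' the group-level +/-2SD outlier rule to the FRN features (separately per
#' phase, pooled across conditions; flagged values become `NA`), joins the
#' behavioral outcomes, and writes `features.csv`.
#'
#' @param config A [run_config()].
#' @return The feature tibble (one row per participant).
#' @export
run_features <- function(config) {
  stopifnot(inherits(config, "vmr_config"))
  cohort <- readr::read_csv(file.path(config$out_dir, "cohort.csv"),
                            show_col_types = FALSE)
  if (!config$eeg) {
    feats <- dplyr::select(
      cohort, "id", "condition",
      dplyr::all_of(c("frn_early", "frn_late", "alpha_erd_early",
                      "alpha_erd_late", "beta_erd_early", "beta_erd_late",
                      "learning_pct", "retention_pct", "total_score"))
    )
    readr::write_csv(feats, file.path(config$out_dir, "features.csv"))
    return(feats)
  }

  eeg_dir <- file.path(config$out_dir, "eeg")
  rows <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    id <- cohort$id[i]
    out <- list(id = id, condition = cohort$condition[i])
    for (ph in c("early", "late")) {
      go <- read_epochs(file.path(eeg_dir, sprintf("%s_go_%s", id, ph)))
      erd <- extract_erd_features(go)
      out[[paste0("alpha_erd_", ph)]] <-
        erd$value_pct[erd$band == "alpha"]
      out[[paste0("beta_erd_", ph)]] <- erd$value_pct[erd$band == "beta"]
      fb <- read_epochs(file.path(eeg_dir, sprintf("%s_fb_%s", id, ph)))
      out[[paste0("frn_", ph)]] <- extract_frn_feature(fb)
    }
    tibble::as_tibble(out)
  })

  for (ph in c("early", "late")) {
    col <- paste0("frn_", ph)
    keep <- exclude_outliers(rows[[col]])
    rows[[paste0(col, "_outlier")]] <- keep %in% FALSE
    rows[[col]][keep %in% FALSE] <- NA
  }

  feats <- dplyr::left_join(
    rows,
    dplyr::select(cohort, "id", "learning_pct", "retention_pct",
                  "total_score"),
    by = "id"
  )
  readr::write_csv(feats, file.path(config$out_dir, "features.csv"))
  feats
}

#' Run the statistical layer and write results
#'
#' Stage 3. Reproduces the inference chain on the simulated cohort: the
#' four-phase mixed ANOVA on reach direction with Greenhouse-Geisser
#' handling and Holm post hocs, the independent t test on total scores,
#' 2 x 2 mixed ANOVAs on the alpha/beta ERD and FRN features, the
#' Lasso-1SE + OLS individual-differences fits for learning and retention,
#' and the a-priori power numbers. Writes `results.json` and a plain-text
#' `report.txt` whose every number is a JSON field.
#'
#' @param config A [run_config()].
#' @return An object of class `vmr_results` (the results list).
#' @export
run_stats <- function(config) {
  stopifnot(inherits(config, "vmr_config"))
  trials <- readr::read_csv(file.path(config$out_dir, "trials.csv"),
                            show_col_types = FALSE)
  feats <- readr::read_csv(file.path(config$out_dir, "features.csv"),
                           show_col_types = FALSE)

  # behavior: four-phase ANOVA on per-participant mean reach direction
  pm <- trials |>
    dplyr::group_by(.data$id, .data$condition) |>
    dplyr::group_modify(~ phase_means(.x)) |>
    dplyr::ungroup()
  beh_anova <- mixed_anova(pm, dv = "mean_theta_deg", within = "phase",
                           between = "condition", id = "id")
  posthoc <- posthoc_between_at_levels(pm, dv = "mean_theta_deg",
                                       within = "phase",
                                       between = "condition", id = "id")
  scores <- feats |> dplyr::distinct(.data$id, .data$condition, .data$total_score)
  ttest <- independent_t(scores$total_score[scores$condition == "reward"],
                         scores$total_score[scores$condition == "punishment"])

  eeg_anova <- function(early, late) {
    long <- feats |>
      dplyr::select("id", "condition", early = dplyr::all_of(early),
                    late = dplyr::all_of(late)) |>
      tidyr::pivot_longer(c("early", "late"), names_to = "time") |>
      dplyr::filter(!is.na(.data$value))
    mixed_anova(long, dv = "value", within = "time",
                between = "condition", id = "id")
  }
  alpha_anova <- eeg_anova("alpha_erd_early", "alpha_erd_late")
  beta_anova <- eeg_anova("beta_erd_early", "beta_erd_late")
  frn_anova <- eeg_anova("frn_early", "frn_late")

  fit_ret <- individual_differences_fit(feats, "retention_pct",
                                        seed = stage_seed_(config, 2L))
  fit_lrn <- individual_differences_fit(feats, "learning_pct",
                                        seed = stage_seed_(config, 3L))

  res <- list(
    behavior = list(anova = as.data.frame(beh_anova$table),
                    mauchly_p = beh_anova$mauchly_p,
                    epsilon_gg = beh_anova$epsilon_gg,
                    posthoc = as.data.frame(posthoc),
                    total_score_t = as.data.frame(ttest)),
    erd = list(alpha = as.data.frame(alpha_anova$table),
               alpha_n = alpha_anova$n_subjects,
               beta = as.data.frame(beta_anova$table),
               beta_n = beta_anova$n_subjects),
    frn = list(anova = as.data.frame(frn_anova$table),
               n = frn_anova$n_subjects),
    retention_fit = list(selected = fit_ret$lasso$selected,
                         coefficients = as.data.frame(tidy(fit_ret)),
                         r2_adj = fit_ret$ols$r2_adj,
                         n = fit_ret$n_used),
    learning_fit = list(selected = fit_lrn$lasso$selected,
                        coefficients = as.data.frame(tidy(fit_lrn)),
                        r2_adj = fit_lrn$ols$r2_adj,
                        n = fit_lrn$n_used),
    power = list(f2 = f2_from_r2(0.25),
                 required_n = power_regression_n(7, 0.33, 0.05, 0.80))
  )
  jsonlite::write_json(res, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  rep_path <- file.path(config$out_dir, "report.txt")
  con <- file(rep_path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("vmrlearn pipeline report")
  w("========================")
  ia <- beh_anova$table[3, ]
  w("Behavior phase x condition: F(%.2f, %.2f) = %.2f, p = %.4g",
    ia$df1, ia$df2, ia$F, ia$p)
  w("Total score t test: t(%d) = %.2f, p = %.4g",
    as.integer(ttest$df), ttest$statistic, ttest$p.value)
  w("Alpha ERD time main effect: F(%g, %g) = %.2f, p = %.4g (n = %d)",
    alpha_anova$table$df1[2], alpha_anova$table$df2[2],
    alpha_anova$table$F[2], alpha_anova$table$p[2], alpha_anova$n_subjects)
  w("Beta ERD time main effect: F(%g, %g) = %.2f, p = %.4g (n = %d)",
    beta_anova$table$df1[2], beta_anova$table$df2[2],
    beta_anova$table$F[2], beta_anova$table$p[2], beta_anova$n_subjects)
  w("FRN time main effect: F(%g, %g) = %.2f, p = %.4g (n = %d)",
    frn_anova$table$df1[2], frn_anova$table$df2[2],
    frn_anova$table$F[2], frn_anova$table$p[2], frn_anova$n_subjects)
  w("Retention fit (n = %d): selected [%s], adj R2 = %.3f",
    fit_ret$n_used, paste(fit_ret$lasso$selected, collapse = ", "),
    fit_ret$ols$r2_adj)
  w("Learning fit (n = %d): selected [%s], adj R2 = %.3f",
    fit_lrn$n_used, paste(fit_lrn$lasso$selected, collapse = ", "),
    fit_lrn$ols$r2_adj)
  w("Power analysis: f2 = %.4f, required N = %d",
    res$power$f2, res$power$required_n)

  structure(res, class = "vmr_results")
}

#' Run the full pipeline
#'
#' [run_simulate()], [run_features()] and [run_stats()] back to back.
#'
#' @param config A [run_config()].
#' @return The [run_stats()] results object.
#' @export
run_pipeline <- function(config) {
  run_simulate(config)
  run_features(config)
  run_stats(config)
}
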