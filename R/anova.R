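#' Mauchly's sphericity test and Greenhouse-Geisser epsilon
#'
#' Both statistics are computed from the covariance of the within-subject
#' measurements, projected onto an orthonormal contrast basis. With a
#' grouping factor the covariance is pooled within groups (error df
#' `N - g`). Mauchly's `W` is referred to a chi-square with the Box
#' correction factor; the Greenhouse-Geisser epsilon is
#' `(sum lambda)^2 / (d * sum lambda^2)` over the eigenvalues of the
#' contrast-projected covariance, which lies in `[1/(k-1), 1]` and equals 1
#' exactly when the within factor has two levels.
#'
#' @param within_data Numeric matrix, participants x within-levels.
#' @param group Optional factor (length = rows) for pooling the covariance
#'   within groups.
#' @return A list: `W`, `chisq`, `df`, `p`, `epsilon_gg`, `k`, `n_error_df`.
#'   With `k = 2` the test is not applicable (`W`, `p` are `NA`) and
#'   epsilon is exactly 1.
#' @export
mauchly_gg <- function(within_data, group = NULL) {
  Y <- as.matrix(within_data)
  k <- ncol(Y)
  n <- nrow(Y)
  if (k < 2) abort("Need at least 2 within-subject levels.")
  d <- k - 1

  if (is.null(group)) {
    S <- stats::cov(Y)
    n_err <- n - 1
  } else {
    group <- factor(group)
    g <- nlevels(group)
    S <- matrix(0, k, k)
    for (lev in levels(group)) {
      Yg <- Y[group == lev, , drop = FALSE]
      if (nrow(Yg) > 1) S <- S + (nrow(Yg) - 1) * stats::cov(Yg)
    }
    n_err <- n - g
    S <- S / n_err
  }

  # orthonormal contrast basis
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  Sc <- t(C) %*% S %*% C
  lam <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  eps <- if (sum(lam^2) == 0) 1 else sum(lam)^2 / (d * sum(lam^2))
  eps <- clamp_(eps, 1 / d, 1)

  if (k == 2) {
    return(list(W = NA_real_, chisq = NA_real_, df = NA_real_, p = NA_real_,
                epsilon_gg = 1, k = k, n_error_df = n_err))
  }

  detSc <- det(Sc)
  W <- if (detSc <= 0) 0 else detSc / (sum(diag(Sc)) / d)^d
  df <- d * (d + 1) / 2 - 1
  # Box correction factor for the chi-square approximation
  rho <- 1 - (2 * d^2 + d + 2) / (6 * d * n_err)
  chisq <- if (W <= 0) Inf else -rho * n_err * log(W)
  p <- pchisq(chisq, df, lower.tail = FALSE)
  list(W = W, chisq = chisq, df = df, p = p, epsilon_gg = eps, k = k,
       n_error_df = n_err)
}

#' Two-way mixed ANOVA with sphericity handling
#'
#' Repeated-measures ANOVA with one within-subject factor (e.g. task phase)
#' and one between-subjects factor (e.g. feedback condition). Participants
#' missing any within level are dropped listwise (with a message). When the
#' within factor has more than two levels, Mauchly's test is run on the
#' pooled within-group covariance; if it rejects at `alpha`, the
#' Greenhouse-Geisser correction multiplies the degrees of freedom of the
#' within-subject effects by epsilon and the p-values are recomputed
#' (`sphericity = "auto"`, the default; `"always"` and `"never"` force the
#' behaviour).
#'
#' @param data Long-format data frame.
#' @param dv,within,between,id Column names (strings) of the value, the
#'   within factor, the between factor, and the participant identifier.
#' @param sphericity `"auto"`, `"never"` or `"always"`.
#' @param alpha Significance level of Mauchly's test used by `"auto"`.
#' @return An object of class `vmr_anova`: a results tibble (`effect`,
#'   `df1`, `df2`, `ss`, `ms`, `F`, `p`, `gg_corrected`) plus `mauchly_w`,
#'   `mauchly_p`, `epsilon_gg`, `n_subjects`, `n_dropped`.
#' @examples
#' set.seed(1)
#' df <- tidyr::expand_grid(id = paste0("s", 1:12), phase = c("a", "b"))
#' df$grp <- rep(c("x", "y"), each = 12)
#' df$y <- rnorm(nrow(df))
#' mixed_anova(df, dv = "y", within = "phase", between = "grp", id = "id")
#' @export
mixed_anova <- function(data, dv, within, between, id,
                        sphericity = c("auto", "never", "always"),
                        alpha = 0.05) {
  sphericity <- match.arg(sphericity)
  df <- tibble::tibble(
    id = factor(data[[id]]),
    w = factor(data[[within]]),
    b = factor(data[[between]]),
    y = as.numeric(data[[dv]])
  )
  df <- df[complete.cases(df), ]
  k <- nlevels(df$w)

  counts <- table(df$id, df$w)
  complete <- rownames(counts)[apply(counts, 1, function(r) all(r == 1))]
  n_dropped <- nlevels(df$id) - length(complete)
  if (n_dropped > 0) {
    message(n_dropped, " participant(s) dropped: missing within-subject levels.")
  }
  df <- df[df$id %in% complete, ]
  df$id <- droplevels(df$id)
  df$b <- droplevels(df$b)
  n <- nlevels(df$id)
  g <- nlevels(df$b)
  if (n < 3 || g < 2) abort("Need >= 3 complete participants and >= 2 groups.")

  # between-subjects stratum, from per-participant means
  subj <- df |>
    dplyr::group_by(.data$id, .data$b) |>
    dplyr::summarise(m = mean(.data$y), .groups = "drop")
  grand <- mean(df$y)
  grp_means <- tapply(subj$m, subj$b, mean)
  n_g <- table(subj$b)
  ss_between <- k * sum(n_g * (grp_means - grand)^2)
  ss_subj <- k * sum((subj$m - grp_means[subj$b])^2)
  df_between <- g - 1
  df_subj <- n - g

  # within-subject stratum: center by participant, project sequentially
  df$z <- df$y - subj$m[match(df$id, subj$id)]
  fit_w <- lm(z ~ w, data = df)
  fit_wb <- lm(z ~ w + w:b, data = df)
  ss_within_tot <- sum(df$z^2)
  ss_w <- sum(fitted(fit_w)^2)
  ss_wb <- sum(fitted(fit_wb)^2) - ss_w
  ss_err <- ss_within_tot - ss_w - ss_wb
  df_w <- k - 1
  df_wb <- (g - 1) * (k - 1)
  df_err <- (n - g) * (k - 1)

  # sphericity on the participants x levels matrix, covariance pooled by group
  wide <- tapply(df$y, list(df$id, df$w), mean)
  grp_of <- subj$b[match(rownames(wide), subj$id)]
  sph <- mauchly_gg(wide, group = grp_of)
  eps <- sph$epsilon_gg
  correct <- switch(sphericity,
    never = FALSE,
    always = k > 2,
    auto = k > 2 && is.finite(sph$p) && sph$p < alpha
  )

  eff <- tibble::tibble(
    effect = c(between, within, paste0(within, ":", between)),
    df1 = c(df_between, df_w, df_wb),
    df2 = c(df_subj, df_err, df_err),
    ss = c(ss_between, ss_w, ss_wb),
    err_ss = c(ss_subj, ss_err, ss_err),
    gg_corrected = c(FALSE, correct, correct)
  )
  eff$ms <- eff$ss / eff$df1
  eff$F <- ifelse(eff$ss < 1e-12, 0, eff$ms / (eff$err_ss / eff$df2))
  eff$df1 <- ifelse(eff$gg_corrected, eps * eff$df1, eff$df1)
  eff$df2 <- ifelse(eff$gg_corrected, eps * eff$df2, eff$df2)
  eff$p <- pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  eff <- eff[, c("effect", "df1", "df2", "ss", "ms", "F", "p", "gg_corrected")]

  structure(list(table = eff, mauchly_w = sph$W, mauchly_p = sph$p,
                 epsilon_gg = eps, n_subjects = n, n_dropped = n_dropped,
                 within = within, between = between),
            class = "vmr_anova")
}

#' @method print vmr_anova
#' @export
print.vmr_anova <- function(x, ...) {
  cat(sprintf("Mixed ANOVA: %d participants (%d dropped)\n",
              x$n_subjects, x$n_dropped))
  if (is.finite(x$mauchly_p %||% NA)) {
    cat(sprintf("Mauchly W = %.4f, p = %.4g; GG epsilon = %.4f\n",
                x$mauchly_w, x$mauchly_p, x$epsilon_gg))
  }
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @method tidy vmr_anova
#' @export
tidy.vmr_anova <- function(x, ...) {
  dplyr::rename(x$table, statistic = "F", p.value = "p", term = "effect")
}

#' @method glance vmr_anova
#' @export
glance.vmr_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_dropped = x$n_dropped,
                 mauchly_w = x$mauchly_w, mauchly_p = x$mauchly_p,
                 epsilon_gg = x$epsilon_gg)
}
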