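#' Holm step-down adjustment for post hoc contrasts
#'
#' Wraps the Bonferroni-Holm step-down procedure: raw p-values are ordered,
#' multiplied by `m`, `m - 1`, ... and monotonized. The adjustment is
#' monotone in the raw p-values and leaves a single test unchanged.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same order as the input.
#' @examples
#' posthoc_holm(c(0.01, 0.04))  # 0.02, 0.04
#' @export
posthoc_holm <- function(p) {
  if (length(p) < 1) abort("Need at least one p-value.")
  p.adjust(p, method = "holm")
}

#' Independent-samples t test (pooled variance)
#'
#' Student's two-sample t test with pooled variance and
#' `df = n1 + n2 - 2`, as used to compare total scores between the reward
#' and punishment groups.
#'
#' @param x,y Numeric samples (n >= 2 each).
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `mean_x`,
#'   `mean_y`.
#' @export
independent_t <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("Need n >= 2 per sample.")
  if (var(x) == 0 && var(y) == 0) abort("Zero pooled variance; t is undefined.")
  ht <- t.test(x, y, var.equal = TRUE)
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p.value = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Between-group post hoc comparisons at each within level
#'
#' Runs an independent-samples t test between the two groups at every level
#' of the within factor and applies the Holm correction across levels --
#' the follow-up used when the phase-by-condition interaction is
#' significant.
#'
#' @inheritParams mixed_anova
#' @return A tibble with one row per within level: `level`, `statistic`,
#'   `df`, `p.value`, `p.holm`.
#' @export
posthoc_between_at_levels <- function(data, dv, within, between, id) {
  w <- factor(data[[within]])
  b <- factor(data[[between]])
  if (nlevels(b) != 2) abort("Exactly two between-subject groups are required.")
  y <- as.numeric(data[[dv]])
  res <- purrr::map_dfr(levels(w), function(lev) {
    sel <- w == lev & !is.na(y)
    tt <- independent_t(y[sel & b == levels(b)[1]], y[sel & b == levels(b)[2]])
    tibble::tibble(level = lev, statistic = tt$statistic, df = tt$df,
                   p.value = tt$p.value)
  })
  res$p.holm <- posthoc_holm(res$p.value)
  res
}
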