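#' Lasso solution by coordinate descent
#'
#' Minimises `(1/(2n)) * ||y - X b||^2 + lambda * ||b||_1` for a fixed
#' penalty by cyclic coordinate descent with soft-thresholding. `X` is
#' expected already standardized and `y` centered (no intercept is fit);
#' [cv_lasso_1se()] handles the standardization and the penalty path.
#'
#' @param X Numeric matrix (n x p), no constant columns.
#' @param y Numeric response, length n.
#' @param lambda Non-negative penalty.
#' @param tol Convergence tolerance on the largest coefficient update.
#' @param max_iter Iteration cap.
#' @param beta_init Optional warm start.
#' @return Named numeric vector of coefficients (length p).
#' @export
lasso_fit <- function(X, y, lambda, tol = 1e-8, max_iter = 100000L,
                      beta_init = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) abort("`y` length must match nrow(X).")
  if (!all(is.finite(X)) || !all(is.finite(y)) || !is.finite(lambda) ||
      lambda < 0) {
    abort("Inputs must be finite and `lambda` >= 0.")
  }
  # covariance-form updates: each coordinate step is O(p), independent of n
  XtX <- crossprod(X) / n
  Xty <- as.numeric(crossprod(X, y)) / n
  cn <- diag(XtX)
  if (any(cn == 0)) abort("Constant (zero-variance) columns are not allowed.")

  beta <- beta_init %||% numeric(p)
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  cd_pass <- function(beta) {
    delta_max <- 0
    for (j in seq_len(p)) {
      bj_old <- beta[j]
      rho <- Xty[j] - sum(XtX[j, ] * beta) + cn[j] * bj_old
      bj <- soft(rho, lambda) / cn[j]
      if (bj != bj_old) {
        beta[j] <- bj
        delta_max <- max(delta_max, abs(bj - bj_old))
      }
    }
    list(beta = beta, delta = delta_max)
  }
  # On a fixed support with fixed signs s the minimiser solves
  # XtX[A, A] b = Xty[A] - lambda * s; coordinate passes locate the
  # support, the exact solve removes the slow zigzag on correlated
  # designs, and the KKT conditions certify the solution.
  solve_support <- function(beta) {
    for (it in seq_len(10 * p + 10)) {
      A <- which(beta != 0)
      if (length(A)) {
        s <- sign(beta[A])
        bA <- tryCatch(solve(XtX[A, A, drop = FALSE], Xty[A] - lambda * s),
                       error = function(e) NULL)
        if (is.null(bA)) return(NULL)  # singular: fall back to plain CD
        flipped <- sign(bA) != s & bA != 0
        if (any(flipped)) {
          beta[A[flipped]] <- 0
          next
        }
        beta[A] <- bA
      }
      grad <- Xty - as.numeric(XtX %*% beta)
      inactive <- if (length(A)) setdiff(seq_len(p), A) else seq_len(p)
      viol <- abs(grad[inactive]) - lambda
      if (!length(inactive) || max(viol) <= 1e-12) return(beta)
      j <- inactive[which.max(viol)]
      beta[j] <- sign(grad[j]) * 1e-12
    }
    NULL
  }
  for (it in seq_len(max_iter)) {
    st <- cd_pass(beta)
    beta <- st$beta
    if (it >= 2) {
      refined <- solve_support(beta)
      if (!is.null(refined)) {
        chk <- cd_pass(refined)
        if (chk$delta < tol) {
          beta <- chk$beta
          break
        }
        beta <- chk$beta
      }
    }
    if (st$delta < tol) break
  }
  names(beta) <- colnames(X) %||% paste0("x", seq_len(p))
  beta
}

#' Penalized path with 5-fold cross-validation and the 1SE rule
#'
#' Standardizes the predictors (z-scores) and centers the outcome, builds a
#' descending log-spaced penalty grid from `lambda_max = max |X'y| / n`
#' (the smallest penalty at which every coefficient is zero) down to
#' `lambda_min_ratio * lambda_max`, cross-validates the mean squared
#' prediction error over `k` seeded folds, and applies the one-standard-
#' error rule: the chosen `lambda_1se` is the largest penalty whose CV
#' error is within one standard error of the minimum. Coefficients at
#' `lambda_1se` (full-data fit, warm-started along the path) define the
#' selected variable set.
#'
#' Folds with a constant outcome would make the fold MSE degenerate; if one
#' occurs the folds are redrawn with the next seed (with a message).
#'
#' @param X Numeric matrix or data frame of predictors (original scale).
#' @param y Numeric outcome.
#' @param k Number of CV folds.
#' @param lambda_grid Optional descending penalty grid (on the standardized
#'   scale); built automatically when `NULL`.
#' @param seed Integer seed for the fold assignment.
#' @param n_lambda,lambda_min_ratio Grid size and range.
#' @return An object of class `vmr_lasso`: `lambda_grid`, `cv_mean`,
#'   `cv_se`, `lambda_min`, `lambda_1se`, `selected` (names of non-zero
#'   coefficients at `lambda_1se`), `beta_1se` (standardized scale),
#'   `fold_id`, `seed`.
#' @export
cv_lasso_1se <- function(X, y, k = 5, lambda_grid = NULL, seed = NULL,
                         n_lambda = 100, lambda_min_ratio = 1e-3) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) abort("Need at least as many observations as folds.")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    abort("Inputs must be finite; drop incomplete rows first.")
  }
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) abort("Constant predictor columns are not allowed.")
  Xs <- scale(X)
  yc <- y - mean(y)

  if (is.null(lambda_grid)) {
    lambda_max <- max(abs(crossprod(Xs, yc))) / n
    lambda_grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                           length.out = n_lambda))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  nl <- length(lambda_grid)

  draw_folds <- function(s) with_seed_(s, sample(rep(seq_len(k), length.out = n)))
  seed0 <- seed %||% 20240501
  fold_id <- draw_folds(seed0)
  degenerate <- function(fid) {
    isTRUE(any(tapply(yc, fid, sd) == 0, na.rm = TRUE))
  }
  tries <- 0
  while (degenerate(fold_id) && tries < 25) {
    tries <- tries + 1
    message("Degenerate fold (constant outcome); redrawing with next seed.")
    fold_id <- draw_folds(seed0 + tries)
  }
  if (degenerate(fold_id)) abort("Could not build non-degenerate CV folds.")

  path_fit <- function(Xtr, ytr) {
    betas <- matrix(0, ncol(Xtr), nl)
    b <- numeric(ncol(Xtr))
    for (li in seq_len(nl)) {
      b <- lasso_fit(Xtr, ytr, lambda_grid[li], beta_init = b)
      betas[, li] <- b
    }
    betas
  }

  mse <- matrix(NA_real_, k, nl)
  for (f in seq_len(k)) {
    tr <- fold_id != f
    betas <- path_fit(Xs[tr, , drop = FALSE], yc[tr])
    pred <- Xs[!tr, , drop = FALSE] %*% betas
    mse[f, ] <- colMeans((yc[!tr] - pred)^2)
  }
  cv_mean <- colMeans(mse)
  cv_se <- apply(mse, 2, sd) / sqrt(k)

  i_min <- which.min(cv_mean)
  thresh <- cv_mean[i_min] + cv_se[i_min]
  i_1se <- min(which(cv_mean <= thresh))  # grid is descending: largest lambda
  beta_full <- path_fit(Xs, yc)
  beta_1se <- beta_full[, i_1se]
  names(beta_1se) <- colnames(X) %||% paste0("x", seq_len(ncol(X)))

  structure(
    list(lambda_grid = lambda_grid, cv_mean = cv_mean, cv_se = cv_se,
         lambda_min = lambda_grid[i_min], lambda_1se = lambda_grid[i_1se],
         selected = names(beta_1se)[beta_1se != 0], beta_1se = beta_1se,
         fold_id = fold_id, seed = seed0 + tries),
    class = "vmr_lasso"
  )
}

#' @method print vmr_lasso
#' @export
print.vmr_lasso <- function(x, ...) {
  cat(sprintf("<vmr_lasso> %d-lambda path; lambda_min = %.4g, lambda_1se = %.4g\n",
              length(x$lambda_grid), x$lambda_min, x$lambda_1se))
  if (length(x$selected)) {
    cat("selected at 1SE:", paste(x$selected, collapse = ", "), "\n")
  } else {
    cat("selected at 1SE: (none)\n")
  }
  invisible(x)
}

#' @method tidy vmr_lasso
#' @export
tidy.vmr_lasso <- function(x, ...) {
  tibble::tibble(lambda = x$lambda_grid, cv_mean = x$cv_mean, cv_se = x$cv_se)
}

#' @method glance vmr_lasso
#' @export
glance.vmr_lasso <- function(x, ...) {
  tibble::tibble(lambda_min = x$lambda_min, lambda_1se = x$lambda_1se,
                 n_selected = length(x$selected), cv_seed = x$seed)
}

#' Final OLS model on the Lasso-selected regressors
#'
#' Refits the selected columns by ordinary least squares on their original
#' (unstandardized) scale, so coefficients are directly interpretable in
#' the outcome's units. With an empty selection an intercept-only null
#' model is returned (adjusted R^2 of 0).
#'
#' @param X Predictor matrix or data frame (original scale).
#' @param y Numeric outcome.
#' @param selected Character vector of column names to refit (possibly
#'   empty).
#' @return An object of class `vmr_ols`: coefficient tibble (`term`,
#'   `estimate`, `std.error`, `statistic`, `p.value`), `r2`, `r2_adj`,
#'   `sigma`, `n`, and the underlying `lm` fit.
#' @export
ols_final <- function(X, y, selected = colnames(as.matrix(X))) {
  X <- as.data.frame(X)
  if (length(selected) == 0) {
    fit <- lm(y ~ 1)
  } else {
    if (!all(selected %in% names(X))) abort("Unknown selected column name(s).")
    d <- X[, selected, drop = FALSE]
    if (qr(cbind(1, as.matrix(d)))$rank < length(selected) + 1) {
      abort("Selected columns are collinear; the OLS refit is not identified.")
    }
    d$y <- y
    fit <- lm(y ~ ., data = d)
  }
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  tab <- tibble::tibble(
    term = rownames(co), estimate = co[, 1], std.error = co[, 2],
    statistic = co[, 3], p.value = co[, 4]
  )
  r2 <- if (length(selected) == 0) 0 else sm$r.squared
  r2_adj <- if (length(selected) == 0) 0 else sm$adj.r.squared
  structure(list(coefficients = tab, r2 = r2, r2_adj = r2_adj,
                 sigma = sm$sigma, n = length(y), fit = fit),
            class = "vmr_ols")
}

#' @method print vmr_ols
#' @export
print.vmr_ols <- function(x, ...) {
  cat(sprintf("<vmr_ols> n = %d, R2 = %.3f, adj R2 = %.3f\n",
              x$n, x$r2, x$r2_adj))
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @method tidy vmr_ols
#' @export
tidy.vmr_ols <- function(x, ...) x$coefficients

#' @method glance vmr_ols
#' @export
glance.vmr_ols <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, adj.r.squared = x$r2_adj,
                 sigma = x$sigma, nobs = x$n)
}
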