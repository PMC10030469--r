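# Internal: centre y, centre and unit-variance-scale X (population sd),
# dropping zero-variance columns with a warning.
standardise_design <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  mu <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2, mu)^2))
  keep <- s > 0
  if (!all(keep)) {
    warnf("dropping %d zero-variance feature(s): %s", sum(!keep),
          paste(utils::head(colnames(X)[!keep], 3), collapse = ", "))
  }
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], "/")
  list(Xs = Xs, mu = mu[keep], s = s[keep], keep = keep,
       ybar = mean(y), yc = y - mean(y))
}

#' Lasso objective value
#'
#' (1/(2n)) sum (y - b - X w)^2 + alpha * sum |w_std|, with the penalty
#' applied on the standardised-coefficient scale used internally by
#' [lasso_fit()].
#'
#' @param fit a `lasso_fit` object.
#' @param X,y the design and response the fit was computed from.
#' @return Scalar objective value.
#' @export
lasso_objective <- function(fit, X, y) {
  X <- as.matrix(X)
  resid <- y - fit$intercept - X[, names(fit$coefficients), drop = FALSE] %*%
    fit$coefficients
  sum(resid^2) / (2 * length(y)) + fit$alpha * sum(abs(fit$coefficients_std))
}

#' L1-regularised linear regression by coordinate descent
#'
#' Minimises (1/(2n)) * RSS + alpha * sum(|w_i|) by cyclic coordinate
#' descent with soft-thresholding, the shrinkage driving unimportant
#' coefficients exactly to zero. Predictors are standardised internally
#' so the penalty treats mixed indicator/continuous columns evenly;
#' coefficients are reported on the original scale. At
#' `alpha >= alpha_max = max|X'y|/n` (standardised problem) the solution
#' is the null model.
#'
#' @param X numeric design matrix.
#' @param y numeric response.
#' @param alpha non-negative penalty weight.
#' @param max_sweeps cap on coordinate-descent sweeps.
#' @param tol convergence tolerance on the maximum coefficient change
#'   (standardised scale).
#' @param zero_tol threshold below which a coefficient counts as zero.
#' @return A `lasso_fit`: `alpha`, `coefficients` (original scale, named),
#'   `coefficients_std`, `intercept`, `selected` (feature names with
#'   `|w| > zero_tol` on the standardised scale) and `alpha_max`.
#' @export
lasso_fit <- function(X, y, alpha, max_sweeps = 1000, tol = 1e-7,
                      zero_tol = 1e-8) {
  if (alpha < 0) stopf("alpha must be >= 0")
  st <- standardise_design(X, y)
  n <- length(y)
  G <- crossprod(st$Xs) / n
  q <- drop(crossprod(st$Xs, st$yc)) / n
  W <- lasso_cd_path(G, q, alpha, as.integer(max_sweeps), tol)
  w_std <- drop(W[, 1])
  names(w_std) <- colnames(st$Xs)
  beta <- w_std / st$s
  intercept <- st$ybar - sum(beta * st$mu)
  structure(
    list(alpha = alpha,
         coefficients = beta,
         coefficients_std = w_std,
         intercept = intercept,
         selected = names(w_std)[abs(w_std) > zero_tol],
         alpha_max = max(abs(q))),
    class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> alpha = %.5g, %d/%d nonzero coefficients\n",
              x$alpha, length(x$selected), length(x$coefficients)))
  invisible(x)
}

# default 50-point log-spaced grid from alpha_max down to alpha_max/1000
default_alpha_grid <- function(alpha_max, length_out = 50, ratio = 1e-3) {
  exp(seq(log(alpha_max), log(alpha_max * ratio), length.out = length_out))
}

#' Cross-validated selection of the Lasso penalty
#'
#' K-fold cross-validation of mean held-out squared error over a penalty
#' grid (default: 50 log-spaced values from alpha_max down to
#' alpha_max/1000, fitted pathwise with warm starts). Ties break toward
#' the larger alpha, i.e. the sparser model.
#'
#' @inheritParams lasso_fit
#' @param alpha_grid penalty grid; `NULL` for the default.
#' @param folds number of CV folds (>= 2).
#' @param seed seed for the fold assignment.
#' @param rule `"min"` (smallest mean CV error, default) or `"1se"` (the
#'   largest alpha within one standard error of the minimum — the usual
#'   choice when a sparser support matters more than the last percent of
#'   held-out error).
#' @return The chosen alpha, with the grid and CV-error curve attached as
#'   attribute `"cv"`.
#' @export
select_alpha <- function(X, y, alpha_grid = NULL, folds = 5, seed = 1L,
                         max_sweeps = 1000, tol = 1e-7,
                         rule = c("min", "1se")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (folds < 2) stopf("folds must be >= 2")
  if (n < folds) stopf("n = %d is smaller than the number of folds (%d)", n, folds)
  if (is.null(alpha_grid)) {
    st <- suppressWarnings(standardise_design(X, y))
    amax <- max(abs(crossprod(st$Xs, st$yc) / n))
    if (!is.finite(amax) || amax <= 0) {
      # constant or orthogonal response: every penalty gives the null model
      return(structure(0, cv = data.frame(alpha = 0, cv_error = var(y))))
    }
    alpha_grid <- default_alpha_grid(amax)
  }
  if (length(alpha_grid) == 0) stopf("alpha_grid is empty")
  grid <- sort(alpha_grid, decreasing = TRUE)  # strongest penalty first, warm starts down the path
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  err <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    st <- suppressWarnings(standardise_design(X[tr, , drop = FALSE], y[tr]))
    ntr <- sum(tr)
    G <- crossprod(st$Xs) / ntr
    q <- drop(crossprod(st$Xs, st$yc)) / ntr
    W <- lasso_cd_path(G, q, grid, as.integer(max_sweeps), tol)
    beta <- W / st$s
    intercepts <- st$ybar - drop(crossprod(beta, st$mu))
    Xte <- X[!tr, colnames(st$Xs), drop = FALSE]
    pred <- sweep(Xte %*% beta, 2, intercepts, "+")
    err[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cv_mean <- colMeans(err)
  cv_se <- apply(err, 2, sd) / sqrt(folds)
  cutoff <- if (rule == "1se") {
    min(cv_mean) + cv_se[which.min(cv_mean)]
  } else {
    min(cv_mean) + 1e-12  # exact ties break toward the sparser model
  }
  best <- max(grid[cv_mean <= cutoff])
  structure(best, cv = data.frame(alpha = grid, cv_error = cv_mean,
                                  cv_se = cv_se))
}

#' Nonzero-coefficient features of a Lasso fit
#'
#' @param fit a [lasso_fit()] result.
#' @param zero_tol coefficients with standardised magnitude above this
#'   count as selected.
#' @return Character vector of feature names.
#' @export
selected_features <- function(fit, zero_tol = 1e-8) {
  stopifnot(inherits(fit, "lasso_fit"))
  names(fit$coefficients_std)[abs(fit$coefficients_std) > zero_tol]
}
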