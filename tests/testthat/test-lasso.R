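# orthonormal design in the population-sd sense used internally:
# centred columns, orthogonal, each with mean-square one
orthonormal_design <- function(n) {
  H <- stats::contr.helmert(n)
  sweep(H, 2, sqrt(colMeans(H^2)), "/")
}

test_that("alpha = 0 reproduces least squares", {
  set.seed(1)
  X <- matrix(rnorm(50 * 5), ncol = 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  y <- drop(X %*% c(1, -2, 0.5, 0, 3)) + rnorm(50, sd = 0.3)
  fit <- lasso_fit(X, y, alpha = 0, tol = 1e-12)
  ls <- stats::lm(y ~ X)
  expect_equal(unname(fit$coefficients), unname(coef(ls)[-1]),
               tolerance = 1e-6)
  expect_equal(fit$intercept, unname(coef(ls)[1]), tolerance = 1e-6)
})

test_that("alpha at or above alpha_max yields the exact null model", {
  set.seed(2)
  X <- matrix(rnorm(40 * 6), ncol = 6)
  y <- rnorm(40)
  amax <- lasso_fit(X, y, alpha = 1)$alpha_max
  fit <- lasso_fit(X, y, alpha = amax)
  expect_true(all(fit$coefficients == 0))
  expect_equal(length(selected_features(fit)), 0)
  expect_equal(fit$intercept, mean(y))
})

test_that("negative penalties are rejected", {
  expect_error(lasso_fit(matrix(1:4, 2), c(1, 2), alpha = -0.1), "alpha")
})

test_that("orthonormal designs give the closed-form soft threshold", {
  n <- 24
  X <- orthonormal_design(n)
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  set.seed(3)
  beta <- rnorm(ncol(X))
  y <- drop(X %*% beta) + rnorm(n, sd = 0.2)
  ls <- drop(crossprod(X, y - mean(y))) / n  # least-squares solution
  for (alpha in c(0.05, 0.2, 0.6)) {
    fit <- lasso_fit(X, y, alpha = alpha, tol = 1e-12)
    expected <- sign(ls) * pmax(abs(ls) - alpha, 0)
    expect_equal(unname(fit$coefficients), unname(expected),
                 tolerance = 1e-6)
    expect_setequal(selected_features(fit), colnames(X)[abs(ls) > alpha])
  }
})

test_that("support is non-increasing in alpha on orthonormal designs", {
  n <- 30
  X <- orthonormal_design(n)
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  set.seed(4)
  y <- drop(X %*% rnorm(ncol(X))) + rnorm(n, sd = 0.2)
  alphas <- c(0.01, 0.05, 0.1, 0.3, 0.6, 1.2)
  supports <- lapply(alphas, function(a)
    selected_features(lasso_fit(X, y, alpha = a, tol = 1e-12)))
  for (i in seq_along(alphas)[-1]) {
    expect_true(all(supports[[i]] %in% supports[[i - 1]]))
  }
})

test_that("the objective is non-increasing over coordinate-descent sweeps", {
  set.seed(5)
  Z <- matrix(rnorm(60 * 8), ncol = 8)
  X <- Z %*% chol(0.5 * diag(8) + 0.5)  # correlated design
  colnames(X) <- paste0("x", 1:8)
  y <- drop(X %*% c(2, -1, rep(0, 6))) + rnorm(60)
  obj <- vapply(1:8, function(sw) {
    lasso_objective(lasso_fit(X, y, alpha = 0.2, max_sweeps = sw, tol = 0),
                    X, y)
  }, numeric(1))
  expect_true(all(diff(obj) <= 1e-10))
})

test_that("coordinate descent matches glmnet's objective", {
  set.seed(6)
  X <- matrix(rnorm(80 * 10), ncol = 10)
  X <- sweep(sweep(X, 2, colMeans(X)), 2,
             sqrt(colMeans(sweep(X, 2, colMeans(X))^2)), "/")
  colnames(X) <- paste0("x", 1:10)
  y <- drop(X %*% c(1.5, -2, 0, 0, 1, rep(0, 5))) + rnorm(80, sd = 0.5)
  for (alpha in c(0.05, 0.3)) {
    ours <- lasso_fit(X, y, alpha = alpha, tol = 1e-12)
    ref <- glmnet::glmnet(X, y, lambda = alpha, standardize = FALSE,
                          thresh = 1e-14)
    ref_fit <- list(alpha = alpha,
                    coefficients = setNames(as.numeric(ref$beta), rownames(ref$beta)),
                    coefficients_std = as.numeric(ref$beta),
                    intercept = as.numeric(ref$a0))
    class(ref_fit) <- "lasso_fit"
    expect_equal(lasso_objective(ours, X, y),
                 lasso_objective(ref_fit, X, y), tolerance = 1e-6)
  }
})

test_that("cross-validation handles forced and degenerate cases", {
  set.seed(7)
  X <- matrix(rnorm(30 * 3), ncol = 3)
  y <- rnorm(30)
  expect_equal(as.numeric(select_alpha(X, y, alpha_grid = 0.42, seed = 1)),
               0.42)
  expect_error(select_alpha(X[1:3, ], y[1:3], folds = 5), "folds")
  expect_error(select_alpha(X, y, folds = 1), "folds")
  # constant response: null model, zero penalty path
  a0 <- select_alpha(X, rep(2, 30), seed = 1)
  expect_true(length(selected_features(lasso_fit(X, rep(2, 30), as.numeric(a0)))) == 0)
})

test_that("cross-validated lasso recovers a sparse planted support", {
  set.seed(8)
  n <- 500
  p <- 100
  X <- matrix(rnorm(n * p), ncol = p, dimnames = list(NULL, paste0("x", 1:p)))
  truth <- paste0("x", 1:5)
  y <- drop(X[, 1:5] %*% c(3, -3, 2, 2, -2)) + rnorm(n)
  # the one-standard-error rule keeps the support tight; the plain
  # CV-minimum also recovers the truth but drags in more noise features
  alpha <- select_alpha(X, y, seed = 8, rule = "1se")
  sel <- selected_features(lasso_fit(X, y, as.numeric(alpha)))
  expect_true(all(truth %in% sel))
  expect_lte(length(setdiff(sel, truth)), 5)
  alpha_min <- select_alpha(X, y, seed = 8)
  expect_lte(as.numeric(alpha_min), as.numeric(alpha))
  sel_min <- selected_features(lasso_fit(X, y, as.numeric(alpha_min)))
  expect_true(all(truth %in% sel_min))
})

test_that("pure-noise responses give a near-empty model and flat CV error", {
  set.seed(9)
  n <- 300
  X <- matrix(rnorm(n * 50), ncol = 50, dimnames = list(NULL, paste0("x", 1:50)))
  y <- rnorm(n)
  alpha <- select_alpha(X, y, seed = 9)
  sel <- selected_features(lasso_fit(X, y, as.numeric(alpha)))
  expect_lte(length(sel), 5)
  cv <- attr(alpha, "cv")
  expect_equal(min(cv$cv_error), var(y), tolerance = 0.2)
})

test_that("zero-variance features are dropped with a warning", {
  set.seed(10)
  X <- cbind(flat = rep(1, 20), ok = rnorm(20))
  y <- rnorm(20)
  expect_warning(fit <- lasso_fit(X, y, alpha = 0.1), "zero-variance")
  expect_false("flat" %in% names(fit$coefficients))
})

test_that("tiny coefficients fall below the selection tolerance", {
  fit <- structure(list(coefficients_std = c(a = 1e-12, b = 0.3)),
                   class = "lasso_fit")
  expect_equal(selected_features(fit), "b")
})
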