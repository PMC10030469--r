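# Lloyd's algorithm with seeded restarts. Written out in full (rather
# than delegating to stats::kmeans) because the assignment rule,
# tie-breaking, empty-cluster repair and restart policy are part of the
# procedure under study; stats::kmeans serves as an independent
# cross-check in the test suite.

# squared Euclidean distances rows(X) x rows(C)
sq_dist <- function(X, C) {
  d <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  d[d < 0] <- 0
  d
}

# distance-weighted (k-means++-style) seeding; "random" picks k distinct rows
init_centroids <- function(X, k, method) {
  n <- nrow(X)
  if (method == "random") {
    return(X[sample.int(n, k), , drop = FALSE])
  }
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- sq_dist(X, X[idx[1], , drop = FALSE])[, 1]
  for (j in seq_len(k)[-1]) {
    if (all(d2 == 0)) {
      idx[j] <- sample.int(n, 1)
    } else {
      idx[j] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, sq_dist(X, X[idx[j], , drop = FALSE])[, 1])
  }
  X[idx, , drop = FALSE]
}

lloyd_once <- function(X, k, max_iter, tol, init) {
  n <- nrow(X)
  C <- init_centroids(X, k, init)
  labels <- integer(n)
  inertia_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    D <- sq_dist(X, C)
    new_labels <- max.col(-D, ties.method = "first")  # nearest; lowest index wins ties
    # repair empty clusters by reseeding from the farthest point
    for (j in which(tabulate(new_labels, k) == 0)) {
      far <- which.max(D[cbind(seq_len(n), new_labels)])
      C[j, ] <- X[far, ]
      D[, j] <- sq_dist(X, C[j, , drop = FALSE])[, 1]
      new_labels <- max.col(-D, ties.method = "first")
    }
    inertia_trace <- c(inertia_trace, sum(D[cbind(seq_len(n), new_labels)]))
    converged <- it > 1 && all(new_labels == labels)
    labels <- new_labels
    newC <- C
    for (j in seq_len(k)) {
      newC[j, ] <- colMeans(X[labels == j, , drop = FALSE])
    }
    shift <- sqrt(max(rowSums((newC - C)^2)))
    C <- newC
    if (converged || shift < tol) break
  }
  D <- sq_dist(X, C)
  labels <- max.col(-D, ties.method = "first")
  list(centroids = C, labels = labels,
       inertia = sum(D[cbind(seq_len(n), labels)]),
       inertia_trace = inertia_trace, iter = it)
}

#' Fit K-Means by Lloyd's algorithm with seeded restarts
#'
#' Starts from `n_init` distance-weighted random seedings, runs Lloyd
#' iterations (assign each observation to the nearest centroid, then
#' recompute the centroids as cluster means) until an iteration no longer
#' reassigns any observation or the centroid shift drops below `tol`, and
#' keeps the restart with the lowest within-cluster sum of squares
#' (inertia). Assignment ties break toward the lowest cluster index;
#' clusters that empty out are re-seeded from the farthest point.
#'
#' @param X numeric matrix (rows = observations).
#' @param k number of clusters; must not exceed the number of distinct rows.
#' @param n_init number of seeded restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @param tol centroid-shift convergence tolerance.
#' @param seed integer seed; restart r uses a seed derived from it.
#' @param init `"kmeans++"` (distance-weighted seeding, default) or
#'   `"random"` (uniform over rows).
#' @return A `cluster_model`: list with `k`, `centroids`, `labels`,
#'   `inertia`, `n_init`, `seed`, `iter` and the best restart's
#'   per-iteration `inertia_trace`.
#' @export
kmeans_fit <- function(X, k, n_init = 10, max_iter = 300, tol = 1e-6,
                       seed = 1L, init = c("kmeans++", "random")) {
  init <- match.arg(init)
  X <- as.matrix(X)
  if (nrow(X) == 0) stopf("empty input matrix")
  n_distinct <- nrow(unique(X))
  if (k < 1) stopf("k must be >= 1")
  if (k > n_distinct) {
    stopf("k = %d exceeds the number of distinct rows (%d)", k, n_distinct)
  }
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- with_seed(derive_seed(seed, r), lloyd_once(X, k, max_iter, tol, init))
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(
    list(k = k, centroids = best$centroids, labels = best$labels,
         inertia = best$inertia, n_init = n_init, seed = as.integer(seed),
         iter = best$iter, inertia_trace = best$inertia_trace),
    class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, n = %d, inertia = %.4f\n",
              x$k, length(x$labels), x$inertia))
  cat("  sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Within-cluster sum of squares across a range of K
#'
#' Fits [kmeans_fit()] for each `k` in `1:k_max` under a shared restart
#' budget and returns the inertia curve used by the elbow method.
#'
#' @inheritParams kmeans_fit
#' @param k_max largest K to fit.
#' @return Named numeric vector `wcss_by_k` (names `"1"` to `"k_max"`).
#' @export
wcss_curve <- function(X, k_max, n_init = 10, seed = 1L, ...) {
  ks <- seq_len(k_max)
  setNames(vapply(ks, function(k) {
    kmeans_fit(X, k, n_init = n_init, seed = derive_seed(seed, 1000L + k),
               ...)$inertia
  }, numeric(1)), ks)
}
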