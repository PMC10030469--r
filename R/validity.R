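#' Silhouette widths
#'
#' For observation i with mean intra-cluster distance a(i) (excluding
#' itself) and b(i) the smallest mean distance to another cluster,
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)), which lies in \[-1, 1\].
#' Values near +1 mean the point sits far from neighbouring clusters,
#' values near 0 on a boundary, and negative values suggest assignment to
#' the wrong cluster. Points in singleton clusters get s(i) = 0.
#'
#' @param X numeric matrix of observations.
#' @param labels integer cluster labels (at least two non-empty clusters).
#' @return List with `values` (per-row s(i)) and `mean`.
#' @export
silhouette_widths <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stopf("silhouette requires at least two clusters")
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  sizes <- tabulate(labels, max(ks))
  # mean distance from each point to every cluster (including its own)
  member <- outer(labels, ks, "==") * 1
  sums <- D %*% member
  means <- sweep(sums, 2, sizes[ks], "/")
  own <- match(labels, ks)
  a <- sums[cbind(seq_len(n), own)] / pmax(sizes[labels] - 1, 1)
  other <- means
  other[cbind(seq_len(n), own)] <- Inf
  b <- apply(other, 1, min)
  s <- as.numeric((b - a) / pmax(a, b))
  s[sizes[labels] == 1] <- 0
  s[!is.finite(s)] <- 0
  list(values = s, mean = mean(s))
}

#' Calinski-Harabasz criterion
#'
#' C(k) = Trace(B) (n - k) / (Trace(W) (k - 1)), where B is the
#' cluster-size-weighted between-cluster scatter about the grand mean and
#' W the pooled within-cluster scatter. Higher values indicate compact,
#' well-separated clusters.
#'
#' @inheritParams silhouette_widths
#' @return Scalar criterion value.
#' @export
calinski_harabasz <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  k <- length(ks)
  n <- nrow(X)
  if (k < 2) stopf("Calinski-Harabasz requires k >= 2")
  if (k >= n) stopf("Calinski-Harabasz requires k < n")
  grand <- colMeans(X)
  trace_b <- 0
  trace_w <- 0
  for (g in ks) {
    Xg <- X[labels == g, , drop = FALSE]
    mu <- colMeans(Xg)
    trace_b <- trace_b + nrow(Xg) * sum((mu - grand)^2)
    trace_w <- trace_w + sum(sweep(Xg, 2, mu)^2)
  }
  if (trace_w <= 0) stopf("degenerate clustering: Trace(W) = 0")
  trace_b * (n - k) / (trace_w * (k - 1))
}

#' Ray-Turi criterion
#'
#' Ratio of within-cluster compactness to between-cluster separation:
#' the mean squared distance of observations to their cluster centroid,
#' divided by the minimum squared distance between two centroids. Lower
#' is better.
#'
#' @inheritParams silhouette_widths
#' @return Scalar criterion value (non-negative).
#' @export
ray_turi <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stopf("Ray-Turi requires k >= 2")
  centroids <- t(vapply(ks, function(g) colMeans(X[labels == g, , drop = FALSE]),
                        numeric(ncol(X))))
  within <- mean(rowSums((X - centroids[match(labels, ks), , drop = FALSE])^2))
  d2 <- as.matrix(stats::dist(centroids))^2
  sep <- min(d2[upper.tri(d2)])
  if (sep == 0) stopf("coincident centroids: between-cluster separation is 0")
  within / sep
}

#' Elbow selection of the number of clusters
#'
#' Picks the K where the WCSS curve bends most sharply: the argmax over
#' interior K of the second difference w(K-1) - 2 w(K) + w(K+1). The full
#' curve should still be inspected by eye; it is returned as an attribute.
#'
#' @param wcss_by_k named numeric vector of WCSS for consecutive K
#'   starting at 1 (at least three values).
#' @return The chosen K (integer), with the curve attached as attribute
#'   `"curve"`. Exactly flat curvature ties break toward the smallest K
#'   with a warning; a non-increasing violation also warns.
#' @export
elbow_select <- function(wcss_by_k) {
  w <- as.numeric(wcss_by_k)
  m <- length(w)
  if (m < 3) stopf("elbow selection needs WCSS for at least three K values")
  if (any(diff(w) > 1e-8 * max(abs(w), 1))) {
    warnf("WCSS curve is not non-increasing in K; check the restart budget")
  }
  ks <- if (!is.null(names(wcss_by_k))) as.integer(names(wcss_by_k)) else seq_len(m)
  d2 <- w[1:(m - 2)] - 2 * w[2:(m - 1)] + w[3:m]
  if (max(d2) - min(d2) < 1e-12 * max(abs(w), 1)) {
    warnf("WCSS curve has no curvature; defaulting to the smallest interior K")
  }
  chosen <- ks[which.max(d2) + 1L]
  structure(as.integer(chosen), curve = wcss_by_k)
}

#' Cluster-validity report
#'
#' Computes the WCSS curve over `1:k_max`, the elbow choice of K, and at
#' the chosen K the silhouette values, Calinski-Harabasz and Ray-Turi
#' criteria.
#'
#' @inheritParams kmeans_fit
#' @param k_max largest K for the WCSS curve.
#' @param k optional forced K for the metric evaluation (the elbow choice
#'   is still reported).
#' @return List with `wcss_by_k`, `chosen_k`, `silhouette`,
#'   `calinski_harabasz`, `ray_turi` and the fitted `model` at the
#'   evaluated K.
#' @export
validity_report <- function(X, k_max = 6, k = NULL, n_init = 10, seed = 1L) {
  wcss <- wcss_curve(X, k_max, n_init = n_init, seed = seed)
  chosen <- suppressWarnings(elbow_select(wcss))
  k_eval <- k %||% as.integer(chosen)
  model <- kmeans_fit(X, k_eval, n_init = n_init,
                      seed = derive_seed(seed, 1000L + k_eval))
  sil <- silhouette_widths(X, model$labels)
  list(wcss_by_k = wcss,
       chosen_k = as.integer(chosen),
       evaluated_k = k_eval,
       silhouette = sil,
       calinski_harabasz = calinski_harabasz(X, model$labels),
       ray_turi = ray_turi(X, model$labels),
       model = model)
}
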