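# Independent oracles. These re-derive expected values from first
# principles (exhaustive enumeration, literal definitions) and must stay
# free of the package's own computational paths.

oracle_wcss <- function(X, labels) {
  total <- 0
  for (g in unique(labels)) {
    Xg <- X[labels == g, , drop = FALSE]
    mu <- colMeans(Xg)
    total <- total + sum(sweep(Xg, 2, mu)^2)
  }
  total
}

# exhaustive minimum WCSS over every partition of n points into at most
# k non-empty groups, via restricted-growth-string enumeration
oracle_best_partition <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  labels <- integer(n)
  recurse <- function(i, used) {
    if (i > n) {
      best <<- min(best, oracle_wcss(X, labels[seq_len(n)]))
      return(invisible())
    }
    for (g in seq_len(min(used + 1L, k))) {
      labels[i] <<- g
      recurse(i + 1L, max(used, g))
    }
  }
  recurse(1L, 0L)
  best
}

# literal silhouette definition, double loop
oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}
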