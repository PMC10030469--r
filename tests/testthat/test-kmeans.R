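test_that("k = 1 gives the total sum of squares about the mean", {
  X <- matrix(rnorm(40, sd = 3), ncol = 2)
  fit <- kmeans_fit(X, 1, seed = 1)
  expect_equal(fit$inertia, sum(sweep(X, 2, colMeans(X))^2))
})

test_that("the six-point instance is split into its two natural groups", {
  fit <- kmeans_fit(six_points(), 2, seed = 1)
  expect_equal(fit$inertia, 8 / 3)
  expect_equal(length(unique(fit$labels[1:3])), 1)
  expect_equal(length(unique(fit$labels[4:6])), 1)
  expect_false(fit$labels[1] == fit$labels[4])
})

test_that("k equal to the number of distinct rows gives zero inertia", {
  X <- matrix(c(0, 0, 1, 0, 0, 1, 5, 5), ncol = 2, byrow = TRUE)
  fit <- kmeans_fit(X, 4, seed = 2)
  expect_equal(fit$inertia, 0)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(c(0, 0, 0, 0, 1, 1), ncol = 2, byrow = TRUE)
  expect_error(kmeans_fit(X, 3, seed = 1), "distinct rows")
  expect_error(kmeans_fit(X[0, , drop = FALSE], 1), "empty")
  expect_error(kmeans_fit(X, 0), "k must be")
})

test_that("restarted Lloyd attains the exhaustive-partition optimum", {
  set.seed(20)
  for (i in 1:12) {
    n <- sample(5:10, 1)
    k <- sample(2:3, 1)
    X <- matrix(rnorm(2 * n), ncol = 2)
    fit <- kmeans_fit(X, k, n_init = 50, seed = i)
    expect_equal(fit$inertia, oracle_best_partition(X, k), tolerance = 1e-9)
  }
})

test_that("inertia is non-increasing across Lloyd iterations", {
  set.seed(8)
  X <- rbind(matrix(rnorm(120), ncol = 3),
             matrix(rnorm(120, mean = 2), ncol = 3))
  fit <- kmeans_fit(X, 3, n_init = 3, seed = 8)
  expect_true(all(diff(fit$inertia_trace) <= 1e-9))
})

test_that("best-restart inertia is no worse than stats::kmeans", {
  set.seed(31)
  X <- rbind(matrix(rnorm(200), ncol = 4),
             matrix(rnorm(160, mean = 1.5), ncol = 4))
  ours <- kmeans_fit(X, 3, n_init = 30, seed = 31)$inertia
  ref <- stats::kmeans(X, 3, nstart = 30, iter.max = 100)$tot.withinss
  # both are restart heuristics; they must land on optima of the same
  # quality even if the exact basin differs
  expect_lte(ours, ref * 1.02)
})

test_that("the same seed reproduces the same model", {
  X <- six_points()
  a <- kmeans_fit(X, 2, seed = 99)
  b <- kmeans_fit(X, 2, seed = 99)
  expect_identical(a, b)
})

test_that("silhouette values respect their definition and range", {
  X <- six_points()
  s <- silhouette_widths(X, six_labels)
  expect_true(all(s$values >= -1 & s$values <= 1))
  expect_true(all(s$values > 0.8))
  expect_equal(s$values, oracle_silhouette(X, six_labels))
  expect_equal(s$mean, mean(oracle_silhouette(X, six_labels)))

  # a point assigned to the wrong of two distant clusters scores negative
  wrong <- c(2L, 1L, 1L, 2L, 2L, 2L)
  expect_lt(silhouette_widths(X, wrong)$values[1], 0)

  expect_error(silhouette_widths(X, rep(1L, 6)), "two clusters")
})

test_that("singleton clusters get silhouette zero", {
  X <- rbind(six_points(), c(100, 100))
  s <- silhouette_widths(X, c(six_labels, 3L))
  expect_equal(s$values[7], 0)
})

test_that("Calinski-Harabasz matches the direct scatter computation", {
  X <- six_points()
  expect_equal(calinski_harabasz(X, six_labels), 450)
  # invariant to cluster relabelling
  expect_equal(calinski_harabasz(X, 3L - six_labels), 450)
  expect_error(calinski_harabasz(X, rep(1L, 6)), "k >= 2")
  # every point at its centroid: degenerate compactness
  Xd <- matrix(c(0, 0, 0, 0, 5, 5, 5, 5), ncol = 2, byrow = TRUE)
  expect_error(calinski_harabasz(Xd, c(1L, 1L, 2L, 2L)), "Trace\\(W\\) = 0")
})

test_that("Ray-Turi equals within-compactness over centroid separation", {
  X <- six_points()
  # mean squared distance to centroid (8/3)/6 over min squared
  # inter-centroid distance 200
  expect_equal(ray_turi(X, six_labels), (8 / 3) / 6 / 200)
  # scale invariance: both terms scale as c^2
  expect_equal(ray_turi(3.7 * X, six_labels), ray_turi(X, six_labels))
  # perfectly compact clusters score zero
  Xd <- matrix(c(0, 0, 0, 0, 5, 5, 5, 5), ncol = 2, byrow = TRUE)
  expect_equal(ray_turi(Xd, c(1L, 1L, 2L, 2L)), 0)
  # coincident centroids are degenerate
  Xc <- matrix(c(0, 1, 0, -1, 1, 0, -1, 0), ncol = 2, byrow = TRUE)
  expect_error(ray_turi(Xc, c(1L, 1L, 2L, 2L)), "coincident")
})

test_that("elbow selection maximises the second difference", {
  w <- setNames(c(100, 40, 20, 18, 17), 1:5)
  expect_equal(as.integer(elbow_select(w)), 2L)
  expect_error(elbow_select(w[1:2]), "at least three")
  expect_warning(e <- elbow_select(setNames(c(30, 20, 10), 1:3)),
                 "no curvature")
  expect_equal(as.integer(e), 2L)
  expect_warning(elbow_select(setNames(c(10, 12, 5, 4), 1:4)),
                 "not non-increasing")
})

test_that("wcss curve is non-increasing and elbow finds the planted K", {
  sim <- generate_couple_survey(crisp_config(n = 300, seed = 6))
  enc <- encode_survey_pair(sim)
  w <- wcss_curve(enc, 5, seed = 6)
  expect_true(all(diff(w) <= 1e-6 * w[1]))
  expect_equal(as.integer(elbow_select(w)), 3L)
})

test_that("all four validity metrics agree that the planted K is best", {
  sim <- generate_couple_survey(crisp_config(n = 300, seed = 12))
  enc <- encode_survey_pair(sim)
  ks <- 2:4
  fits <- lapply(ks, function(k) kmeans_fit(enc, k, seed = 12))
  sil <- vapply(fits, function(f) silhouette_widths(enc, f$labels)$mean,
                numeric(1))
  ch <- vapply(fits, function(f) calinski_harabasz(enc, f$labels), numeric(1))
  rt <- vapply(fits, function(f) ray_turi(enc, f$labels), numeric(1))
  expect_equal(ks[which.max(sil)], 3)
  expect_equal(ks[which.max(ch)], 3)
  expect_equal(ks[which.min(rt)], 3)
  w <- wcss_curve(enc, 5, seed = 12)
  expect_equal(as.integer(elbow_select(w)), 3L)
})
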