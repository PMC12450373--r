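test_that("silhouette matches hand computation and the brute-force oracle", {
  # 1-D pairs {0, 0.1} and {10, 10.1}: a = 0.1 everywhere, b = 10.05 for
  # the outer points and 9.95 for the inner ones
  X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c(0L, 0L, 1L, 1L)
  expect_equal(silhouette_score(X, lab),
               ((10.05 - 0.1) / 10.05 + (9.95 - 0.1) / 9.95) / 2,
               tolerance = 1e-9)
  # two identical clusters at the same location: a = b so S = 0
  Y <- matrix(1, 16, 2)
  expect_equal(silhouette_score(Y, rep(c(0L, 1L), each = 8)), 0)
  # random instances against the brute-force definition
  set.seed(12)
  for (k in 1:8) {
    n <- sample(10:30, 1)
    Z <- matrix(rnorm(n * 3), n, 3)
    lz <- sample(0:2, n, replace = TRUE)
    lz[sample(n, 3)] <- -1L  # some noise points
    expect_equal(silhouette_score(Z, lz), brute_silhouette(Z, lz),
                 tolerance = 1e-12)
  }
  # fewer than two clusters: undefined, not an error
  expect_true(is.na(silhouette_score(matrix(rnorm(10), 5, 2), rep(0L, 5))))
  expect_true(is.na(silhouette_score(matrix(rnorm(10), 5, 2), rep(-1L, 5))))
})

test_that("silhouette agrees with the cluster package on clean labelings", {
  set.seed(3)
  X <- matrix(rnorm(40 * 4), 40, 4)
  lab <- sample(0:3, 40, replace = TRUE)
  ref <- mean(cluster::silhouette(lab + 1L, dist(X))[, "sil_width"])
  expect_equal(silhouette_score(X, lab), ref, tolerance = 1e-9)
})

test_that("density clustering separates blobs and handles degenerate input", {
  set.seed(5)
  blobs <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
                 matrix(rnorm(40, 5, 0.1), 20, 2))
  lab <- cluster_embeddings(blobs, density_cluster_params(
    min_cluster_size = 5, min_samples = 5, selection_epsilon = 0))
  expect_equal(length(setdiff(unique(lab), -1L)), 2L)
  expect_true(all(lab >= -1L))
  expect_equal(length(unique(lab[1:20])), 1L)
  expect_equal(length(unique(lab[21:40])), 1L)
  # three blobs
  b3 <- rbind(blobs, matrix(rnorm(40, -5, 0.1), 20, 2))
  lab3 <- cluster_embeddings(b3, density_cluster_params(5, 5, 0))
  expect_equal(length(setdiff(unique(lab3), -1L)), 3L)
  # identical points: one cluster or all noise, never a crash
  same <- matrix(1, 30, 2)
  lab_same <- cluster_embeddings(same, density_cluster_params(5, 5, 0))
  expect_true(length(setdiff(unique(lab_same), -1L)) <= 1L)
  expect_error(cluster_embeddings(matrix(rnorm(6), 3, 2),
                                  density_cluster_params(10, 5)),
               "min_cluster_size")
})

test_that("bootstrap clustering is reproducible and summarizes correctly", {
  gen <- small_families(n_groups = 8, members = 12, seed = 41)
  # perfectly separated families: within-family identical pooled vectors
  gids <- vapply(gen$data$records, `[[`, "", "group_id")
  centers <- diag(8) * 10
  pooled <- centers[as.integer(factor(gids)), ]
  rownames(pooled) <- names(gen$data$records)
  rep1 <- bootstrap_cluster_silhouette(
    gen$data, pooled, bootstrap_config(2, 6, seed = 3),
    density_cluster_params(5, 3, 0))
  expect_equal(rep1$max_score, 1.0)
  rep2 <- bootstrap_cluster_silhouette(
    gen$data, pooled, bootstrap_config(2, 6, seed = 3),
    density_cluster_params(5, 3, 0))
  expect_identical(rep1, rep2)
  expect_equal(rep1$max_score,
               max(rep1$per_iteration_scores, na.rm = TRUE))
  expect_error(bootstrap_cluster_silhouette(
    gen$data, pooled, bootstrap_config(1, 99, seed = 1)), "exceeds")
})

test_that("shrinking within-family dispersion never lowers the mean silhouette", {
  gen <- small_families(n_groups = 6, members = 12, seed = 43)
  gids <- vapply(gen$data$records, `[[`, "", "group_id")
  centers <- matrix(rnorm(6 * 8, sd = 5), 6, 8)
  means <- numeric(0)
  for (disp in c(2, 1, 0.5, 0.25)) {
    set.seed(7)  # same noise draws, scaled
    noise <- matrix(rnorm(length(gids) * 8), length(gids), 8)
    pooled <- centers[as.integer(factor(gids)), ] + disp * noise
    rownames(pooled) <- names(gen$data$records)
    rep0 <- bootstrap_cluster_silhouette(
      gen$data, pooled, bootstrap_config(5, 4, seed = 11),
      density_cluster_params(5, 3, 0))
    means <- c(means, mean(rep0$per_iteration_scores, na.rm = TRUE))
  }
  expect_true(all(diff(means) >= -1e-12))
})
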