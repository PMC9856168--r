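test_that("kmeans_fit handles degenerate and trivial inputs", {
  X <- matrix(rep(c(1, 2, 3, 1, 0, 2), each = 5), 5, 6)
  fit <- kmeans_fit(X, k = 1, n_init = 5, seed = 1)
  expect_equal(unname(fit$centroids[1, ]), c(1, 2, 3, 1, 0, 2))
  expect_equal(fit$inertia, 0)
  expect_error(kmeans_fit(X[1:2, ], k = 3, n_init = 5), "n >= k")
  Xbad <- X; Xbad[1, 1] <- NA
  expect_error(kmeans_fit(Xbad, k = 1), "finite")
})

test_that("kmeans_fit separates well-separated blobs and reports true inertia", {
  blobs <- make_blobs(30, mu1 = c(2.3, 2.6, 3.4, 1.4, 0.5, 2.0),
                      mu2 = c(0.8, 0.5, 1.2, 0.7, 0.0, 1.3),
                      sd = 0.2, seed = 5)
  fit <- kmeans_fit(blobs$X, k = 2, n_init = 20, seed = 9)
  # labels split the blobs perfectly (up to label permutation)
  agree <- max(mean(fit$labels == blobs$truth),
               mean(fit$labels != blobs$truth))
  expect_equal(agree, 1)
  # centroids near blob means: 3 * sd / sqrt(n_per)
  for (mu in list(c(2.3, 2.6, 3.4, 1.4, 0.5, 2.0),
                  c(0.8, 0.5, 1.2, 0.7, 0.0, 1.3))) {
    d <- sqrt(min(rowSums(sweep(fit$centroids, 2, mu)^2)))
    expect_lt(d, 3 * 0.2 / sqrt(30) * sqrt(6))
  }
  # reported inertia equals recomputed sum of squared distances
  recomputed <- sum(vapply(seq_len(nrow(blobs$X)), function(i)
    sum((blobs$X[i, ] - fit$centroids[fit$labels[i], ])^2), numeric(1)))
  expect_equal(fit$inertia, recomputed)
})

test_that("kmeans_fit attains the exhaustive global optimum on small instances", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(8:12, 1)
    X <- matrix(runif(n * 6, 0, 4), n, 6)
    fit <- kmeans_fit(X, k = 2, n_init = 100)
    expect_equal(fit$inertia, best_partition_inertia_k2(X), tolerance = 1e-9)
  }
})

test_that("kmeans_fit is deterministic given a seed and matches stats::kmeans", {
  set.seed(12)
  X <- matrix(runif(240, 0, 5), 40, 6)
  f1 <- kmeans_fit(X, 2, n_init = 50, seed = 77)
  f2 <- kmeans_fit(X, 2, n_init = 50, seed = 77)
  expect_identical(f1$centroids, f2$centroids)
  expect_identical(f1$labels, f2$labels)
  # independent cross-check on clustered data: many-restart Hartigan-Wong
  # reaches the same global optimum
  blobs <- make_blobs(20, mu1 = rep(0.8, 6), mu2 = rep(3, 6), sd = 0.4,
                      seed = 13)
  fb <- kmeans_fit(blobs$X, 2, n_init = 50, seed = 78)
  km <- stats::kmeans(blobs$X, 2, nstart = 50, iter.max = 100)
  expect_equal(fb$inertia, km$tot.withinss, tolerance = 1e-6)
})

test_that("silhouette behaves at its boundary cases and matches cluster::", {
  # two tight, far-separated pairs: score essentially 1
  X <- rbind(c(0, 0, 0, 0, 0, 0), c(0.01, 0, 0, 0, 0, 0),
             c(4, 5, 6, 3, 2, 3), c(4, 5, 6, 3, 2, 2.99))
  expect_gt(silhouette_mean(X, c(1, 1, 2, 2)), 0.99)
  # coincident points within clusters: exactly 1 by the a = 0 convention
  Xc <- rbind(c(0, 0, 0, 0, 0, 0), c(0, 0, 0, 0, 0, 0),
              c(4, 5, 6, 3, 2, 3), c(4, 5, 6, 3, 2, 3))
  expect_equal(silhouette_mean(Xc, c(1, 1, 2, 2)), 1)
  expect_error(silhouette_mean(X, c(1, 1, 1, 1)), "2 clusters")
  # random labels on one isotropic blob: near zero
  set.seed(8)
  blob <- matrix(rnorm(200 * 6), 200, 6)
  expect_lt(abs(silhouette_mean(blob, sample(1:2, 200, TRUE))), 0.2)
  # range bound and agreement with the reference implementation
  skip_if_not_installed("cluster")
  for (k in 2:4) {
    lab <- sample(seq_len(k), 60, replace = TRUE)
    X60 <- matrix(runif(360), 60, 6)
    s <- silhouette_mean(X60, lab)
    expect_true(s >= -1 && s <= 1)
    ref <- mean(cluster::silhouette(lab, dist(X60))[, "sil_width"])
    expect_equal(s, ref, tolerance = 1e-12)
  }
})

test_that("twin-sample agreement is permutation-matched and bounded", {
  blobs <- make_blobs(25, mu1 = rep(0, 6), mu2 = rep(4, 6), sd = 0.3, seed = 3)
  twin <- make_blobs(20, mu1 = rep(0, 6), mu2 = rep(4, 6), sd = 0.3, seed = 4)
  expect_equal(twin_sample_validate(blobs$X, twin$X, k = 2, n_init = 20,
                                    seed = 1), 1)
  # structureless data: matching over the two label permutations keeps
  # agreement at or above one half
  set.seed(99)
  for (rep in 1:5) {
    a <- matrix(runif(120), 20, 6)
    b <- matrix(runif(120), 20, 6)
    agr <- twin_sample_validate(a, b, k = 2, n_init = 20)
    expect_gte(agr, 0.5)
    expect_lte(agr, 1)
  }
  expect_error(twin_sample_validate(matrix(1, 1, 6), matrix(1, 5, 6), k = 2,
                                    n_init = 2), "at least k")
})

test_that("cross-validated centroid selection recovers the generating structure", {
  synth <- generate_cohort(generator_config(n = 190, seed = 2024))
  cv <- select_centroids_cv(synth$cohort, k = 2, folds = 5, n_init = 60,
                            seed = 55)
  expect_length(cv$report$fold_accuracies, 5)
  expect_true(all(cv$report$fold_accuracies > 0.9))
  expect_equal(cv$report$selected_fold, which.max(cv$report$fold_accuracies))
  expect_equal(cv$report$aggregate_accuracy, mean(cv$report$fold_accuracies))
  # fold assignment is a partition of the cohort
  expect_identical(sort(unique(cv$report$fold_assignment)), 1:5)
  expect_length(cv$report$fold_assignment, 190)
  # centroids near the generating means, CDI = 1 the higher-sum one
  cfg <- synth$config
  expect_true(all(abs(cv$model$centroid_cdi1 - cfg$cluster_means$cdi1) < 0.5))
  expect_true(all(abs(cv$model$centroid_cdi0 - cfg$cluster_means$cdi0) < 0.5))
  expect_gt(sum(cv$model$centroid_cdi1), sum(cv$model$centroid_cdi0))
  # bit-for-bit reproducibility under the same seed
  cv2 <- select_centroids_cv(synth$cohort, k = 2, folds = 5, n_init = 60,
                             seed = 55)
  expect_identical(cv$model$centroid_cdi1, cv2$model$centroid_cdi1)
  expect_identical(cv$report$fold_accuracies, cv2$report$fold_accuracies)
})

test_that("perfectly separated toy data gives unit accuracies and first-fold ties", {
  # two exact groups, duplicate-free within group
  X <- rbind(
    cbind(seq(0, 0.5, length.out = 10), 0, 0, 0, 0, 0),
    cbind(seq(3.5, 4, length.out = 10), 5, 6, 3, 2, 3))
  cv <- select_centroids_cv(X, k = 2, folds = 5, n_init = 10, seed = 7)
  expect_equal(cv$report$fold_accuracies, rep(1, 5))
  expect_equal(cv$report$selected_fold, 1L)   # tie -> lowest fold index
  expect_error(select_centroids_cv(X[1:8, ], k = 2, folds = 5, n_init = 5),
               "too small")
})

test_that("nearest-centroid assignment matches frozen distances and is
           invariant to ordering and centroid storage", {
  model <- cdi_builtin_model()
  # squared distances recomputed by hand from the shipped fold-3 centroids
  expect_equal(sum((c(2, 3, 3, 1, 0, 2) - model$centroid_cdi1)^2), 0.7172)
  expect_equal(sum((c(2, 3, 3, 1, 0, 2) - model$centroid_cdi0)^2), 11.1994)
  expect_identical(assign_cdi(c(2, 3, 3, 1, 0, 2), model), 1L)
  expect_identical(assign_cdi(rep(0, 6), model), 0L)          # 29.82 vs 4.56
  expect_identical(assign_cdi(c(1, 1, 2, 1, 0, 2), model), 0L) # 6.72 vs 1.46
  # storage order of the centroids is irrelevant: relabelled on construction
  swapped <- cdi_model(centroid_cdi0 = model$centroid_cdi1,
                       centroid_cdi1 = model$centroid_cdi0)
  m <- rbind(c(2, 3, 3, 1, 0, 2), rep(0, 6), c(1, 1, 2, 1, 0, 2))
  expect_identical(assign_cdi(m, swapped), assign_cdi(m, model))
  # row order invariance
  expect_identical(assign_cdi(m[3:1, ], model), rev(assign_cdi(m, model)))
  # tie in distance goes to the conservative class 0
  tie_model <- cdi_model(centroid_cdi0 = c(1, 0, 0, 0, 0, 0),
                         centroid_cdi1 = c(3, 0, 0, 0, 0, 0))
  expect_identical(assign_cdi(c(2, 0, 0, 0, 0, 0), tie_model), 0L)
})
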