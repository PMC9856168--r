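# K-means++ / Lloyd clustering, silhouette, twin-sample validation and the
# cross-validated centroid selection that defines the CDI model.

# One K-means++ initialization: D^2-weighted seeding (Arthur & Vassilvitskii).
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- sqdist(X, centers[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      if (sum(d2) <= 0) idx <- sample.int(n, 1L)
      else idx <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, sqdist(X, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

# Lloyd iterations from given centers; stops when assignments are unchanged
# or after max_iter.  Empty clusters are re-seeded at the point farthest
# from the empty cluster's (stale) centroid.  Inertia is checked to be
# non-increasing across plain update steps (repairs excepted).
lloyd <- function(X, centers, max_iter = 300L) {
  n <- nrow(X)
  k <- nrow(centers)
  labels <- rep(0L, n)
  inertia_prev <- Inf
  repaired <- FALSE
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    D <- sqdist(X, centers)
    new_labels <- max.col(-D, ties.method = "first")
    empties <- setdiff(seq_len(k), unique(new_labels))
    if (length(empties)) {
      for (j in empties) centers[j, ] <- X[which.max(D[, j]), ]
      repaired <- TRUE
      if (iter >= max_iter) break
      next
    }
    inertia <- sum(D[cbind(seq_len(n), new_labels)])
    if (!repaired && inertia > inertia_prev + 1e-8)
      stop("internal error: inertia increased during Lloyd iteration")
    inertia_prev <- inertia
    repaired <- FALSE
    if (identical(new_labels, labels)) { converged <- TRUE; labels <- new_labels; break }
    labels <- new_labels
    if (iter >= max_iter) break
    for (j in seq_len(k))
      centers[j, ] <- colMeans(X[labels == j, , drop = FALSE])
  }
  D <- sqdist(X, centers)
  labels <- max.col(-D, ties.method = "first")
  inertia <- sum(D[cbind(seq_len(n), labels)])
  list(centers = centers, labels = labels, inertia = inertia,
       iterations = iter, converged = converged)
}

#' K-means clustering with K-means++ restarts
#'
#' Runs Lloyd's algorithm from `n_init` independent K-means++
#' initializations and keeps the run with minimal inertia (total
#' within-cluster sum of squared Euclidean distances).  Deterministic given
#' `seed`.  Subscores are clustered on their raw integer scales; no
#' standardization is applied.
#'
#' @param data Numeric matrix, one row per sample (6 columns for CRS-R use,
#'   but any dimension is accepted), or a cohort data frame.
#' @param k Number of clusters, `1 <= k <= nrow(data)`.
#' @param n_init Number of random initializations (default 500).
#' @param seed Integer seed, or NULL to use the current RNG stream.
#' @param max_iter Lloyd iteration cap per initialization.
#' @return Object of class `cdi_kmeans`: `centroids` (k x d), `labels`,
#'   `inertia`, `n_init`, `seed`, `iterations`, `converged`.
#' @export
kmeans_fit <- function(data, k, n_init = 500L, seed = NULL, max_iter = 300L) {
  X <- if (is.data.frame(data)) as_subscore_matrix(data) else as.matrix(data)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("non-finite values in data", call. = FALSE)
  n <- nrow(X)
  if (k < 1L || n < k) stop(sprintf("need n >= k >= 1 (n = %d, k = %d)", n, k),
                            call. = FALSE)
  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      fit <- lloyd(X, kmeanspp_init(X, k), max_iter = max_iter)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  structure(list(centroids = best$centers, labels = best$labels,
                 inertia = best$inertia, n_init = as.integer(n_init),
                 seed = seed, iterations = best$iterations,
                 converged = best$converged),
            class = "cdi_kmeans")
}

#' Mean silhouette score of a clustering
#'
#' For each sample, `a` is its mean distance to the other members of its
#' own cluster and `b` the smallest mean distance to any other cluster; the
#' silhouette is `(b - a) / max(a, b)`.  Members of singleton clusters
#' contribute 0, as do samples with `a = b = 0`.  Used to confirm that two
#' clusters partition the cohort best.
#'
#' @param data Numeric matrix or cohort data frame, n >= 3 rows.
#' @param labels Integer cluster labels covering at least 2 clusters.
#' @return Mean silhouette in [-1, 1].
#' @export
silhouette_mean <- function(data, labels) {
  X <- if (is.data.frame(data)) as_subscore_matrix(data) else as.matrix(data)
  labels <- as.integer(labels)
  n <- nrow(X)
  stopifnot(length(labels) == n)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L)
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  D <- as.matrix(stats::dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    m <- sum(own)
    if (m == 1L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (m - 1L)
    b <- min(vapply(clusters[clusters != labels[i]],
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Agreement between two label vectors, maximized over cluster-label
# permutations (labels are arbitrary up to permutation across fits).
match_agreement <- function(labels_a, labels_b, k) {
  stopifnot(length(labels_a) == length(labels_b))
  max(vapply(permutations(k),
             function(p) mean(p[labels_a] == labels_b), numeric(1)))
}

#' Twin-sample validation of clustering stability
#'
#' Fits one clustering on the training set and an independent one on the
#' validation set, labels every validation sample under both models (by
#' nearest centroid for the training model; by its own fit for the
#' validation model), and returns the proportion of agreeing labels after
#' maximizing over cluster-label permutations.  For k = 2 the matched
#' agreement is therefore always >= 0.5.
#'
#' @param train,validation Subscore matrices (or cohort data frames), each
#'   with at least `k` rows.
#' @param k Number of clusters.
#' @param n_init,seed,max_iter Passed to [kmeans_fit()].
#' @return Agreement proportion in [0, 1].
#' @export
twin_sample_validate <- function(train, validation, k = 2L, n_init = 500L,
                                 seed = NULL, max_iter = 300L) {
  Xt <- if (is.data.frame(train)) as_subscore_matrix(train) else as.matrix(train)
  Xv <- if (is.data.frame(validation)) as_subscore_matrix(validation) else as.matrix(validation)
  if (nrow(Xt) < k || nrow(Xv) < k)
    stop("train and validation sets each need at least k rows", call. = FALSE)
  with_seed(seed, {
    fit_t <- kmeans_fit(Xt, k, n_init = n_init, max_iter = max_iter)
    fit_v <- kmeans_fit(Xv, k, n_init = n_init, max_iter = max_iter)
    labels_from_train <- max.col(-sqdist(Xv, fit_t$centroids),
                                 ties.method = "first")
    match_agreement(labels_from_train, fit_v$labels, k)
  })
}

#' Derive the CDI model by cross-validated twin-sample selection
#'
#' Partitions the reference cohort into `folds` disjoint folds (seeded,
#' unstratified); for each fold, estimates k-means++ centroids on the
#' training portion and scores twin-sample agreement on the held-out fold;
#' then returns the training centroids of the fold with minimal
#' twin-validation error (ties broken toward the lowest fold index).  The
#' higher-sum centroid is labelled CDI = 1.
#'
#' @param reference Reference cohort (data frame) or n x 6 subscore matrix,
#'   with at least `folds * k` rows.
#' @param k Number of clusters (the CDI uses 2).
#' @param folds Number of cross-validation folds.
#' @param n_init,seed,max_iter Passed to [kmeans_fit()].
#' @return List with `model` (a [cdi_model()]) and `report`
#'   (class `cdi_twin_report`: `fold_accuracies`, `selected_fold`,
#'   `aggregate_accuracy`, `fold_centroids`, `fold_assignment`).
#' @export
select_centroids_cv <- function(reference, k = 2L, folds = 5L, n_init = 500L,
                                seed = NULL, max_iter = 300L) {
  X <- if (is.data.frame(reference)) as_subscore_matrix(reference) else as.matrix(reference)
  n <- nrow(X)
  if (n < folds * k)
    stop(sprintf("cohort too small: need at least folds * k = %d rows, got %d",
                 folds * k, n), call. = FALSE)
  with_seed(seed, {
    fold_id <- sample(rep_len(seq_len(folds), n))
    accs <- numeric(folds)
    cents1 <- matrix(NA_real_, folds, ncol(X))
    cents0 <- matrix(NA_real_, folds, ncol(X))
    colnames(cents1) <- colnames(cents0) <- colnames(X)
    rownames(cents1) <- rownames(cents0) <- paste0("fold", seq_len(folds))
    for (f in seq_len(folds)) {
      Xt <- X[fold_id != f, , drop = FALSE]
      Xv <- X[fold_id == f, , drop = FALSE]
      fit_t <- kmeans_fit(Xt, k, n_init = n_init, max_iter = max_iter)
      fit_v <- kmeans_fit(Xv, k, n_init = n_init, max_iter = max_iter)
      labels_from_train <- max.col(-sqdist(Xv, fit_t$centroids),
                                   ties.method = "first")
      accs[f] <- match_agreement(labels_from_train, fit_v$labels, k)
      sums <- rowSums(fit_t$centroids)
      cents1[f, ] <- fit_t$centroids[which.max(sums), ]
      cents0[f, ] <- fit_t$centroids[which.min(sums), ]
    }
    selected <- which.max(accs)  # min twin error; ties -> lowest index
    model <- cdi_model(centroid_cdi0 = cents0[selected, ],
                       centroid_cdi1 = cents1[selected, ],
                       source_fold = selected,
                       provenance = sprintf(
                         "%d-fold CV on n = %d reference cohort, k-means++ x %d inits",
                         folds, n, n_init))
    report <- structure(
      list(fold_accuracies = accs, selected_fold = selected,
           aggregate_accuracy = mean(accs),
           fold_centroids = list(cdi1 = cents1, cdi0 = cents0),
           fold_assignment = fold_id),
      class = "cdi_twin_report")
    list(model = model, report = report)
  })
}

#' @export
print.cdi_twin_report <- function(x, ...) {
  cat("Twin-sample validation report\n")
  cat("fold accuracies:", paste(sprintf("%.3f", x$fold_accuracies),
                                collapse = " "), "\n")
  cat(sprintf("selected fold: %d (aggregate accuracy %.3f)\n",
              x$selected_fold, x$aggregate_accuracy))
  invisible(x)
}
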