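#' Construct a CDI centroid-pair model
#'
#' The deployable CDI model is a pair of 6-dimensional centroids in CRS-R
#' subscore space.  CDI = 1 is, by convention, the higher-responsiveness
#' cluster: the centroid with the larger component sum.  Centroids passed
#' in either order are relabelled to satisfy this, so downstream labels
#' never depend on storage order.
#'
#' @param centroid_cdi0,centroid_cdi1 Numeric 6-vectors of subscore means,
#'   each component within its subscale range.
#' @param source_fold Optional integer: cross-validation fold the centroids
#'   came from.
#' @param provenance Free-text provenance note.
#' @return An object of class `cdi_model`.
#' @export
cdi_model <- function(centroid_cdi0, centroid_cdi1, source_fold = NA_integer_,
                      provenance = "") {
  c0 <- as.numeric(centroid_cdi0)
  c1 <- as.numeric(centroid_cdi1)
  stopifnot(length(c0) == 6L, length(c1) == 6L,
            all(is.finite(c0)), all(is.finite(c1)))
  maxima <- crsr_subscale_max()
  for (j in seq_len(6L)) {
    if (c0[j] < 0 || c0[j] > maxima[j] || c1[j] < 0 || c1[j] > maxima[j])
      stop(sprintf("centroid component '%s' outside [0, %d]",
                   names(maxima)[j], maxima[j]), call. = FALSE)
  }
  if (sum(c1) < sum(c0)) { tmp <- c0; c0 <- c1; c1 <- tmp }
  if (sum(c1) == sum(c0))
    stop("degenerate model: both centroids have equal component sums",
         call. = FALSE)
  names(c0) <- names(c1) <- crsr_subscales()
  structure(list(centroid_cdi0 = c0, centroid_cdi1 = c1,
                 source_fold = as.integer(source_fold),
                 provenance = provenance),
            class = "cdi_model")
}

#' @export
print.cdi_model <- function(x, ...) {
  cat("CDI centroid-pair model\n")
  m <- rbind(`CDI=0` = x$centroid_cdi0, `CDI=1` = x$centroid_cdi1)
  print(round(m, 3))
  if (!is.na(x$source_fold)) cat("source fold:", x$source_fold, "\n")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Reference-cohort centroids for all five cross-validation folds
#'
#' Per-fold K-means++ centroids estimated on the 190-patient reference
#' cohort used to derive the CDI (five-fold cross-validation; fold 3
#' attained the minimum twin-validation error and is the shipped model).
#' Exposed so that fold-summary tables (median/IQR across folds) can be
#' recomputed.
#'
#' @return List with 5 x 6 matrices `cdi1` and `cdi0` (rows = folds).
#' @seealso [cdi_builtin_model()], [centroid_fold_summary()]
#' @export
cdi_reference_folds <- function() {
  sub <- crsr_subscales()
  cdi1 <- matrix(c(
    2.42, 2.56, 3.26, 1.51, 0.47, 1.95,
    2.50, 2.74, 3.22, 1.56, 0.44, 2.02,
    2.33, 2.65, 3.37, 1.37, 0.46, 1.98,
    2.41, 2.72, 3.45, 1.36, 0.50, 2.00,
    2.27, 2.60, 3.33, 1.47, 0.51, 1.91),
    nrow = 5, byrow = TRUE, dimnames = list(paste0("fold", 1:5), sub))
  cdi0 <- matrix(c(
    0.85, 0.58, 1.28, 0.66, 0.01, 1.31,
    0.82, 0.55, 1.41, 0.69, 0.03, 1.32,
    0.81, 0.54, 1.24, 0.66, 0.01, 1.28,
    0.91, 0.61, 1.22, 0.70, 0.01, 1.34,
    0.89, 0.54, 1.21, 0.73, 0.01, 1.30),
    nrow = 5, byrow = TRUE, dimnames = list(paste0("fold", 1:5), sub))
  list(cdi1 = cdi1, cdi0 = cdi0)
}

#' The built-in CDI reference model
#'
#' The fold-3 centroid pair from [cdi_reference_folds()] — the fold with
#' minimum twin-validation error on the reference cohort — ready for
#' nearest-centroid assignment with [assign_cdi()].
#'
#' @return A `cdi_model`.
#' @export
cdi_builtin_model <- function() {
  folds <- cdi_reference_folds()
  cdi_model(centroid_cdi0 = folds$cdi0["fold3", ],
            centroid_cdi1 = folds$cdi1["fold3", ],
            source_fold = 3L,
            provenance = "built-in reference model (fold 3, minimum twin-validation error)")
}

#' Summarize per-fold centroids by median and IQR
#'
#' Applies [median_iqr_hinges()] column-wise to each cluster's fold
#' centroids, producing the fold-summary table reported alongside a
#' cross-validated model.
#'
#' @param folds List with matrices `cdi1` and `cdi0` (folds x subscales),
#'   as returned by [cdi_reference_folds()] or [select_centroids_cv()].
#' @return Data frame with columns cluster, statistic, and the six subscales.
#' @export
centroid_fold_summary <- function(folds) {
  stopifnot(is.list(folds), all(c("cdi1", "cdi0") %in% names(folds)))
  one <- function(m, label) {
    med <- vapply(seq_len(ncol(m)),
                  function(j) median_iqr_hinges(m[, j])[["median"]], numeric(1))
    iqr <- vapply(seq_len(ncol(m)),
                  function(j) median_iqr_hinges(m[, j])[["iqr"]], numeric(1))
    out <- data.frame(cluster = label, statistic = c("median", "iqr"),
                      rbind(med, iqr), check.names = FALSE, row.names = NULL)
    names(out)[-(1:2)] <- colnames(m)
    out
  }
  rbind(one(folds$cdi1, "CDI=1"), one(folds$cdi0, "CDI=0"))
}

#' Serialize a CDI model to JSON
#'
#' @param model A `cdi_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cdi_model <- function(model, path) {
  stopifnot(inherits(model, "cdi_model"))
  jsonlite::write_json(
    list(centroid_cdi0 = model$centroid_cdi0,
         centroid_cdi1 = model$centroid_cdi1,
         source_fold = model$source_fold,
         provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a CDI model from JSON
#'
#' @param path Path written by [write_cdi_model()], or the string
#'   `"builtin"` for the shipped reference model.
#' @return A `cdi_model`.
#' @export
read_cdi_model <- function(path) {
  if (identical(path, "builtin")) return(cdi_builtin_model())
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cdi_model(x$centroid_cdi0, x$centroid_cdi1,
            source_fold = x$source_fold %||% NA_integer_,
            provenance = x$provenance %||% "")
}

#' Assign the Consciousness Domain Index by nearest centroid
#'
#' Each patient is assigned to the cluster whose centroid is nearest in
#' 6-dimensional Euclidean distance over the CRS-R subscores.  Returns 1
#' iff the squared distance to the CDI = 1 centroid is strictly smaller
#' than to the CDI = 0 centroid; exact ties go to 0 (the conservative,
#' lower-responsiveness class).
#'
#' @param crsr A cohort data frame, subscore matrix, or single record.
#' @param model A `cdi_model` (default: the built-in reference model).
#' @return Integer vector of 0/1 labels.
#' @examples
#' assign_cdi(c(2, 3, 3, 1, 0, 2))  # 1: close to the high-responsiveness centroid
#' assign_cdi(c(1, 1, 2, 1, 0, 2))  # 0
#' @export
assign_cdi <- function(crsr, model = cdi_builtin_model()) {
  stopifnot(inherits(model, "cdi_model"))
  m <- as_subscore_matrix(crsr)
  C <- rbind(model$centroid_cdi0, model$centroid_cdi1)
  D <- sqdist(m, C)
  as.integer(D[, 2] < D[, 1])
}
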