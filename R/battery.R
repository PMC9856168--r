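# The multivariate prognostic battery: five predictor variants x three
# follow-ups, each adjusted for the same confounders.

battery_predictors <- c("CDI", "diagnosis", "CRSR8", "CRSR10", "CRSR_total")

# Confounder design shared by every model: age (years), sex (F vs M),
# time post-injury (days), etiology as TBI and HI/A indicators against
# a vascular (or other) reference.
confounder_design <- function(cohort) {
  cbind(intercept = 1,
        age = cohort$age,
        sex_F = as.numeric(cohort$sex == "F"),
        tpi = cohort$time_post_injury,
        etiology_TBI = as.numeric(cohort$etiology == "TBI"),
        etiology_HIA = as.numeric(cohort$etiology == "HI_A"))
}

predictor_column <- function(cohort, predictor, cdi_labels) {
  switch(predictor,
         CDI = as.numeric(cdi_labels),
         diagnosis = as.numeric(cohort$diagnosis == "MCS"),
         CRSR8 = as.numeric(dichotomize_total(cohort$total, 8L)),
         CRSR10 = as.numeric(dichotomize_total(cohort$total, 10L)),
         CRSR_total = as.numeric(cohort$total),
         stop("unknown predictor: ", predictor, call. = FALSE))
}

outcome_column <- function(cohort, follow_up) {
  col <- paste0("outcome_", follow_up, "m")
  if (!col %in% names(cohort))
    stop("cohort has no outcome column for ", follow_up, " months",
         call. = FALSE)
  cohort[[col]]
}

#' Run the multivariate logistic-regression battery
#'
#' Fits one logistic regression per predictor of interest (CDI from
#' nearest-centroid assignment, clinical diagnosis, the CRS-R total
#' dichotomized at 8 and at 10, and the continuous CRS-R total) and per
#' follow-up, always adjusted for age, sex, time post-injury and etiology
#' (TBI and hypoxic-ischemic/anoxic indicators against a vascular
#' reference).  Records missing the outcome at a given follow-up are
#' excluded from that follow-up's models only.
#'
#' @param cohort A validated cohort data frame.
#' @param model A `cdi_model` used to derive the CDI predictor.
#' @param follow_ups Integer months to evaluate (default 6, 12, 24).
#' @return Object of class `cdi_battery`: a named list of [fit_logistic()]
#'   results keyed `"<predictor>_<follow-up>m"`, with a `specs` attribute.
#' @export
run_model_battery <- function(cohort, model = cdi_builtin_model(),
                              follow_ups = c(6L, 12L, 24L)) {
  cohort <- validate_cohort(cohort)
  cdi_labels <- assign_cdi(cohort, model)
  fits <- list()
  specs <- list()
  for (fu in follow_ups) {
    outcome <- outcome_column(cohort, fu)
    keep <- !is.na(outcome)
    y <- as.numeric(outcome[keep] == "eMCS")
    sub <- cohort[keep, , drop = FALSE]
    conf <- confounder_design(sub)
    for (pred in battery_predictors) {
      key <- sprintf("%s_%dm", pred, fu)
      X <- cbind(conf, predictor_column(sub, pred, cdi_labels[keep]))
      colnames(X)[ncol(X)] <- pred
      fits[[key]] <- tryCatch(
        fit_logistic(X, y),
        error = function(e)
          stop(sprintf("model %s (predictor %s, %d months): %s",
                       key, pred, fu, conditionMessage(e)), call. = FALSE))
      specs[[key]] <- list(predictor = pred, follow_up = fu, n = sum(keep))
    }
  }
  structure(fits, specs = specs, class = "cdi_battery")
}

#' Tabulate a fitted battery
#'
#' Long-format report with one row per model term: predictor of interest,
#' follow-up, odds ratio with 95% Wald CI and p-value, plus per-model
#' Nagelkerke R2 and AuROC (repeated on each of the model's rows).
#'
#' @param battery A `cdi_battery` from [run_model_battery()].
#' @return Data frame.
#' @export
battery_report <- function(battery) {
  stopifnot(inherits(battery, "cdi_battery"))
  specs <- attr(battery, "specs")
  rows <- lapply(names(battery), function(key) {
    fit <- battery[[key]]
    sp <- specs[[key]]
    cbind(data.frame(predictor = sp$predictor, follow_up_months = sp$follow_up,
                     n = fit$n, nagelkerke_r2 = fit$nagelkerke_r2,
                     auroc = fit$auroc, separation = fit$separation),
          fit$or_table)
  })
  do.call(rbind, rows)
}

#' @export
print.cdi_battery <- function(x, ...) {
  specs <- attr(x, "specs")
  cat(sprintf("prognostic battery: %d logistic models\n", length(x)))
  for (key in names(x)) {
    fit <- x[[key]]
    cat(sprintf("  %-14s n = %3d  R2 = %.3f  AuROC = %.3f%s\n", key, fit$n,
                fit$nagelkerke_r2, fit$auroc,
                if (fit$separation) "  [separation]" else ""))
  }
  invisible(x)
}
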