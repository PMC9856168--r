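# Synthetic cohort generator.  Emulates the statistical structure the CDI
# analysis assumes: a two-cluster mixture in CRS-R subscore space around
# the reference centroids, demographics near the validation cohort's
# (median age 53 y, ~71% male, median time post-injury 56 d, roughly half
# MCS), and a logistic outcome process in which CDI = 1, younger age,
# shorter time post-injury, male sex and non-anoxic etiology all raise the
# probability of recovering full consciousness, with recovery monotone
# non-decreasing across the 6-, 12- and 24-month follow-ups.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: cluster
#' means at the built-in reference centroids with per-subscale Gaussian
#' dispersion 0.7 (rounded and clipped to subscale ranges), a 45% weight
#' on the high-responsiveness cluster, a 10% diagnosis flip rate
#' (clinical diagnosis disagrees with the latent cluster for a minority of
#' patients), demographics calibrated to median/IQR age 53/35 years and
#' time post-injury 56/54 days with 71% males and etiology proportions
#' 38.5% TBI / 24.5% HI-A / 37.1% vascular, and outcome log-odds giving
#' roughly 38% recovery at 6 months rising by follow-up shifts 0.23 and
#' 0.32 at 12 and 24 months.
#'
#' @param n Cohort size.
#' @param cluster_means List with 6-vectors `cdi1` and `cdi0`.
#' @param cluster_sd Per-subscale Gaussian dispersion (> 0).
#' @param mix_weight Probability of the CDI = 1 cluster, in (0, 1).
#' @param diagnosis_flip Probability that the recorded clinical diagnosis
#'   disagrees with the latent cluster.
#' @param outcome_coefs Named log-odds coefficients: intercept, cdi, age,
#'   sex_F, tpi, etiology_TBI, etiology_HIA.
#' @param followup_shifts Named additive log-odds shifts for follow-ups
#'   `"6"`, `"12"`, `"24"`; must be non-decreasing so recovery is monotone.
#' @param demo List of demographic parameters (medians/IQRs, proportions).
#' @param seed Integer seed, or NULL for the current RNG stream.
#' @return A `cdi_generator_config` list.
#' @export
generator_config <- function(
    n = 143L,
    cluster_means = list(cdi1 = cdi_builtin_model()$centroid_cdi1,
                         cdi0 = cdi_builtin_model()$centroid_cdi0),
    cluster_sd = 0.7,
    mix_weight = 0.45,
    diagnosis_flip = 0.10,
    outcome_coefs = c(intercept = 2.0, cdi = 2.8, age = -0.035,
                      sex_F = -1.0, tpi = -0.03,
                      etiology_TBI = -0.1, etiology_HIA = -0.7),
    followup_shifts = c(`6` = 0, `12` = 0.23, `24` = 0.32),
    demo = list(age_median = 53, age_iqr = 35,
                prop_male = 0.71,
                tpi_median = 56, tpi_iqr = 54,
                etiology_probs = c(TBI = 0.385, HI_A = 0.245,
                                   VASCULAR = 0.371)),
    seed = NULL) {
  stopifnot(n >= 0, cluster_sd > 0, mix_weight > 0, mix_weight < 1,
            diagnosis_flip >= 0, diagnosis_flip < 1)
  required <- c("intercept", "cdi", "age", "sex_F", "tpi",
                "etiology_TBI", "etiology_HIA")
  if (!all(required %in% names(outcome_coefs)))
    stop("outcome_coefs must name: ", paste(required, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(followup_shifts))
    stop("followup_shifts must be non-decreasing (monotone recovery)",
         call. = FALSE)
  stopifnot(length(cluster_means$cdi1) == 6L, length(cluster_means$cdi0) == 6L)
  structure(list(n = as.integer(n), cluster_means = cluster_means,
                 cluster_sd = cluster_sd, mix_weight = mix_weight,
                 diagnosis_flip = diagnosis_flip,
                 outcome_coefs = outcome_coefs,
                 followup_shifts = followup_shifts,
                 demo = demo, seed = seed),
            class = "cdi_generator_config")
}

# integer draw around a median with the given IQR, via a rounded normal
# (sd = IQR / 1.349) clipped to [lo, hi]
draw_median_iqr <- function(n, med, iqr, lo, hi) {
  pmin(pmax(round(stats::rnorm(n, med, iqr / 1.349)), lo), hi)
}

#' Generate a synthetic patient cohort
#'
#' Draws each patient's latent cluster, subscores (cluster mean + Gaussian
#' noise, rounded and clipped to subscale ranges), demographics, a
#' clinical diagnosis linked to the latent cluster with a configurable
#' flip rate, and monotone longitudinal outcomes from a shared latent
#' uniform draw against rising recovery probabilities.  Bit-reproducible
#' given the seed.
#'
#' @param config A [generator_config()].
#' @return Object of class `cdi_synth`: `cohort` (validated `cdi_cohort`),
#'   `latent_cluster` (0/1 ground truth), `linear_predictor` (6-month
#'   outcome log-odds), `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "cdi_generator_config"))
  n <- config$n
  with_seed(config$seed, {
    maxima <- crsr_subscale_max()
    z <- stats::rbinom(n, 1L, config$mix_weight)
    means <- rbind(config$cluster_means$cdi0, config$cluster_means$cdi1)
    scores <- matrix(0L, n, 6L, dimnames = list(NULL, crsr_subscales()))
    if (n > 0) {
      noise <- matrix(stats::rnorm(n * 6L, 0, config$cluster_sd), n, 6L)
      raw <- means[z + 1L, , drop = FALSE] + noise
      for (j in seq_len(6L))
        scores[, j] <- as.integer(pmin(pmax(round(raw[, j]), 0L), maxima[j]))
    }
    d <- config$demo
    age <- draw_median_iqr(n, d$age_median, d$age_iqr, 18, 95)
    tpi <- draw_median_iqr(n, d$tpi_median, d$tpi_iqr, 28, 92)
    sex <- ifelse(stats::runif(n) < d$prop_male, "M", "F")
    ep <- d$etiology_probs / sum(d$etiology_probs)
    etiology <- if (n > 0) sample(names(ep), n, replace = TRUE, prob = ep)
                else character(0)
    flip <- stats::runif(n) < config$diagnosis_flip
    diagnosis <- ifelse(xor(z == 1L, flip), "MCS", "VS_UWS")
    b <- config$outcome_coefs
    lp <- b[["intercept"]] + b[["cdi"]] * z + b[["age"]] * age +
      b[["sex_F"]] * (sex == "F") + b[["tpi"]] * tpi +
      b[["etiology_TBI"]] * (etiology == "TBI") +
      b[["etiology_HIA"]] * (etiology == "HI_A")
    u <- stats::runif(n)
    outcome_at <- function(shift)
      ifelse(u < stats::plogis(lp + shift), "eMCS", "pDoC")
    cohort <- data.frame(
      id = if (n > 0) sprintf("S%04d", seq_len(n)) else character(0),
      stringsAsFactors = FALSE)
    for (j in seq_len(6L)) cohort[[crsr_subscales()[j]]] <- scores[, j]
    cohort$total <- as.integer(rowSums(scores))
    cohort$diagnosis <- diagnosis
    cohort$age <- as.numeric(age)
    cohort$sex <- sex
    cohort$etiology <- etiology
    cohort$time_post_injury <- as.numeric(tpi)
    cohort$outcome_6m <- outcome_at(config$followup_shifts[["6"]])
    cohort$outcome_12m <- outcome_at(config$followup_shifts[["12"]])
    cohort$outcome_24m <- outcome_at(config$followup_shifts[["24"]])
    cohort <- validate_cohort(cohort)
    structure(list(cohort = cohort, latent_cluster = z,
                   linear_predictor = unname(lp), config = config),
              class = "cdi_synth")
  })
}
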