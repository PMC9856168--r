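#' CRS-R subscale names and maxima
#'
#' The Coma Recovery Scale-Revised scores behavioural responses on six
#' subscales; the standard instrument caps them at 4 (auditory), 5 (visual),
#' 6 (motor), 3 (oromotor), 2 (communication) and 3 (arousal), so the total
#' ranges 0-23.  The maxima are exposed so that validation bounds are
#' inspectable (and, in principle, replaceable for scale variants).
#'
#' @return Named integer vector of per-subscale maxima, in canonical order.
#' @export
crsr_subscale_max <- function() {
  c(auditory = 4L, visual = 5L, motor = 6L, oromotor = 3L,
    communication = 2L, arousal = 3L)
}

crsr_subscales <- function() names(crsr_subscale_max())

.cohort_columns <- function() {
  c("id", crsr_subscales(), "total", "diagnosis", "age", "sex", "etiology",
    "time_post_injury", "outcome_6m", "outcome_12m", "outcome_24m")
}

.diagnosis_levels <- c("VS_UWS", "MCS")
.sex_levels <- c("M", "F")
.etiology_levels <- c("TBI", "VASCULAR", "HI_A", "OTHER")
.outcome_levels <- c("eMCS", "pDoC")

#' Construct a single validated CRS-R record
#'
#' @param auditory,visual,motor,oromotor,communication,arousal Integer
#'   subscores within the standard subscale ranges.
#' @param total Optional total; must equal the sum of the six subscores
#'   (computed when omitted).
#' @return Named integer vector with the six subscores and `total`.
#' @examples
#' crsr_record(1, 1, 2, 1, 0, 2)
#' @export
crsr_record <- function(auditory, visual, motor, oromotor, communication,
                        arousal, total = NULL) {
  x <- c(auditory = auditory, visual = visual, motor = motor,
         oromotor = oromotor, communication = communication, arousal = arousal)
  maxima <- crsr_subscale_max()
  for (s in names(x)) {
    v <- x[[s]]
    if (!is.finite(v) || v != as.integer(v) || v < 0 || v > maxima[[s]])
      stop(sprintf("subscore '%s' = %s outside [0, %d]", s, format(v), maxima[[s]]),
           call. = FALSE)
  }
  x <- as.integer(x)
  names(x) <- crsr_subscales()
  if (is.null(total)) total <- sum(x)
  if (total != sum(x))
    stop(sprintf("total (%s) does not equal the sum of subscores (%d)",
                 format(total), sum(x)), call. = FALSE)
  c(x, total = as.integer(total))
}

# Pull the n x 6 subscore matrix out of a cohort data frame (or pass a
# numeric matrix/vector through, validating dimensions).
as_subscore_matrix <- function(x) {
  if (is.data.frame(x)) {
    missing_cols <- setdiff(crsr_subscales(), names(x))
    if (length(missing_cols))
      stop("missing subscore columns: ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    m <- as.matrix(x[, crsr_subscales(), drop = FALSE])
  } else if (is.matrix(x)) {
    if (ncol(x) != 6L) stop("subscore matrix must have 6 columns", call. = FALSE)
    m <- x
    colnames(m) <- crsr_subscales()
  } else if (is.numeric(x) && length(x) >= 6L) {
    m <- matrix(x[seq_len(6L)], nrow = 1L,
                dimnames = list(NULL, crsr_subscales()))
  } else stop("cannot interpret input as CRS-R subscores", call. = FALSE)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite subscore values", call. = FALSE)
  m
}

#' Validate a cohort data frame
#'
#' Checks every row against the data contract: subscores within subscale
#' ranges, total equal to the subscore sum, age >= 18, unique ids, and
#' categorical fields drawn from their fixed token sets (`VS_UWS`/`MCS`,
#' `M`/`F`, `TBI`/`VASCULAR`/`HI_A`/`OTHER`, outcomes `eMCS`/`pDoC` or
#' missing).  Time post-injury outside 28-92 days (the study-entry window
#' for prolonged DoC) raises a warning, not an error.
#'
#' @param cohort Data frame with the columns of [read_cohort()].
#' @return The cohort, invisibly, with class `cdi_cohort` prepended.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(.cohort_columns(), names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cohort$id))
    stop("duplicate patient ids: ",
         paste(unique(cohort$id[duplicated(cohort$id)]), collapse = ", "),
         call. = FALSE)
  maxima <- crsr_subscale_max()
  bad_field <- function(row, field, msg)
    stop(sprintf("row %d (id %s): field '%s' %s", row,
                 as.character(cohort$id[row]), field, msg), call. = FALSE)
  for (i in seq_len(nrow(cohort))) {
    for (s in crsr_subscales()) {
      v <- cohort[[s]][i]
      if (is.na(v) || v != round(v) || v < 0 || v > maxima[[s]])
        bad_field(i, s, sprintf("= %s outside [0, %d]", format(v), maxima[[s]]))
    }
    tot <- cohort$total[i]
    ssum <- sum(as.numeric(cohort[i, crsr_subscales()]))
    if (is.na(tot) || tot != ssum)
      bad_field(i, "total", sprintf("= %s but subscores sum to %d",
                                    format(tot), as.integer(ssum)))
    if (is.na(cohort$age[i]) || cohort$age[i] < 18)
      bad_field(i, "age", "must be >= 18")
    if (!cohort$diagnosis[i] %in% .diagnosis_levels)
      bad_field(i, "diagnosis", paste("must be one of",
                                      paste(.diagnosis_levels, collapse = "/")))
    if (!cohort$sex[i] %in% .sex_levels)
      bad_field(i, "sex", "must be M or F")
    if (!cohort$etiology[i] %in% .etiology_levels)
      bad_field(i, "etiology", paste("must be one of",
                                     paste(.etiology_levels, collapse = "/")))
    for (oc in c("outcome_6m", "outcome_12m", "outcome_24m")) {
      v <- cohort[[oc]][i]
      if (!is.na(v) && !v %in% .outcome_levels)
        bad_field(i, oc, "must be eMCS, pDoC or missing")
    }
  }
  tpi <- cohort$time_post_injury
  out_of_window <- !is.na(tpi) & (tpi < 28 | tpi > 92)
  if (any(out_of_window))
    warning(sprintf("%d record(s) with time post-injury outside 28-92 days",
                    sum(out_of_window)), call. = FALSE)
  if (!inherits(cohort, "cdi_cohort"))
    class(cohort) <- c("cdi_cohort", class(cohort))
  invisible(cohort)
}

#' Read a patient cohort from CSV
#'
#' The dialect is comma-separated UTF-8 with a header naming the columns
#' `id`, the six subscales (`auditory`, `visual`, `motor`, `oromotor`,
#' `communication`, `arousal`), `total`, `diagnosis`, `age`, `sex`,
#' `etiology`, `time_post_injury`, and `outcome_6m`/`outcome_12m`/
#' `outcome_24m`; a missing outcome is an empty cell.  Row order is
#' preserved and every row is validated on ingest.
#'
#' @param path CSV file path.
#' @return A validated `cdi_cohort` data frame.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(.cohort_columns(), names(raw))
  if (length(missing_cols))
    stop("CSV header is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num <- function(col, field) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | !nzchar(raw[[col]]))
    if (length(bad))
      stop(sprintf("row %d: field '%s' is not numeric ('%s')",
                   bad[1], field, raw[[col]][bad[1]]), call. = FALSE)
    v
  }
  cohort <- data.frame(id = raw$id, stringsAsFactors = FALSE)
  for (s in crsr_subscales()) cohort[[s]] <- as.integer(num(s, s))
  cohort$total <- as.integer(num("total", "total"))
  cohort$diagnosis <- raw$diagnosis
  cohort$age <- num("age", "age")
  cohort$sex <- raw$sex
  cohort$etiology <- raw$etiology
  cohort$time_post_injury <- num("time_post_injury", "time_post_injury")
  for (oc in c("outcome_6m", "outcome_12m", "outcome_24m")) {
    v <- raw[[oc]]
    v[!nzchar(v)] <- NA_character_
    cohort[[oc]] <- v
  }
  validate_cohort(cohort)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: missing outcomes become empty cells and the
#' round-trip is field-identical.
#'
#' @param cohort A cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- as.data.frame(cohort)[, .cohort_columns()]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Has a patient emerged from the minimally conscious state?
#'
#' Emergence (eMCS, recovery of full consciousness) is operationalised as
#' functional communication (communication subscore at its maximum, 2)
#' and/or functional object use (motor subscore at its maximum, 6).
#'
#' @param crsr A cohort data frame, a subscore matrix, or a single record.
#' @return Logical vector, one entry per record.
#' @export
is_emergent <- function(crsr) {
  m <- as_subscore_matrix(crsr)
  maxima <- crsr_subscale_max()
  unname(m[, "communication"] == maxima[["communication"]] |
           m[, "motor"] == maxima[["motor"]])
}

#' Dichotomize the CRS-R total score at a cut-off
#'
#' Returns 1 iff `total >= cutoff` (the ">=" convention used for the
#' CRS-R 8 and CRS-R 10 binary predictors).
#'
#' @param total Integer total score(s), 0-23.
#' @param cutoff Integer cut-off, 0-23; the shipped pipeline uses 8 and 10.
#' @return Integer vector of 0/1.
#' @export
dichotomize_total <- function(total, cutoff) {
  stopifnot(length(cutoff) == 1L, cutoff >= 0, cutoff <= 23)
  if (any(!is.finite(total) | total < 0 | total > 23))
    stop("total score out of range [0, 23]", call. = FALSE)
  as.integer(total >= cutoff)
}

#' Median and IQR with Tukey inclusive hinges
#'
#' The interquartile range is Q3 - Q1 with quartiles computed as Tukey
#' hinges: each half of the sorted data includes the overall median when n
#' is odd.  This is the convention that reproduces the shipped reference
#' centroid summaries; it is `stats::fivenum()`'s definition.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `c(median =, iqr =)`.
#' @examples
#' median_iqr_hinges(c(2.42, 2.50, 2.33, 2.41, 2.27))  # 2.41, 0.09
#' @export
median_iqr_hinges <- function(values) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  fv <- stats::fivenum(unname(as.numeric(values)))
  c(median = fv[3], iqr = fv[4] - fv[2])
}
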