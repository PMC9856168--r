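# Univariate evaluation of binary predictors against binary outcomes:
# 2x2 contingency tables, uncorrected Pearson chi-square, and
# accuracy/sensitivity/specificity in both outcome orientations.

#' Build a 2x2 contingency table from binary vectors
#'
#' Rows index the predictor (positive, then negative), columns the outcome
#' (positive, then negative): `a` = predictor+/outcome+, `b` =
#' predictor+/outcome-, `c` = predictor-/outcome+, `d` =
#' predictor-/outcome-.
#'
#' @param predictions,outcomes Equal-length 0/1 vectors without missing
#'   entries.
#' @param row_label,col_label Text recorded for the orientation.
#' @return Object of class `cdi_contingency` with cells `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(predictions, outcomes,
                              row_label = "predictor", col_label = "outcome") {
  if (length(predictions) != length(outcomes))
    stop("predictions and outcomes differ in length", call. = FALSE)
  if (length(predictions) < 1L) stop("empty input", call. = FALSE)
  if (anyNA(predictions) || anyNA(outcomes))
    stop("missing entries are not allowed", call. = FALSE)
  if (!all(predictions %in% c(0, 1)) || !all(outcomes %in% c(0, 1)))
    stop("inputs must be binary 0/1", call. = FALSE)
  structure(list(
    a = sum(predictions == 1 & outcomes == 1),
    b = sum(predictions == 1 & outcomes == 0),
    c = sum(predictions == 0 & outcomes == 1),
    d = sum(predictions == 0 & outcomes == 0),
    row_label = row_label, col_label = col_label),
    class = "cdi_contingency")
}

#' Construct a contingency table directly from cell counts
#'
#' @param a,b,c,d Non-negative integer cell counts (see
#'   [build_contingency()] for the orientation).
#' @param row_label,col_label Orientation labels.
#' @return A `cdi_contingency`.
#' @export
contingency2x2 <- function(a, b, c, d, row_label = "predictor",
                           col_label = "outcome") {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells) | cells < 0 | cells != round(cells)))
    stop("cells must be non-negative integers", call. = FALSE)
  if (sum(cells) < 1) stop("table is empty", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d,
                 row_label = row_label, col_label = col_label),
            class = "cdi_contingency")
}

#' @export
print.cdi_contingency <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(paste(x$row_label, c("+", "-")),
                              paste(x$col_label, c("+", "-"))))
  print(m)
  invisible(x)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected (no Yates continuity correction):
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, referred to the chi-square
#' distribution with one degree of freedom.
#'
#' @param t A `cdi_contingency`.
#' @return List with `chi_square`, `df` (always 1) and `p_value`.
#' @export
chi_square_2x2 <- function(t) {
  stopifnot(inherits(t, "cdi_contingency"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  margins <- c("row 1 (predictor positive)" = a + b,
               "row 2 (predictor negative)" = c + d,
               "column 1 (outcome positive)" = a + c,
               "column 2 (outcome negative)" = b + d)
  zero <- margins == 0
  if (any(zero))
    stop("chi-square undefined: zero margin in ",
         paste(names(margins)[zero], collapse = ", "), call. = FALSE)
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(chi_square = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Accuracy is `(a + d) / n`.  Sensitivity and specificity depend on which
#' outcome column is declared positive: with `positive_class = "recovery"`
#' (outcome-positive column) sensitivity is `a / (a + c)` and specificity
#' `d / (b + d)`; with `"persistence"` the roles swap.  Both orientations
#' are meaningful for prognosis, so the choice is an explicit, recorded
#' parameter.  A zero column total yields `NA` for the affected metric with
#' an `undefined` flag rather than a silent 0.
#'
#' @param t A `cdi_contingency`.
#' @param positive_class `"recovery"` or `"persistence"`.
#' @return Object of class `cdi_diag_metrics`: chi-square results plus
#'   `accuracy`, `sensitivity`, `specificity`, `positive_class`,
#'   `undefined` (character vector of metrics that could not be computed).
#' @export
diagnostic_metrics <- function(t, positive_class = c("recovery", "persistence")) {
  stopifnot(inherits(t, "cdi_contingency"))
  positive_class <- match.arg(positive_class)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  chi <- tryCatch(chi_square_2x2(t),
                  error = function(e) list(chi_square = NA_real_, df = 1L,
                                           p_value = NA_real_))
  undefined <- character(0)
  col_pos <- a + c   # outcome-positive column total
  col_neg <- b + d
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(NA_real_) }
    num / den
  }
  if (positive_class == "recovery") {
    sens <- ratio(a, col_pos, "sensitivity")
    spec <- ratio(d, col_neg, "specificity")
  } else {
    sens <- ratio(d, col_neg, "sensitivity")
    spec <- ratio(a, col_pos, "specificity")
  }
  if (length(undefined))
    warning("undefined metric(s): ", paste(undefined, collapse = ", "),
            call. = FALSE)
  structure(list(chi_square = chi$chi_square, df = chi$df,
                 p_value = chi$p_value,
                 accuracy = (a + d) / n,
                 sensitivity = sens, specificity = spec,
                 positive_class = positive_class, undefined = undefined),
            class = "cdi_diag_metrics")
}

#' @export
print.cdi_diag_metrics <- function(x, ...) {
  cat(sprintf("chi-square = %.3f (df = %d), p %s\n", x$chi_square, x$df,
              format_p(x$p_value)))
  cat(sprintf("accuracy = %.3f, sensitivity = %.3f, specificity = %.3f (positive: %s)\n",
              x$accuracy, x$sensitivity, x$specificity, x$positive_class))
  invisible(x)
}

# display convention: very small p-values are shown as a threshold
format_p <- function(p, threshold = 0.001) {
  if (is.na(p)) return("= NA")
  if (p < threshold) sprintf("< %g", threshold) else sprintf("= %.3f", p)
}
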