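# Logistic-regression machinery for the prognostic battery: maximum
# likelihood via IRLS (stats::glm.fit), Wald inference, Nagelkerke
# pseudo-R2 and the rank-based AuROC.

#' Fit a logistic regression from a design matrix
#'
#' Maximum-likelihood fit by iteratively reweighted least squares.  The
#' design matrix is supplied explicitly (including its intercept column),
#' which keeps the battery's encodings — indicator variables against fixed
#' reference levels — under the caller's control.  Standard errors come
#' from the inverse observed information at the optimum; the score
#' equations are checked there, and quasi-separation (fitted probabilities
#' collapsing to 0/1 with diverging coefficients) is flagged rather than
#' silently reported.
#'
#' @param design Numeric n x p matrix, full column rank, n > p; include an
#'   intercept column.
#' @param y Binary 0/1 response containing both classes.
#' @return Object of class `cdi_logit`: `coefficients`, `se`, `covariance`,
#'   `loglik_model`, `loglik_null`, `n`, `nagelkerke_r2`, `auroc`,
#'   `or_table` (OR, 95% CI, Wald p per term), `fitted`,
#'   `linear_predictor`, `converged`, `separation`, `max_score`.
#' @export
fit_logistic <- function(design, y) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (length(y) != n) stop("design and response differ in length", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values in design or response", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("response contains a single class; model is not identifiable",
         call. = FALSE)
  if (n <= p) stop(sprintf("need n > p (n = %d, p = %d)", n, p), call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  beta <- fit$coefficients
  # Newton polish: glm.fit stops on relative deviance change, which can
  # leave the score equations satisfied only loosely when covariates are
  # on large scales (age in years, TPI in days).  Iterate to the score
  # tolerance, with step halving as a safeguard.
  loglik_at <- function(b) {
    mu <- stats::plogis(drop(X %*% b))
    sum(stats::dbinom(y, 1, mu, log = TRUE))
  }
  ll <- loglik_at(beta)
  for (it in seq_len(25L)) {
    mu <- stats::plogis(drop(X %*% beta))
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < 1e-8) break
    info <- crossprod(X, X * (mu * (1 - mu)))
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    accepted <- FALSE
    for (h in 0:10) {
      cand <- beta + step / 2^h
      ll_cand <- loglik_at(cand)
      if (is.finite(ll_cand) && ll_cand >= ll - 1e-12) {
        beta <- cand; ll <- ll_cand; accepted <- TRUE; break
      }
    }
    if (!accepted) break
  }
  mu <- stats::plogis(drop(X %*% beta))
  score <- drop(crossprod(X, y - mu))
  w <- mu * (1 - mu)
  info <- crossprod(X, X * w)
  covariance <- solve(info)
  se <- sqrt(diag(covariance))
  separation <- any(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(beta) > 15)
  converged <- isTRUE(fit$converged) && (max(abs(score)) < 1e-6 || separation)
  if (!converged)
    warning("IRLS did not converge to the score tolerance", call. = FALSE)
  if (separation)
    warning("quasi-separation detected: estimates and CIs are unstable",
            call. = FALSE)
  eta <- drop(X %*% beta)
  loglik_model <- sum(stats::dbinom(y, 1, mu, log = TRUE))
  pbar <- mean(y)
  loglik_null <- n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
  zp <- 2 * stats::pnorm(-abs(beta / se))
  ors <- t(vapply(seq_len(p),
                  function(j) wald_or_ci(beta[j], se[j]), numeric(3)))
  or_table <- data.frame(term = colnames(X), estimate = unname(beta),
                         se = unname(se), OR = ors[, 1],
                         ci_lower = ors[, 2], ci_upper = ors[, 3],
                         p_value = unname(zp), row.names = NULL)
  structure(list(coefficients = beta, se = se, covariance = covariance,
                 loglik_model = loglik_model, loglik_null = loglik_null,
                 n = n,
                 nagelkerke_r2 = nagelkerke_r2(loglik_model, loglik_null, n),
                 auroc = auroc(eta, y),
                 or_table = or_table, fitted = mu, linear_predictor = eta,
                 converged = converged, separation = separation,
                 max_score = max(abs(score))),
            class = "cdi_logit")
}

#' @export
print.cdi_logit <- function(x, ...) {
  cat(sprintf("logistic fit: n = %d, Nagelkerke R2 = %.3f, AuROC = %.3f\n",
              x$n, x$nagelkerke_r2, x$auroc))
  if (x$separation) cat("(quasi-separation flagged)\n")
  tab <- x$or_table
  tab[-1] <- lapply(tab[-1], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Nagelkerke pseudo-R-squared
#'
#' Rescales the Cox-Snell R2,
#' `1 - exp(2 (loglik_null - loglik_model) / n)`, by its maximum attainable
#' value `1 - exp(2 loglik_null / n)` so the index ranges 0-1, with 0 for a
#' model no better than the intercept and 1 for a perfect fit.
#'
#' @param loglik_model,loglik_null Model and intercept-only log-likelihoods
#'   (`loglik_model >= loglik_null`).
#' @param n Number of observations.
#' @return Number in [0, 1].
#' @export
nagelkerke_r2 <- function(loglik_model, loglik_null, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (loglik_model < loglik_null - 1e-8)
    stop("loglik_model must be >= loglik_null", call. = FALSE)
  r2_cs <- 1 - exp(2 * (loglik_null - loglik_model) / n)
  denom <- 1 - exp(2 * loglik_null / n)
  if (denom <= 0) stop("degenerate null log-likelihood", call. = FALSE)
  min(max(r2_cs / denom, 0), 1)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive case receives a higher score than a randomly chosen negative
#' case, with ties counted one half.  Computed from midranks, so it is
#' exact and O(n log n).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param y Binary 0/1 outcome containing both classes.
#' @return AuROC in [0, 1].
#' @export
auroc <- function(scores, y) {
  y <- as.numeric(y)
  stopifnot(length(scores) == length(y))
  if (anyNA(scores) || anyNA(y)) stop("missing values", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both outcome classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Wald confidence interval for an odds ratio
#'
#' @param coefficient Log-odds coefficient.
#' @param se Its standard error (> 0).
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(OR, lower, upper)`.
#' @export
wald_or_ci <- function(coefficient, se, level = 0.95) {
  stopifnot(is.finite(coefficient), is.finite(se), se > 0,
            level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(OR = exp(coefficient), lower = exp(coefficient - z * se),
    upper = exp(coefficient + z * se))
}
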