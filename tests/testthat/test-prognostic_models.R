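test_that("logistic fits reproduce closed forms and satisfy score equations", {
  # intercept-only: coefficient is logit of the response mean
  y <- c(rep(1, 30), rep(0, 70))
  f0 <- fit_logistic(matrix(1, 100, 1, dimnames = list(NULL, "intercept")), y)
  expect_equal(unname(f0$coefficients), qlogis(0.3), tolerance = 1e-8)

  # saturated 2x2: slope equals the log odds ratio of the table (45,19,9,70)
  x <- c(rep(1, 64), rep(0, 79))
  y <- c(rep(1, 45), rep(0, 19), rep(1, 9), rep(0, 70))
  f <- fit_logistic(cbind(intercept = 1, predictor = x), y)
  expect_equal(unname(f$coefficients["predictor"]),
               log((45 * 70) / (19 * 9)), tolerance = 1e-8)
  expect_lt(f$max_score, 1e-6)

  # agreement with the standard modelling interface, coefficients and SEs
  set.seed(14)
  X <- cbind(intercept = 1, a = rnorm(300), b = rbinom(300, 1, 0.4))
  yy <- rbinom(300, 1, plogis(-0.3 + 0.8 * X[, "a"] - 0.5 * X[, "b"]))
  fit <- fit_logistic(X, yy)
  ref <- glm(yy ~ X[, "a"] + X[, "b"], family = binomial)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-3)
  expect_equal(fit$loglik_model, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(fit$loglik_null,
               as.numeric(logLik(glm(yy ~ 1, family = binomial))),
               tolerance = 1e-8)
})

test_that("logistic fit rejects ill-posed problems and flags separation", {
  X <- cbind(intercept = 1, x1 = 1:20, x2 = 2 * (1:20))
  expect_error(fit_logistic(X, rep(c(0, 1), 10)), "collinear.*x2")
  expect_error(fit_logistic(X[, 1:2], rep(1, 20)), "single class")
  # perfectly separated predictor
  xs <- c(rep(0, 10), rep(1, 10))
  expect_warning(fs <- fit_logistic(cbind(intercept = 1, x = xs), xs),
                 "separation")
  expect_true(fs$separation)
})

test_that("Nagelkerke R2 matches its formula, bounds and monotonicity", {
  expect_equal(nagelkerke_r2(-50, -50, 100), 0)
  expect_equal(nagelkerke_r2(0, -60, 100), 1)   # perfect fit
  set.seed(3)
  for (rep in 1:50) {
    n <- sample(20:500, 1)
    ll0 <- -runif(1, 1, n)
    llm <- ll0 + runif(1, 0, abs(ll0))
    direct <- (1 - exp(2 * (ll0 - llm) / n)) / (1 - exp(2 * ll0 / n))
    expect_equal(nagelkerke_r2(llm, ll0, n), direct, tolerance = 1e-12)
  }
  r2s <- vapply(seq(-40, -1, length.out = 30),
                function(llm) nagelkerke_r2(llm, -40, 80), numeric(1))
  expect_true(all(diff(r2s) >= 0))
  expect_error(nagelkerke_r2(-50, -40, 100), "loglik_model")
})

test_that("AuROC is the tie-aware pair-counting probability", {
  expect_equal(auroc(c(1, 2, 3, 11, 12), c(0, 0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(2, 10), rep(c(0, 1), 5)), 0.5)   # all ties
  set.seed(77)
  for (rep in 1:5) {
    sc <- sample(round(rnorm(200), 1))   # rounding forces ties
    y <- rbinom(200, 1, 0.5)
    expect_equal(auroc(sc, y), auroc_pair_oracle(sc, y), tolerance = 1e-12)
    expect_equal(auroc(sc, y) + auroc(-sc, y), 1, tolerance = 1e-12)
  }
  expect_error(auroc(1:5, rep(1, 5)), "both")
})

test_that("fitted-probability and linear-predictor AuROC coincide", {
  set.seed(10)
  X <- cbind(intercept = 1, x = rnorm(150), z = rbinom(150, 1, 0.5))
  y <- rbinom(150, 1, plogis(X %*% c(-0.5, 1, 0.7)))
  f <- fit_logistic(X, y)
  expect_equal(auroc(f$fitted, y), auroc(f$linear_predictor, y),
               tolerance = 1e-12)
  expect_equal(f$auroc, auroc(f$linear_predictor, y))
  skip_if_not_installed("pROC")
  expect_equal(f$auroc,
               as.numeric(pROC::auc(pROC::roc(y, f$linear_predictor,
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("Wald odds-ratio intervals have the right form", {
  ci <- wald_or_ci(0, 0.4)
  expect_equal(unname(ci["OR"]), 1)
  expect_equal(log(ci["lower"]) + log(ci["upper"]), 0, ignore_attr = TRUE)
  ci2 <- wald_or_ci(2.914, 0.5)
  expect_equal(unname(ci2), c(exp(2.914), exp(2.914 - 1.959964 * 0.5),
                              exp(2.914 + 1.959964 * 0.5)), tolerance = 1e-6)
  set.seed(2)
  for (rep in 1:20) {
    b <- rnorm(1); s <- runif(1, 0.05, 2); lev <- runif(1, 0.5, 0.99)
    ci <- wald_or_ci(b, s, lev)
    expect_true(ci["lower"] <= ci["OR"] && ci["OR"] <= ci["upper"])
    expect_equal(log(ci["upper"]) - log(ci["lower"]),
                 2 * qnorm(1 - (1 - lev) / 2) * s, ignore_attr = TRUE)
  }
})

test_that("the battery fits all predictor-by-follow-up combinations", {
  g <- generate_cohort(generator_config(n = 120, seed = 301))
  b <- run_model_battery(g$cohort, cdi_builtin_model())
  expect_length(b, 15)
  expect_setequal(names(b),
                  as.vector(outer(c("CDI", "diagnosis", "CRSR8", "CRSR10",
                                    "CRSR_total"),
                                  c(6, 12, 24), function(p, f)
                                    sprintf("%s_%dm", p, f))))
  rep <- battery_report(b)
  expect_true(all(rep$nagelkerke_r2 >= 0 & rep$nagelkerke_r2 <= 1))
  expect_true(all(rep$auroc >= 0 & rep$auroc <= 1))
  expect_true(all(rep$ci_lower <= rep$OR & rep$OR <= rep$ci_upper))
  # per-follow-up missing-outcome exclusion
  co <- as.data.frame(g$cohort)
  co$outcome_12m[1:10] <- NA
  b2 <- run_model_battery(co, cdi_builtin_model())
  expect_equal(attr(b2, "specs")$CDI_12m$n, 110)
  expect_equal(attr(b2, "specs")$CDI_6m$n, 120)
})

test_that("identical dichotomizations give identical panels", {
  g <- generate_cohort(generator_config(n = 90, seed = 12))
  co <- as.data.frame(g$cohort)
  # push every total out of the 8-9 band so >=8 and >=10 coincide
  shift <- co$total %in% c(8, 9)
  co$motor[shift] <- pmin(co$motor[shift] + (10 - co$total[shift]), 6)
  co$total <- co$auditory + co$visual + co$motor + co$oromotor +
    co$communication + co$arousal
  keep <- !(co$total %in% c(8, 9))
  co <- co[keep, ]
  co$id <- sprintf("K%03d", seq_len(nrow(co)))
  b <- run_model_battery(co, cdi_builtin_model(), follow_ups = 6L)
  expect_equal(b$CRSR8_6m$coefficients, b$CRSR10_6m$coefficients,
               ignore_attr = TRUE)
})

test_that("a generator driven purely by the CDI favours the CDI panel", {
  cfg_coefs <- c(intercept = -1.2, cdi = 2.5, age = 0, sex_F = 0, tpi = 0,
                 etiology_TBI = 0, etiology_HIA = 0)
  wins <- 0L
  for (i in 1:40) {
    g <- generate_cohort(generator_config(
      n = 143, outcome_coefs = cfg_coefs, diagnosis_flip = 0.15,
      seed = 5000 + i))
    b <- run_model_battery(g$cohort, cdi_builtin_model(), follow_ups = 6L)
    wins <- wins + (b$CDI_6m$nagelkerke_r2 > b$diagnosis_6m$nagelkerke_r2)
  }
  expect_gte(wins / 40, 0.9)
})
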