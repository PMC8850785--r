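# Expanded CDF, censored likelihood, MLE, Wald test, relevance rule,
# family selection and fit quality.

test_that("expanded CDF matches closed forms and limits", {
  expect_equal(expanded_cdf(exp(4.22), 0, 4.22, 0, 0.46), 0.5)
  expect_equal(expanded_cdf(exp(4.0 + 0.7 * 0.5), 0.7, 4.0, 0.5, 0.3), 0.5)
  expect_equal(expanded_cdf(112.77, 0, 4.22, 0, 0.46), 0.75,
               tolerance = 1e-4)
  expect_lt(expanded_cdf(1e-8, 0, 4.22, 0, 0.46), 1e-6)
  expect_gt(expanded_cdf(1e8, 0, 4.22, 0, 0.46), 1 - 1e-6)
  expect_error(expanded_cdf(-1, 0, 4, 0, 0.3),
               class = "painlimits_domain_error")
})

test_that("censored log-likelihood matches closed forms", {
  b0 <- 4.1; a <- 0.35
  # exact observation at the median of the log-logistic
  d_exact <- tibble::tibble(x = 0, y = exp(b0), L = exp(b0), R = exp(b0),
                            censor_type = "exact")
  expect_equal(painlimits:::aft_loglik(b0, 0, a, d_exact, mode = "exact"),
               -log(4 * a * exp(b0)), tolerance = 1e-12)
  expect_equal(painlimits:::aft_loglik(b0, 0, a, d_exact, mode = "interval"),
               -log(4 * a * exp(b0)), tolerance = 1e-12)

  # right-censored at the median: survival probability 1/2
  d_right <- tibble::tibble(x = 0, y = exp(b0), L = exp(b0), R = Inf,
                            censor_type = "right")
  expect_equal(painlimits:::aft_loglik(b0, 0, a, d_right, mode = "interval"),
               log(0.5), tolerance = 1e-12)

  # interval holding probability mass F(R) - F(L) = 0.8 - 0.3
  d_int <- tibble::tibble(
    x = 0, y = NA,
    L = exp(b0 + a * qlogis(0.3)), R = exp(b0 + a * qlogis(0.8)),
    censor_type = "interval")
  expect_equal(painlimits:::aft_loglik(b0, 0, a, d_int, mode = "interval"),
               log(0.5), tolerance = 1e-12)
})

test_that("MLE recovers the generating parameters", {
  smp <- make_exact_sample(400, 4.0, 0.5, 0.3, seed = 11)
  fit <- fit_aft(smp)
  se <- sqrt(diag(fit$covariance))
  expect_lt(abs(fit$beta0 - 4.0), 3 * se["beta0"])
  expect_lt(abs(fit$beta1 - 0.5), 3 * se["beta1"])
  expect_lt(abs(fit$alpha - 0.3), 3 * se["alpha"])
  expect_true(fit$convergence)
})

test_that("constrained fit is nested in the unconstrained fit", {
  smp <- make_exact_sample(60, 4.0, 0.4, 0.3, seed = 12)
  free <- fit_aft(smp)
  cons <- fit_aft(smp, constrain_beta1_zero = TRUE)
  expect_identical(cons$beta1, 0)
  expect_lte(cons$log_likelihood, free$log_likelihood + 1e-8)

  # single-gender samples cannot identify the gender effect
  mono <- make_exact_sample(30, 4.0, 0, 0.3, male_fraction = 1, seed = 13)
  expect_error(fit_aft(mono), class = "painlimits_identifiability_error")
  expect_s3_class(fit_aft(mono, constrain_beta1_zero = TRUE), "aft_fit")
  expect_error(fit_aft(mono[1:2, ], constrain_beta1_zero = TRUE),
               class = "painlimits_invalid_argument")
})

test_that("optimizer attains at least the grid-search oracle optimum", {
  truth <- c(4.0, 0.4, 0.3)
  smp <- make_exact_sample(30, truth[1], truth[2], truth[3], seed = 14)
  fit <- fit_aft(smp)
  data <- tibble::tibble(x = smp$gender_code, y = smp$y_bar)
  grid <- expand.grid(b0 = truth[1] + seq(-0.5, 0.5, by = 0.05),
                      b1 = truth[2] + seq(-0.5, 0.5, by = 0.05),
                      a = truth[3] * exp(seq(-0.7, 0.7, by = 0.07)))
  ll <- mapply(function(b0, b1, a) {
    painlimits:::aft_loglik(b0, b1, a, data, mode = "exact")
  }, grid$b0, grid$b1, grid$a)
  expect_lte(max(ll), fit$log_likelihood + 1e-4)
})

test_that("exact-mode MLE agrees with the survival-package oracle", {
  skip_if_not_installed("survival")
  smp <- make_exact_sample(200, 3.9, 0.45, 0.28, seed = 15)
  fit <- fit_aft(smp)
  sr <- survival::survreg(
    survival::Surv(smp$y_bar) ~ smp$gender_code, dist = "loglogistic")
  expect_equal(fit$beta0, unname(sr$coefficients[1]), tolerance = 1e-4)
  expect_equal(fit$beta1, unname(sr$coefficients[2]), tolerance = 1e-4)
  expect_equal(fit$alpha, sr$scale, tolerance = 1e-4)

  # interval mode on censored observations against the same oracle
  pop <- sample_population(120, 0.5, seed = 16)
  thr <- draw_threshold(120, 4.2, 0.4, 0.3, gender_code = pop$gender_code,
                        seed = 17)
  L <- thr * 0.9
  R <- thr * 1.1
  smp2 <- tibble::tibble(subject_id = pop$subject_id,
                         gender_code = pop$gender_code,
                         y_bar = (L + R) / 2, n_repeats = 1,
                         L_bar = L, R_bar = R, censor_type = "interval",
                         all_right_censored = FALSE)
  fit2 <- fit_aft(smp2, mode = "interval")
  sr2 <- survival::survreg(
    survival::Surv(L, R, type = "interval2") ~ smp2$gender_code,
    dist = "loglogistic")
  expect_equal(fit2$beta0, unname(sr2$coefficients[1]), tolerance = 1e-4)
  expect_equal(fit2$beta1, unname(sr2$coefficients[2]), tolerance = 1e-4)
  expect_equal(fit2$alpha, sr2$scale, tolerance = 1e-4)
})

test_that("Wald p-values follow the normal reference", {
  cov3 <- diag(c(0.01, 0.04, 0.001))
  dimnames(cov3) <- list(c("beta0", "beta1", "alpha"),
                         c("beta0", "beta1", "alpha"))
  fake <- structure(list(beta0 = 4, beta1 = 0, alpha = 0.3,
                         covariance = cov3, constrained = FALSE),
                    class = "aft_fit")
  expect_equal(wald_p_value(fake), 1)
  fake$beta1 <- 1.96 * 0.2
  expect_equal(wald_p_value(fake), 0.05, tolerance = 1e-3)

  fake$constrained <- TRUE
  expect_error(wald_p_value(fake), class = "painlimits_degenerate_test")
})

test_that("gender relevance requires two significant conditions", {
  expect_true(gender_relevance(c(0.007, 0.050, 0.017, 0.020))$relevant)
  expect_equal(gender_relevance(c(0.007, 0.050, 0.017, 0.020))$n_significant,
               3) # 0.050 is not < 0.05
  expect_false(gender_relevance(c(0.098, 0.455, 0.098, 0.214))$relevant)
  expect_false(gender_relevance(c(0.04, 0.2, 0.2, 0.2))$relevant)
  expect_true(gender_relevance(c(0.04, 0.2, 0.2, 0.2), sigma = 0.3)$relevant)
})

test_that("family selection identifies the generating family", {
  ll_hits <- vapply(1:40, function(s) {
    smp <- make_exact_sample(500, 4.0, 0, 0.3, seed = 5000 + s)
    select_family(smp, constrain_beta1_zero = TRUE)$family == "log-logistic"
  }, logical(1))
  expect_gte(mean(ll_hits), 0.9)

  ln_hits <- vapply(1:40, function(s) {
    pop <- sample_population(500, 0.5, seed = 6000 + s)
    withr::with_seed(6000 + s, {
      y <- exp(rnorm(500, 4.0, 0.3))
    })
    smp <- sample_from_y(y, pop$gender_code)
    select_family(smp, constrain_beta1_zero = TRUE)$family == "log-normal"
  }, logical(1))
  expect_gte(mean(ln_hits), 0.8)

  expect_error(select_family(make_exact_sample(7, 4, 0, 0.3, seed = 1)),
               class = "painlimits_invalid_argument")
})

test_that("fit quality is 1 for data on the model quantiles", {
  b0 <- 4.3; a <- 0.25; n <- 50
  y <- loglogistic_quantile((seq_len(n) - 0.5) / n, b0, 0, a)
  smp <- sample_from_y(y, rep(0, n))
  fake <- list(beta0 = b0, beta1 = 0, alpha = a, family = "log-logistic")
  expect_equal(fit_r_squared(fake, smp), 1, tolerance = 1e-9)

  # shuffling the quantile pairing can only reduce the correlation
  smp_real <- make_exact_sample(40, 4.0, 0.3, 0.3, seed = 18)
  fit <- fit_aft(smp_real)
  r2_sorted <- fit_r_squared(fit)
  y_adj <- smp_real$y_bar / exp(smp_real$gender_code * fit$beta1)
  p <- (seq_len(40) - 0.5) / 40
  q <- loglogistic_quantile(p, fit$beta0, 0, fit$alpha)
  set.seed(19)
  r2_shuffled <- cor(sample(y_adj), q)^2
  expect_lt(r2_shuffled, r2_sorted)
})

test_that("broom-style accessors summarize the fit", {
  smp <- make_exact_sample(60, 4.0, 0.4, 0.3, seed = 20)
  fit <- fit_aft(smp)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("beta0", "beta1", "alpha"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_equal(gl$nobs, 60)
  expect_equal(gl$logLik, fit$log_likelihood)
  expect_s3_class(autoplot(fit), "ggplot")
})
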