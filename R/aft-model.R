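# Parametric threshold model: log-logistic (or Weibull / log-normal) CDF with
# the gender covariate absorbed into the location term through an accelerated
# failure time regression, fitted by maximum likelihood on exact or
# interval-censored per-subject observations.

aft_families <- c("log-logistic", "weibull", "log-normal")

# Standardized log-scale CDF / log-density of the supported families:
# z = (log y - beta0 - x*beta1) / alpha.
family_std_cdf <- function(z, family) {
  switch(family,
         "log-logistic" = plogis(z),
         "weibull" = 1 - exp(-exp(z)),
         "log-normal" = pnorm(z))
}

family_std_logpdf <- function(z, family) {
  switch(family,
         "log-logistic" = stats::dlogis(z, log = TRUE),
         "weibull" = z - exp(z),
         "log-normal" = dnorm(z, log = TRUE))
}

family_std_quantile <- function(p, family) {
  switch(family,
         "log-logistic" = qlogis(p),
         "weibull" = log(-log(1 - p)),
         "log-normal" = qnorm(p))
}

#' Expanded log-logistic CDF with a gender-mix covariate
#'
#' Probability that the pain threshold of a group with male fraction `x_G`
#' lies below `y`:
#' `F(y, x_G) = [1 + exp(-(log y - beta0 - x_G*beta1)/alpha)]^-1`.
#' With `x_G = 0` this is the plain log-logistic CDF; fractional `x_G`
#' represents a mixed-gender group through the accelerated-failure-time shift
#' `exp(x_G * beta1)` of the threshold scale.
#'
#' @param y Threshold value(s), > 0.
#' @param x_G Male fraction in `[0, 1]`.
#' @param beta0,beta1,alpha Model parameters (`alpha > 0`).
#' @return Probabilities in `[0, 1]`.
#' @export
expanded_cdf <- function(y, x_G = 0, beta0, beta1 = 0, alpha) {
  if (any(y <= 0)) abort("`y` must be > 0.", class = "painlimits_domain_error")
  if (any(x_G < 0 | x_G > 1)) abort("`x_G` must be in [0, 1].", class = "painlimits_domain_error")
  if (any(alpha <= 0)) abort("`alpha` must be > 0.", class = "painlimits_invalid_argument")
  plogis((log(y) - beta0 - x_G * beta1) / alpha)
}

# Censored-data log-likelihood. `data` rows carry the covariate `x` and
# either an exact value `y`, or bounds `L`/`R` with `censor_type`.
aft_loglik <- function(beta0, beta1, alpha, data, family = "log-logistic",
                       mode = c("exact", "interval")) {
  mode <- match.arg(mode)
  mu <- beta0 + data$x * beta1
  if (mode == "exact") {
    z <- (log(data$y) - mu) / alpha
    ll <- sum(family_std_logpdf(z, family) - log(alpha) - log(data$y))
  } else {
    ll <- 0
    for (ct in unique(data$censor_type)) {
      d <- data[data$censor_type == ct, ]
      m <- mu[data$censor_type == ct]
      term <- switch(ct,
        exact = {
          z <- (log(d$L) - m) / alpha
          family_std_logpdf(z, family) - log(alpha) - log(d$L)
        },
        left = log(family_std_cdf((log(d$R) - m) / alpha, family)),
        right = log(1 - family_std_cdf((log(d$L) - m) / alpha, family)),
        interval = log(family_std_cdf((log(d$R) - m) / alpha, family) -
                         family_std_cdf((log(d$L) - m) / alpha, family)))
      ll <- ll + sum(term)
    }
  }
  if (!is.finite(ll)) return(-Inf)
  ll
}

# Deterministic multi-start offsets in (beta0, beta1, log alpha).
.start_offsets <- rbind(c(0, 0, 0), c(0.3, 0, 0.3), c(-0.3, 0, -0.3),
                        c(0, 0.4, 0), c(0.3, -0.4, -0.3))

#' Fit the expanded threshold model by maximum likelihood
#'
#' Estimates `beta0` (log-scale intercept), `beta1` (gender effect) and
#' `alpha` (shape) of the expanded CDF for one sample of per-subject
#' thresholds. The default mode treats the midpoint-imputed subject means as
#' exact observations (the descriptive pipeline order); the interval mode
#' maximizes the censored-data likelihood on the per-subject mean intervals
#' instead. Optimization is quasi-Newton over `(beta0, beta1, log alpha)`
#' with deterministic multi-starts seeded from moment estimates; the
#' covariance is the inverse observed information, mapped back to the
#' `(beta0, beta1, alpha)` scale.
#'
#' @param sample Sample tibble from [assemble_sample()] (needs `y_bar`,
#'   `gender_code`, and for interval mode `L_bar`, `R_bar`, `censor_type`).
#' @param family One of `"log-logistic"`, `"weibull"`, `"log-normal"`.
#' @param constrain_beta1_zero Fit with the gender effect fixed at zero.
#' @param mode `"exact"` or `"interval"`.
#' @return An `aft_fit` object.
#' @export
fit_aft <- function(sample, family = "log-logistic",
                    constrain_beta1_zero = FALSE,
                    mode = c("exact", "interval")) {
  mode <- match.arg(mode)
  family <- match.arg(family, aft_families)
  n <- nrow(sample)
  if (n < 3) abort("need at least 3 subjects.", class = "painlimits_invalid_argument")
  x <- sample$gender_code
  if (!constrain_beta1_zero && length(unique(x)) < 2) {
    abort("single-gender sample cannot identify the gender effect.",
          class = "painlimits_identifiability_error")
  }
  data <- tibble::tibble(x = x, y = sample$y_bar)
  if (mode == "interval") {
    data$L <- sample$L_bar
    data$R <- sample$R_bar
    data$censor_type <- sample$censor_type
  }

  ly <- log(pmax(sample$y_bar, .Machine$double.xmin))
  b1_start <- if (constrain_beta1_zero || length(unique(x)) < 2) 0 else
    mean(ly[x == 1]) - mean(ly[x == 0])
  b0_start <- mean(ly - x * b1_start)
  a_start <- max(sd(ly - x * b1_start) * sqrt(3) / pi, 1e-3)

  obj <- if (constrain_beta1_zero) {
    function(par) -aft_loglik(par[1], 0, exp(par[2]), data, family, mode)
  } else {
    function(par) -aft_loglik(par[1], par[2], exp(par[3]), data, family, mode)
  }
  base <- if (constrain_beta1_zero) c(b0_start, log(a_start)) else
    c(b0_start, b1_start, log(a_start))
  sel <- if (constrain_beta1_zero) c(1, 3) else 1:3
  offs <- .start_offsets[, sel, drop = FALSE]
  fits <- lapply(seq_len(nrow(offs)), function(i) {
    tryCatch(optim(base + offs[i, ], obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
             error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  fits <- purrr::keep(fits, ~ is.finite(.x$value))
  if (!length(fits)) {
    abort("maximum-likelihood fit failed for all starts.",
          class = "painlimits_fit_failure")
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]

  par <- best$par
  alpha <- exp(par[length(par)])
  beta0 <- par[1]
  beta1 <- if (constrain_beta1_zero) 0 else par[2]
  H <- tryCatch(optimHess(par, obj), error = function(e) NULL)
  covariance <- NULL
  if (!is.null(H)) {
    covt <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(covt)) {
      J <- diag(length(par))
      J[length(par), length(par)] <- alpha # log alpha -> alpha
      covariance <- J %*% covt %*% J
      dimnames(covariance) <- if (constrain_beta1_zero)
        list(c("beta0", "alpha"), c("beta0", "alpha")) else
        list(c("beta0", "beta1", "alpha"), c("beta0", "beta1", "alpha"))
    }
  }

  fit <- structure(list(
    family = family, beta0 = beta0, beta1 = beta1, alpha = alpha,
    covariance = covariance, log_likelihood = -best$value,
    constrained = constrain_beta1_zero, mode = mode, n_used = n,
    convergence = best$convergence == 0, sample = sample),
    class = "aft_fit")
  fit$p_beta1 <- if (constrain_beta1_zero) NA_real_ else wald_p_value(fit)
  fit$r_squared <- fit_r_squared(fit, sample)
  fit
}

#' @export
print.aft_fit <- function(x, ...) {
  cat(sprintf(
    "<aft_fit: %s%s, n = %d>\n  beta0 = %.3f, beta1 = %.3f, alpha = %.3f\n  logLik = %.2f, p(beta1) = %s, R^2 = %.3f\n",
    x$family, if (x$constrained) " (beta1 = 0)" else "", x$n_used,
    x$beta0, x$beta1, x$alpha, x$log_likelihood,
    ifelse(is.na(x$p_beta1), "-", format.pval(x$p_beta1, digits = 3)),
    x$r_squared))
  invisible(x)
}

#' Wald test of the gender effect
#'
#' Two-sided p-value for the null hypothesis that the gender effect `beta1`
#' is zero, from `z = beta1 / SE(beta1)` against the standard normal.
#'
#' @param fit An unconstrained `aft_fit` with a valid covariance.
#' @return The p-value.
#' @export
wald_p_value <- function(fit) {
  if (fit$constrained || is.null(fit$covariance)) {
    abort("need an unconstrained fit with a covariance.",
          class = "painlimits_degenerate_test")
  }
  se <- sqrt(fit$covariance["beta1", "beta1"])
  if (!is.finite(se) || se <= 0) {
    abort("invalid standard error for beta1.", class = "painlimits_degenerate_test")
  }
  2 * pnorm(-abs(fit$beta1 / se))
}

#' Decide whether gender is relevant for a body location
#'
#' The gender covariate is kept for a body location only if its effect is
#' significant (`p < sigma`) for at least two of the location's test
#' conditions; otherwise the location is refitted with `beta1 = 0`.
#'
#' @param p_values Numeric vector of per-condition p-values (1 to 4).
#' @param sigma Significance level (default 0.05).
#' @return A list: `relevant`, `n_significant`, `p_values`, `sigma`.
#' @export
gender_relevance <- function(p_values, sigma = 0.05) {
  stopifnot(length(p_values) >= 1, length(p_values) <= 4)
  n_sig <- sum(p_values < sigma, na.rm = TRUE)
  list(relevant = n_sig >= 2, n_significant = n_sig,
       p_values = p_values, sigma = sigma)
}

# Anderson-Darling statistic of probability-integral-transformed values.
ad_statistic <- function(u) {
  u <- sort(pmin(pmax(u, 1e-12), 1 - 1e-12))
  n <- length(u)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

#' Select the distribution family by Anderson-Darling fit
#'
#' Fits all three candidate families to the sample and returns the one whose
#' fitted CDF leaves the smallest Anderson-Darling statistic on the
#' probability-integral-transformed subject means (each transformed with its
#' own gender covariate). Ties break toward the log-logistic.
#'
#' @param sample Sample tibble (at least 8 subjects).
#' @param constrain_beta1_zero Passed to [fit_aft()].
#' @param mode Fit mode passed to [fit_aft()].
#' @return A list: `family`, `statistics` (named vector), `fits`.
#' @export
select_family <- function(sample, constrain_beta1_zero = FALSE,
                          mode = "exact") {
  if (nrow(sample) < 8) {
    abort("family selection needs at least 8 subjects.",
          class = "painlimits_invalid_argument")
  }
  fits <- purrr::map(setNames(aft_families, aft_families), function(fam) {
    tryCatch(fit_aft(sample, family = fam,
                     constrain_beta1_zero = constrain_beta1_zero, mode = mode),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) abort("all family fits failed.", class = "painlimits_selection_error")
  stat <- vapply(fits[ok], function(f) {
    z <- (log(sample$y_bar) - f$beta0 - sample$gender_code * f$beta1) / f$alpha
    ad_statistic(family_std_cdf(z, f$family))
  }, numeric(1))
  # ties toward the log-logistic: it sorts first among equals
  ordered <- stat[order(stat, match(names(stat), aft_families))]
  list(family = names(ordered)[1], statistics = stat, fits = fits[ok])
}

#' Quantile-quantile fit quality
#'
#' Coefficient of determination of the fitted CDF: the squared Pearson
#' correlation between the sorted gender-adjusted subject means (each divided
#' by its own `exp(x * beta1)` shift) and the base-model quantiles at the
#' plotting positions `(i - 0.5)/N`.
#'
#' @param fit An `aft_fit`.
#' @param sample The sample the fit was computed on (default: the fit's own).
#' @return R-squared in `[0, 1]`.
#' @export
fit_r_squared <- function(fit, sample = fit$sample) {
  n <- nrow(sample)
  if (n < 3) abort("R^2 undefined for fewer than 3 subjects.",
                   class = "painlimits_invalid_argument")
  y_adj <- sort(sample$y_bar / exp(sample$gender_code * fit$beta1))
  p <- (seq_len(n) - 0.5) / n
  q <- exp(fit$beta0 + fit$alpha * family_std_quantile(p, fit$family))
  cor(y_adj, q)^2
}

#' @describeIn fit_aft Tidy per-parameter summary (estimate, standard error,
#'   Wald statistic and p-value).
#' @param x,object An `aft_fit`.
#' @param ... Unused.
#' @method tidy aft_fit
#' @export
tidy.aft_fit <- function(x, ...) {
  terms <- if (x$constrained) c("beta0", "alpha") else c("beta0", "beta1", "alpha")
  est <- c(beta0 = x$beta0, beta1 = x$beta1, alpha = x$alpha)[terms]
  se <- if (is.null(x$covariance)) rep(NA_real_, length(terms)) else
    sqrt(diag(x$covariance))
  stat <- est / se
  tibble::tibble(term = terms, estimate = unname(est), std.error = unname(se),
                 statistic = unname(stat),
                 p.value = 2 * pnorm(-abs(unname(stat))))
}

#' @describeIn fit_aft One-row model summary.
#' @method glance aft_fit
#' @export
glance.aft_fit <- function(x, ...) {
  tibble::tibble(family = x$family, nobs = x$n_used,
                 logLik = x$log_likelihood, r.squared = x$r_squared,
                 p.beta1 = x$p_beta1, constrained = x$constrained,
                 converged = x$convergence)
}

#' @describeIn fit_aft Empirical distribution of the gender-adjusted subject
#'   means against the fitted base CDF.
#' @method autoplot aft_fit
#' @export
autoplot.aft_fit <- function(object, ...) {
  s <- object$sample
  y_adj <- sort(s$y_bar / exp(s$gender_code * object$beta1))
  grid <- exp(seq(log(min(y_adj)) - 0.3, log(max(y_adj)) + 0.3, length.out = 200))
  z <- (log(grid) - object$beta0) / object$alpha
  df_cdf <- tibble::tibble(y = grid, p = family_std_cdf(z, object$family))
  df_edf <- tibble::tibble(y = y_adj,
                           p = (seq_along(y_adj) - 0.5) / length(y_adj))
  ggplot2::ggplot(df_cdf, ggplot2::aes(x = .data$y, y = .data$p)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_step(data = df_edf, colour = "grey40") +
    ggplot2::geom_point(data = df_edf, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "threshold (gender-adjusted)",
                  y = "cumulative probability",
                  title = sprintf("%s fit, n = %d", object$family,
                                  object$n_used)) +
    ggplot2::theme_minimal()
}
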