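# Quantile limits with confidence intervals, standard-style rounded tables
# with the neck-muscle estimate, and cross-study comparison statistics.

round_half_away <- function(x, unit = 1) {
  sign(x) * floor(abs(x) / unit + 0.5) * unit
}

params_of <- function(fit) {
  if (inherits(fit, "aft_fit")) {
    list(beta0 = fit$beta0, beta1 = fit$beta1, alpha = fit$alpha,
         family = fit$family, covariance = fit$covariance,
         constrained = fit$constrained)
  } else {
    list(beta0 = fit$beta0, beta1 = fit$beta1 %||% 0, alpha = fit$alpha,
         family = fit$family %||% "log-logistic",
         covariance = fit$covariance, constrained = isTRUE(fit$constrained))
  }
}

#' Quantile limit for a group with a given gender mix
#'
#' Inverts the expanded CDF at quantile `q` for a group with male fraction
#' `x_G`: for the log-logistic family,
#' `y = exp(beta0 + x_G*beta1 + alpha*log(q/(1-q)))`.
#'
#' @param fit An `aft_fit`, or any list with `beta0`, `beta1`, `alpha` (and
#'   optionally `family`).
#' @param q Quantile in (0, 1); the published limits use 0.75.
#' @param x_G Male fraction in `[0, 1]`; the published limits use 0.7.
#' @return The limit in the sample's measurand units.
#' @export
quantile_limit <- function(fit, q = 0.75, x_G = 0.7) {
  if (any(q <= 0 | q >= 1)) abort("`q` must be in (0, 1).", class = "painlimits_domain_error")
  if (any(x_G < 0 | x_G > 1)) abort("`x_G` must be in [0, 1].", class = "painlimits_domain_error")
  p <- params_of(fit)
  exp(p$beta0 + x_G * p$beta1 + p$alpha * family_std_quantile(q, p$family))
}

#' Delta-method confidence interval for a quantile limit
#'
#' Normal-theory interval on the linear predictor
#' `eta = beta0 + x_G*beta1 + alpha * w(q)` (with `w` the standardized
#' quantile of the family), exponentiated back to the measurand scale.
#'
#' @param fit An `aft_fit` with a covariance matrix.
#' @param q Quantile in (0, 1).
#' @param x_G Male fraction.
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(lower, estimate, upper)`.
#' @export
quantile_ci <- function(fit, q = 0.75, x_G = 0.7, level = 0.95) {
  p <- params_of(fit)
  if (is.null(p$covariance)) {
    abort("fit has no covariance matrix.", class = "painlimits_invalid_argument")
  }
  w <- family_std_quantile(q, p$family)
  eta <- p$beta0 + x_G * p$beta1 + p$alpha * w
  g <- if (p$constrained) c(1, w) else c(1, x_G, w)
  v <- drop(t(g) %*% p$covariance %*% g)
  if (v < 0 || !is.finite(v)) abort("invalid covariance.", class = "painlimits_invalid_argument")
  zc <- qnorm(1 - (1 - level) / 2)
  c(lower = exp(eta - zc * sqrt(v)), estimate = exp(eta),
    upper = exp(eta + zc * sqrt(v)))
}

#' Build a quantile-limit table
#'
#' Computes one limit per body location and condition from a parameter table
#' (such as [threshold_params()] or a pipeline's fitted parameters). The
#' gender mix enters only through `beta1`, which is zero wherever gender was
#' judged not relevant, so `x_G` affects exactly the gender-relevant rows.
#'
#' @param params Tibble with `location_id`, `load_type`, `contact_type`,
#'   `beta0`, `beta1`, `alpha` (optional `location_name`, `units`, and a
#'   `fit` list-column of `aft_fit` objects for confidence intervals).
#' @param q Quantile (default 0.75).
#' @param x_G Male fraction (default 0.7).
#' @param level Confidence level for intervals where fits are available.
#' @return A tibble with `y_L`, `y_B`, `y_U` (N or N/cm^2 per the contact
#'   type), `q`, `x_G` and `gender_relevant` columns.
#' @export
build_limit_table <- function(params, q = 0.75, x_G = 0.7, level = 0.95) {
  out <- params
  if (!"units" %in% names(out)) {
    out$units <- ifelse(out$contact_type == "semi-sharp", "N/cm^2", "N")
  }
  out$q <- q
  out$x_G <- x_G
  out$gender_relevant <- out$beta1 > 0
  out$y_B <- exp(out$beta0 + x_G * out$beta1 +
                   out$alpha * qlogis(q))
  if ("fit" %in% names(params)) {
    ci <- purrr::map(params$fit, function(f) {
      if (is.null(f) || is.null(f$covariance)) return(c(NA_real_, NA_real_))
      quantile_ci(f, q, x_G, level)[c("lower", "upper")]
    })
    out$y_L <- vapply(ci, `[[`, numeric(1), 1)
    out$y_U <- vapply(ci, `[[`, numeric(1), 2)
  } else {
    out$y_L <- NA_real_
    out$y_U <- NA_real_
  }
  keep <- intersect(c("location_id", "location_name", "load_type",
                      "contact_type", "units", "q", "x_G", "y_L", "y_B",
                      "y_U", "gender_relevant"), names(out))
  out[, keep]
}

#' Round a limit table for standard use and add the neck estimate
#'
#' Rounds all limits to the nearest 10 (half away from zero) and appends the
#' untested neck muscle (location 4) as 1.2 x the temple's rounded limits,
#' re-rounded to the nearest 10 - an estimate justified by the similarity of
#' the neck-muscle and temple threshold distributions in earlier algometry
#' data.
#'
#' @param limit_table Tibble from [build_limit_table()] containing the temple
#'   (location 2).
#' @return The table with a `limit` column of rounded values and four
#'   appended neck-muscle rows flagged `estimated`.
#' @export
round_for_standard <- function(limit_table) {
  out <- limit_table
  out$limit <- round_half_away(out$y_B, 10)
  out$estimated <- FALSE
  temple <- dplyr::filter(out, .data$location_id == 2)
  if (!nrow(temple)) abort("temple rows are required for the neck estimate.",
                           class = "painlimits_invalid_argument")
  neck <- temple
  neck$location_id <- 4L
  if ("location_name" %in% names(neck)) neck$location_name <- "neck muscle"
  neck$limit <- round_half_away(1.2 * temple$limit, 10)
  neck$y_B <- NA_real_
  neck$y_L <- NA_real_
  neck$y_U <- NA_real_
  neck$estimated <- TRUE
  dplyr::arrange(dplyr::bind_rows(out, neck), .data$location_id,
                 .data$load_type, .data$contact_type)
}

#' Relative impact-to-pinching difference of limits
#'
#' For one contact type, the per-location quotient of the impact limit over
#' the pinching limit at the same quantile and gender mix, and its mean over
#' all measured locations.
#'
#' @param limit_table Tibble from [build_limit_table()] covering both load
#'   types.
#' @param contact_type `"blunt"` or `"semi-sharp"`.
#' @return A list: `per_location` (tibble `location_id`, `w_q`), `w_bar`.
#' @export
relative_difference <- function(limit_table, contact_type = "blunt") {
  d <- dplyr::filter(limit_table, .data$contact_type == !!contact_type)
  wide <- tidyr::pivot_wider(
    d[, c("location_id", "load_type", "y_B")],
    names_from = "load_type", values_from = "y_B")
  missing <- is.na(wide$impact) | is.na(wide$pinching)
  if (any(missing)) {
    warning("skipping locations without both load types: ",
            paste(wide$location_id[missing], collapse = ", "))
    wide <- wide[!missing, ]
  }
  per <- tibble::tibble(location_id = wide$location_id,
                        w_q = wide$impact / wide$pinching)
  list(per_location = per, w_bar = mean(per$w_q))
}

#' Relative deviation between two studies' limits
#'
#' `epsilon = 1 - reference/own`: zero when the studies agree, negative when
#' the reference limit exceeds this study's, bounded above by 1.
#'
#' @param reference_value Limit(s) from the reference study.
#' @param own_value Limit(s) from this study (> 0).
#' @return The relative deviation (fraction; multiply by 100 for percent).
#' @export
relative_deviation <- function(reference_value, own_value) {
  if (any(own_value <= 0, na.rm = TRUE)) {
    abort("`own_value` must be > 0.", class = "painlimits_domain_error")
  }
  1 - reference_value / own_value
}

#' Pearson correlation of force and pressure measurands
#'
#' Quality measure for pressure-based thresholds: the Pearson correlation
#' between paired maximum contact forces and peak pressures.
#'
#' @param forces,pressures Equal-length numeric vectors (n >= 3).
#' @return The correlation coefficient.
#' @export
pearson_k <- function(forces, pressures) {
  if (length(forces) != length(pressures) || length(forces) < 3) {
    abort("need equal-length vectors with at least 3 pairs.",
          class = "painlimits_invalid_argument")
  }
  if (sd(forces) == 0 || sd(pressures) == 0) {
    abort("zero variance: correlation undefined.",
          class = "painlimits_undefined_correlation")
  }
  cor(forces, pressures)
}

#' @describeIn build_limit_table Limits per body location and condition as a
#'   dot-and-interval chart.
#' @param object A limit table.
#' @param ... Unused.
#' @export
autoplot_limit_table <- function(object, ...) {
  object$condition <- paste(object$load_type, object$contact_type)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$location_id), y = .data$y_B,
                               colour = .data$condition)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$y_L, ymax = .data$y_U),
                             position = ggplot2::position_dodge(0.6),
                             na.rm = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "body location", y = "limit (N or N/cm²)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
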