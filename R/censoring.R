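# Interval censoring of staircase series, midpoint imputation, per-subject
# averaging of repeats, and sample assembly per test condition.

#' Censored observation from a pendulum staircase
#'
#' Converts stepped impact series into interval-censored threshold
#' observations, one per series: the lower bound is the measurand of the
#' penultimate test that caused no pain, the upper bound the measurand of the
#' last test, which did. A series whose very first trial is painful is fully
#' left-censored (`L = 0`); a series that ends at the maximum velocity
#' without pain is right-censored (`R = Inf`).
#'
#' @param trials Tibble of staircase trials in execution order with columns
#'   `peak` (measurand value) and `pain` (logical); an optional `series`
#'   column (e.g. the pendulum mass) splits the input into several series.
#' @return A tibble with one row per series: `series`, `L`, `R`,
#'   `censor_type` (`"interval"`, `"left"`, or `"right"`).
#' @export
intervals_from_staircase <- function(trials) {
  if (!nrow(trials)) abort("empty series.", class = "painlimits_malformed_series")
  if (!"series" %in% names(trials)) trials$series <- 1L
  one <- function(d) {
    pain <- d$pain
    if (any(pain[-length(pain)]) || sum(pain) > 1) {
      abort("pain flag must terminate the series.",
            class = "painlimits_malformed_series")
    }
    if (!any(pain)) {
      tibble::tibble(L = d$peak[nrow(d)], R = Inf, censor_type = "right")
    } else if (nrow(d) == 1) {
      tibble::tibble(L = 0, R = d$peak[1], censor_type = "left")
    } else {
      tibble::tibble(L = d$peak[nrow(d) - 1], R = d$peak[nrow(d)],
                     censor_type = "interval")
    }
  }
  trials |>
    dplyr::group_by(.data$series) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Midpoint imputation of censored observations
#'
#' Replaces each censored observation by a point estimate: the interval
#' midpoint `(L + R)/2`, `R/2` for a fully left-censored observation
#' (`L = 0`), the last pain-free value `L` for a right-censored one
#' (`R = Inf`), and `L` itself for exact observations.
#'
#' @param obs Tibble with columns `L`, `R`, `censor_type`.
#' @return `obs` with an added `imputed_y` column.
#' @export
impute_midpoint <- function(obs) {
  obs$imputed_y <- dplyr::case_when(
    obs$censor_type == "exact" ~ obs$L,
    obs$censor_type == "left" ~ obs$R / 2,
    obs$censor_type == "right" ~ obs$L,
    TRUE ~ (obs$L + obs$R) / 2)
  obs
}

#' Average repeated observations per subject
#'
#' The per-subject threshold is the arithmetic mean of the imputed values of
#' all repeats, pooled over pendulum masses. For the interval-likelihood fit
#' mode, the per-subject censoring interval is carried along as the mean of
#' the repeat bounds (`Inf` propagates, so a subject whose repeats are all
#' right-censored stays right-censored and is flagged).
#'
#' @param obs Tibble of imputed observations with columns `subject_id`,
#'   `gender_code`, `L`, `R`, `censor_type`, `imputed_y`.
#' @return A tibble with one row per subject: `subject_id`, `gender_code`,
#'   `y_bar`, `n_repeats`, `L_bar`, `R_bar`, `censor_type`,
#'   `all_right_censored`.
#' @export
average_repeats <- function(obs) {
  if (!nrow(obs)) abort("no observations to average.", class = "painlimits_invalid_argument")
  obs |>
    dplyr::group_by(.data$subject_id, .data$gender_code) |>
    dplyr::summarise(
      y_bar = mean(.data$imputed_y),
      n_repeats = dplyr::n(),
      L_bar = mean(.data$L),
      R_bar = mean(.data$R),
      all_right_censored = all(.data$censor_type == "right"),
      censor_type = dplyr::case_when(
        all(.data$censor_type == "exact") ~ "exact",
        all(is.infinite(.data$R)) ~ "right",
        mean(.data$L) == 0 ~ "left",
        TRUE ~ "interval"),
      .groups = "drop")
}

#' Assemble the sample for one test condition
#'
#' Collects the per-subject means of one body location x load type x contact
#' type cell, enforcing the study's structural rules: the neck muscle
#' (location 4) was never tested, the pectoral muscle (location 9) has no
#' female members, and each subject appears once.
#'
#' @param subject_means Tibble from [average_repeats()].
#' @param location_id Body location id.
#' @param load_type `"pinching"` or `"impact"`.
#' @param contact_type `"semi-sharp"` or `"blunt"`.
#' @return A sample tibble: the subject means with the condition columns
#'   (`location_id`, `load_type`, `contact_type`, `units`) prepended.
#' @export
assemble_sample <- function(subject_means, location_id, load_type,
                            contact_type) {
  if (location_id == 4) {
    abort("location 4 (neck muscle) was excluded from measurement.",
          class = "painlimits_configuration_error")
  }
  if (anyDuplicated(subject_means$subject_id)) {
    abort("one row per subject is required.", class = "painlimits_invalid_argument")
  }
  if (location_id == 9) {
    subject_means <- dplyr::filter(subject_means, .data$gender_code == 1)
  }
  dplyr::bind_cols(
    tibble::tibble(location_id = location_id, load_type = load_type,
                   contact_type = contact_type,
                   units = if (contact_type == "semi-sharp") "N/cm^2" else "N")[
                     rep(1, nrow(subject_means)), ],
    subject_means)
}
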