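# Synthetic subject populations and ground-truth threshold draws.

#' Sample a synthetic subject population
#'
#' Draws `n` subjects with a fixed male fraction (the male count is
#' `round(n * male_fraction)`, half away from zero) and plausible working-age
#' demographics. Deterministic for a fixed seed.
#'
#' @param n Number of subjects (>= 1).
#' @param male_fraction Fraction of males in `[0, 1]`.
#' @param seed Integer seed.
#' @param group Group label attached to every subject (default `"G1"`).
#' @return A tibble with columns `subject_id`, `gender_code` (0 female,
#'   1 male), `group`, `age`, `height`, `weight`.
#' @export
#' @examples
#' sample_population(6, 0.5, seed = 1)
sample_population <- function(n, male_fraction, seed, group = "G1") {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    abort("`n` must be a single integer >= 1.", class = "painlimits_invalid_argument")
  }
  if (!is.numeric(male_fraction) || male_fraction < 0 || male_fraction > 1) {
    abort("`male_fraction` must be in [0, 1].", class = "painlimits_invalid_argument")
  }
  n <- as.integer(n)
  n_male <- as.integer(floor(n * male_fraction + 0.5))
  rng <- local_rng(seed)
  gender <- c(rep(1L, n_male), rep(0L, n - n_male))
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    gender_code = gender,
    group = group,
    age = round(runif(n, 18, 65)),
    height = round(rnorm(n, 1.68 + 0.12 * gender, 0.06), 2),
    weight = round(rnorm(n, 66 + 16 * gender, 9), 1))
}

# Restore-on-exit RNG scope so generators are reproducible without touching
# the caller's stream.
local_rng <- function(seed, envir = parent.frame()) {
  withr::local_seed(as.integer(seed %% .Machine$integer.max),
                    .local_envir = envir)
  invisible(seed)
}

#' Quantile function of the expanded log-logistic threshold law
#'
#' Inverse of [expanded_cdf()]: `y = exp(beta0 + x_G*beta1 + alpha*logit(q))`.
#' Used both to draw synthetic thresholds and to compute limits.
#'
#' @param q Probability in (0, 1).
#' @param beta0,beta1,alpha Model parameters (`alpha > 0`, `beta1 >= 0`).
#' @param x_G Male fraction covariate in `[0, 1]` (a subject's gender code, or
#'   a group mix).
#' @return Threshold value(s), N or N/cm^2 depending on the parameter set.
#' @export
loglogistic_quantile <- function(q, beta0, beta1 = 0, alpha, x_G = 0) {
  if (any(q <= 0 | q >= 1)) abort("`q` must be in (0, 1).", class = "painlimits_domain_error")
  if (any(alpha <= 0)) abort("`alpha` must be > 0.", class = "painlimits_invalid_argument")
  exp(beta0 + x_G * beta1 + alpha * qlogis(q))
}

#' Draw ground-truth pain thresholds
#'
#' Draws thresholds from the expanded log-logistic law for subjects with the
#' given gender codes: `y = exp(beta0 + g*beta1 + alpha*logit(U))` with
#' `U ~ Uniform(0, 1)`.
#'
#' @param n Number of draws (recycled against `gender_code`).
#' @param beta0,beta1,alpha Parameters of the expanded model.
#' @param gender_code 0/1 vector (female/male), length 1 or `n`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Numeric vector of positive thresholds.
#' @export
draw_threshold <- function(n, beta0, beta1 = 0, alpha, gender_code = 0,
                           seed = NULL) {
  if (alpha <= 0 || beta1 < 0) {
    abort("need `alpha` > 0 and `beta1` >= 0.", class = "painlimits_invalid_argument")
  }
  if (!all(gender_code %in% c(0, 1))) {
    abort("`gender_code` must be 0 or 1.", class = "painlimits_invalid_argument")
  }
  if (!is.null(seed)) local_rng(seed)
  u <- runif(n)
  exp(beta0 + gender_code * beta1 + alpha * qlogis(u))
}

#' Default test protocol for a parameter set
#'
#' Builds the protocol configuration used by the trial simulators. The
#' contact stiffness is not a tissue claim: it is chosen per condition so that
#' the median threshold of the supplied parameter set is reached around
#' `v_median` m/s by the heavy pendulum (impact) or within a few seconds of
#' ramping (pinching), keeping simulated staircases inside the protocol's
#' velocity range.
#'
#' @param beta0,beta1,alpha Ground-truth parameters of the condition.
#' @param load_type `"pinching"` or `"impact"`.
#' @param head Logical; head locations use the reduced velocity step.
#' @param v_median Pendulum velocity (m/s) at which the heavy-mass impact
#'   reaches the median threshold (default 0.4).
#' @param noise_sd Measurement noise standard deviation (measurand units).
#' @param offset Constant sensor offset added to raw signals.
#' @param reaction_delay Switch-press delay after pain onset, seconds.
#' @return A list with protocol fields: `deformation_rate`, `velocity_start`,
#'   `velocity_step`, `velocity_max`, `pendulum_masses`, `c_H`, `noise_sd`,
#'   `offset`, `reaction_delay`, `sampling_rate`.
#' @export
default_protocol <- function(beta0, beta1 = 0, alpha, load_type = "impact",
                             head = FALSE, v_median = 0.4, noise_sd = 0.5,
                             offset = 0, reaction_delay = 0) {
  y_med <- exp(beta0 + 0.5 * beta1)
  step <- if (head) 0.01 else 0.05
  if (load_type == "impact") {
    c_H <- (y_med / v_median)^2 / 16.5 # heavy mass reaches median at v_median
    rate <- 1e-3
  } else {
    c_H <- y_med / (1e-3 * 5) # ramp reaches the median in ~5 s
    rate <- 1e-3
  }
  list(deformation_rate = rate,
       velocity_start = step, velocity_step = step, velocity_max = 1.25,
       pendulum_masses = c(16.5, 6.5), c_H = c_H,
       noise_sd = noise_sd, offset = offset,
       reaction_delay = reaction_delay,
       sampling_rate = if (load_type == "impact") 1e4 else 100)
}
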