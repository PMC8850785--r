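# Raw-trial simulators: quasi-static algometer ramps, pendulum impact
# staircases, and pressure-film frame stacks with known ground truth.

new_trial_series <- function(data, sampling_rate, load_type, event_index = NA,
                             meta = list()) {
  structure(list(data = data, sampling_rate = sampling_rate,
                 load_type = load_type, event_index = event_index,
                 meta = meta),
            class = "trial_series")
}

#' @export
print.trial_series <- function(x, ...) {
  cat(sprintf("<trial_series: %s, %g Hz, %d samples%s>\n", x$load_type,
              x$sampling_rate, nrow(x$data),
              if (!is.na(x$event_index)) sprintf(", event @ %d", x$event_index) else ""))
  invisible(x)
}

#' Simulate a quasi-static algometer trial
#'
#' Emulates a pinching load test: after a pre-contact baseline the contact
#' force rises linearly at `c_H * deformation_rate` (linear tissue spring at a
#' 1 mm/s ramp); the subject's switch event fires when the noiseless force
#' first reaches the pain threshold, plus any reaction delay. The raw signal
#' carries a constant sensor offset and additive Gaussian noise; signals are
#' sampled at 100 Hz.
#'
#' @param threshold True pain threshold (measurand units, > 0).
#' @param protocol Protocol list as from [default_protocol()].
#' @param baseline Pre-contact baseline duration in seconds.
#' @param max_duration Maximum ramp duration in seconds after contact.
#' @param seed Optional seed.
#' @return A `trial_series` with columns `time_s`, `f_N`, `event_flag`.
#' @export
simulate_algometer_trial <- function(threshold, protocol, baseline = 1,
                                     max_duration = 60, seed = NULL) {
  if (threshold <= 0) abort("`threshold` must be > 0.", class = "painlimits_invalid_argument")
  if (!is.null(seed)) local_rng(seed)
  fs <- 100
  slope <- protocol$c_H * protocol$deformation_rate # measurand units per s
  t_hit <- threshold / slope
  if (t_hit > max_duration) {
    abort("threshold not reachable within the configured ramp duration.",
          class = "painlimits_simulation_limit")
  }
  t_event <- baseline + t_hit + protocol$reaction_delay
  t_end <- min(baseline + max_duration, t_event + 0.5)
  time <- seq(0, t_end, by = 1 / fs)
  ramp <- pmax(0, time - baseline) * slope
  noise <- if (protocol$noise_sd > 0) rnorm(length(time), 0, protocol$noise_sd) else 0
  f <- ramp + protocol$offset + noise
  event_index <- which(time >= t_event)[1]
  flag <- integer(length(time))
  flag[event_index] <- 1L
  new_trial_series(
    tibble::tibble(time_s = time, f_N = f, event_flag = flag),
    sampling_rate = fs, load_type = "pinching", event_index = event_index,
    meta = list(threshold = threshold, contact_onset = baseline,
                slope = slope, offset = protocol$offset))
}

#' Simulate a pendulum impact staircase
#'
#' Emulates the stepped method-of-limits impact protocol: for each pendulum
#' mass, the impact velocity increases in fixed steps from the starting
#' velocity; under the linear-spring impact model the noiseless peak load is
#' `sqrt(m * c_H) * v`. The series for a mass ends at the first trial whose
#' noiseless peak reaches the subject's threshold (pain) or at the maximum
#' velocity (no pain; the downstream observation is right-censored). Measured
#' peaks carry additive Gaussian noise.
#'
#' @param threshold True pain threshold (> 0).
#' @param protocol Protocol list as from [default_protocol()].
#' @param masses Pendulum masses in kg (default from `protocol`).
#' @param seed Optional seed.
#' @return A tibble with one row per trial: `mass`, `trial`, `velocity`,
#'   `peak_true`, `peak_measured`, `pain`.
#' @export
simulate_pendulum_staircase <- function(threshold, protocol,
                                        masses = protocol$pendulum_masses,
                                        seed = NULL) {
  if (threshold <= 0) abort("`threshold` must be > 0.", class = "painlimits_invalid_argument")
  if (!is.null(seed)) local_rng(seed)
  purrr::map_dfr(masses, function(m) {
    gain <- sqrt(m * protocol$c_H)
    v <- seq(protocol$velocity_start, protocol$velocity_max,
             by = protocol$velocity_step)
    peaks <- gain * v
    hit <- which(peaks >= threshold)[1]
    keep <- if (is.na(hit)) seq_along(v) else seq_len(hit)
    pk <- peaks[keep]
    tibble::tibble(
      mass = m, trial = keep, velocity = v[keep], peak_true = pk,
      peak_measured = pk + if (protocol$noise_sd > 0)
        rnorm(length(pk), 0, protocol$noise_sd) else 0,
      pain = !is.na(hit) & keep == hit)
  })
}

#' Simulate one raw impact force pulse
#'
#' Generates the 10 kHz tri-axial load-cell signal of a single pendulum
#' impact: a half-sine normal-force pulse of the requested peak (duration set
#' by the contact stiffness and moving mass), a pre-contact baseline, sensor
#' offset and Gaussian noise. The peak given is the contact-tip force; the
#' recorded signal is scaled down by the inertia factor `1 / (1 + m_I/m_B)`
#' so that inertia compensation recovers it.
#'
#' @param peak_force Contact-tip peak force in N.
#' @param protocol Protocol list (uses `c_H`, `noise_sd`, `offset`).
#' @param mass Pendulum body mass `m_B` in kg.
#' @param m_I Contact-body mass in kg (default 0.3).
#' @param baseline Pre-contact baseline duration in s.
#' @param seed Optional seed.
#' @return A `trial_series` with columns `time_s`, `fx_N`, `fy_N`, `fz_N`.
#' @export
simulate_impact_trial <- function(peak_force, protocol, mass = 16.5,
                                  m_I = 0.3, baseline = 1, seed = NULL) {
  if (!is.null(seed)) local_rng(seed)
  fs <- 1e4
  half_period <- pi * sqrt(mass / protocol$c_H)
  t_end <- baseline + half_period + 0.1
  time <- seq(0, t_end, by = 1 / fs)
  tau <- time - baseline
  pulse <- ifelse(tau >= 0 & tau <= half_period,
                  peak_force * sin(pi * tau / half_period), 0)
  v_f <- 1 + m_I / mass
  measured <- pulse / v_f # load cell sees the tip force reduced by inertia
  n <- length(time)
  noise <- function() if (protocol$noise_sd > 0) rnorm(n, 0, protocol$noise_sd) else 0
  new_trial_series(
    tibble::tibble(time_s = time,
                   fx_N = measured + protocol$offset + noise(),
                   fy_N = noise(), fz_N = noise()),
    sampling_rate = fs, load_type = "impact",
    meta = list(peak_force = peak_force, m_B = mass, m_I = m_I,
                contact_onset = baseline, offset = protocol$offset))
}

#' Pressure-film geometry of the semi-sharp contact body
#'
#' Describes the sensel grid on the 14 mm x 14 mm face (2 mm corner radius).
#' The outermost sensel ring lies on the rounded edge and is recorded in one
#' of four lateral views (the film bends over the edges); all other sensels
#' are in the overhead view. The film does not reach the rounded corners:
#' those sensels are blind spots. Concentric rectangular rings of sensels form
#' the closed outer contours used for blind-spot interpolation.
#'
#' @param n_side Sensels per side (default 14, 1 mm pitch).
#' @param edge_angle Tilt of the rounded-edge surface normal against the
#'   lateral view normal, radians (default `pi/4`); sets the lateral-view
#'   projection factor `cos(edge_angle)`.
#' @param corner_cells Half-width, in cells, of the square corner blocks not
#'   covered by the film (default 2).
#' @return A `film_geometry` list: `n_side`, `pitch_mm`, `sensel_area_cm2`,
#'   `coverage` (logical matrix, `FALSE` = blind spot), `view` (character
#'   matrix), `projection` (numeric matrix), `ring` (integer matrix of
#'   contour indices, 0 = outermost).
#' @export
film_geometry <- function(n_side = 14, edge_angle = pi / 4, corner_cells = 2) {
  i <- matrix(seq_len(n_side), n_side, n_side)
  j <- t(i)
  ring <- pmin(i - 1, j - 1, n_side - i, n_side - j)
  view <- matrix("overhead", n_side, n_side)
  # outermost ring belongs to the lateral view of its nearest edge;
  # ties (corners) go to the N/S views
  view[ring == 0 & i == 1] <- "lateral-N"
  view[ring == 0 & i == n_side] <- "lateral-S"
  view[ring == 0 & view == "overhead" & j == 1] <- "lateral-W"
  view[ring == 0 & view == "overhead" & j == n_side] <- "lateral-E"
  projection <- matrix(1, n_side, n_side)
  projection[ring == 0] <- cos(edge_angle)
  coverage <- matrix(TRUE, n_side, n_side)
  cc <- seq_len(corner_cells)
  for (ci in list(cc, n_side + 1 - cc)) {
    for (cj in list(cc, n_side + 1 - cc)) coverage[ci, cj] <- FALSE
  }
  structure(list(n_side = n_side, pitch_mm = 14 / n_side,
                 sensel_area_cm2 = (14 / n_side / 10)^2,
                 coverage = coverage, view = view, projection = projection,
                 ring = ring),
            class = "film_geometry")
}

# Perimeter-ordered (row, col) cells of one rectangular contour ring.
ring_path <- function(geometry, ring_index) {
  n <- geometry$n_side
  lo <- ring_index + 1
  hi <- n - ring_index
  if (lo > hi) return(matrix(integer(0), 0, 2))
  if (lo == hi) return(matrix(c(lo, lo), 1, 2))
  rbind(cbind(lo, seq(lo, hi)),                                  # top, L->R
        cbind(seq(lo + 1, hi), hi),                              # right, T->B
        cbind(hi, rev(seq(lo, hi - 1))),                         # bottom, R->L
        if (hi - lo >= 2) cbind(rev(seq(lo + 1, hi - 1)), lo))   # left, B->T
}

#' Simulate pressure-film frame stacks
#'
#' Generates an 8-bit pressure-film recording for a series of instantaneous
#' contact forces: the force is spread over the face with a unimodal (raised
#' cosine) or uniform spatial profile so that the sensel sum times the sensel
#' area equals the force, blind-spot sensels are zeroed, and values are
#' quantized to 8 bit over the film's 0-1200 N/cm^2 range.
#'
#' @param forces Instantaneous contact forces in N, one per frame.
#' @param geometry A [film_geometry()].
#' @param times Frame timestamps in s (default 2.07 kHz spacing).
#' @param profile `"cosine"` (unimodal) or `"uniform"`.
#' @param quantize Apply the 8-bit quantization (default `TRUE`).
#' @param noise_sd Per-sensel Gaussian noise before quantization, N/cm^2.
#' @param seed Optional seed.
#' @return A `pressure_stack`: list with `frames` (list of matrices, N/cm^2),
#'   `times`, `geometry`, `quantized`.
#' @export
simulate_pressure_frames <- function(forces, geometry,
                                     times = (seq_along(forces) - 1) / 2070,
                                     profile = c("cosine", "uniform"),
                                     quantize = TRUE, noise_sd = 0,
                                     seed = NULL) {
  profile <- match.arg(profile)
  if (length(times) != length(forces)) {
    abort("`times` and `forces` lengths differ.", class = "painlimits_invalid_argument")
  }
  if (!is.null(seed)) local_rng(seed)
  n <- geometry$n_side
  ctr <- (n + 1) / 2
  r <- sqrt((row(diag(n)) - ctr)^2 + (col(diag(n)) - ctr)^2)
  w <- switch(profile,
              uniform = matrix(1, n, n),
              cosine = pmax(cos(pi * r / (2 * max(r))), 0.05))
  w <- w / (sum(w) * geometry$sensel_area_cm2) # unit force -> pressures
  step <- 1200 / 255
  frames <- lapply(forces, function(f) {
    p <- f * w
    if (noise_sd > 0) p <- pmax(p + matrix(rnorm(n * n, 0, noise_sd), n), 0)
    p[!geometry$coverage] <- 0
    if (quantize) p <- pmin(pmax(round(p / step), 0), 255) * step
    p
  })
  structure(list(frames = frames, times = times, geometry = geometry,
                 quantized = quantize),
            class = "pressure_stack")
}
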