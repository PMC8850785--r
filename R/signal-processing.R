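# Force-signal conditioning: channel-frequency-class zero-phase Butterworth
# filtering, baseline offset elimination with contact-onset detection,
# inertia compensation, and extraction of the maximum contact force.

#' Construct a force signal
#'
#' Wraps a uniformly sampled single- or tri-axial force recording with the
#' metadata the conditioning operations need.
#'
#' @param data Tibble with `time_s` and 1 or 3 force columns (N).
#' @param sampling_rate Sampling rate in Hz.
#' @param event_index Optional sample index of the subject's switch press.
#' @param m_B,m_I Pendulum-body and contact-body masses in kg (impact only).
#' @return A `force_signal` object.
#' @export
force_signal <- function(data, sampling_rate, event_index = NA,
                         m_B = NA, m_I = NA) {
  fcols <- setdiff(names(data), c("time_s", "event_flag"))
  if (!length(fcols) %in% c(1L, 3L)) {
    abort("force signals must have 1 or 3 axes.", class = "painlimits_invalid_argument")
  }
  structure(list(data = data[, c("time_s", fcols)], sampling_rate = sampling_rate,
                 axes = fcols, event_index = event_index, m_B = m_B, m_I = m_I,
                 filtered = FALSE, offset_removed = FALSE,
                 inertia_compensated = FALSE, onset_index = NA),
            class = "force_signal")
}

#' @export
print.force_signal <- function(x, ...) {
  cat(sprintf("<force_signal: %d axes, %g Hz, %d samples>\n",
              length(x$axes), x$sampling_rate, nrow(x$data)))
  invisible(x)
}

#' Convert a simulated trial to a force signal
#'
#' @param trial A `trial_series` from the simulators.
#' @return A `force_signal` carrying the trial's event index and masses.
#' @export
as_force_signal <- function(trial) {
  force_signal(trial$data, trial$sampling_rate,
               event_index = trial$event_index,
               m_B = trial$meta$m_B %||% NA, m_I = trial$meta$m_I %||% NA)
}

# Channel class -> -3 dB cutoff in Hz (automotive channel-class convention).
cfc_cutoff <- function(cfc_class) {
  switch(cfc_class, CFC1 = 1.65, CFC100 = 165,
         abort("unknown CFC class.", class = "painlimits_invalid_argument"))
}

#' Zero-phase channel-frequency-class low-pass filter
#'
#' Filters each axis with a 2nd-order Butterworth low-pass applied forward
#' and backward (net 4th order, zero phase lag, unity DC gain). The cutoff is
#' `1.65 x` the channel class value in Hz: CFC1 (1.65 Hz) for the quasi-static
#' algometer signals, CFC100 (165 Hz) for the pendulum signals. Edges are
#' reflect-padded; the first/last few filter time constants are still flagged
#' as unreliable in `edge_unreliable`.
#'
#' @param sig A `force_signal`.
#' @param cfc_class `"CFC1"` or `"CFC100"`.
#' @return The filtered `force_signal`.
#' @export
cfc_filter <- function(sig, cfc_class = c("CFC100", "CFC1")) {
  cfc_class <- match.arg(cfc_class)
  fc <- cfc_cutoff(cfc_class)
  fs <- sig$sampling_rate
  if (fc >= fs / 2) {
    abort("cutoff at or above Nyquist.", class = "painlimits_invalid_argument")
  }
  n <- nrow(sig$data)
  if (n < 20) abort("signal too short to filter.", class = "painlimits_invalid_argument")
  bf <- signal::butter(2, fc / (fs / 2), type = "low")
  pad <- min(n - 1, ceiling(3 * fs / fc))
  for (ax in sig$axes) {
    x <- sig$data[[ax]]
    # odd reflection about the endpoints suppresses edge transients
    xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
            2 * x[n] - rev(x[(n - pad):(n - 1)]))
    y <- signal::filter(bf, xp)
    y <- rev(signal::filter(bf, rev(y)))
    sig$data[[ax]] <- y[(pad + 1):(pad + n)]
  }
  sig$filtered <- TRUE
  sig$edge_unreliable <- min(n, ceiling(3 * fs / (2 * pi * fc)))
  sig
}

#' Eliminate sensor offset and locate contact onset
#'
#' Subtracts the per-axis mean of the pre-contact baseline window so the
#' contact force is zero before initial contact, then detects the onset as
#' the first sample whose force magnitude exceeds
#' `max(5 x baseline SD, 0.5 N)` sustained for 5 samples.
#'
#' @param sig A `force_signal`.
#' @param baseline_window Baseline duration in seconds from the start of the
#'   recording (must precede contact).
#' @return The `force_signal` with offsets removed and `onset_index` set.
#' @export
eliminate_offset <- function(sig, baseline_window = 0.5) {
  nb <- max(2, floor(baseline_window * sig$sampling_rate))
  nb <- min(nb, nrow(sig$data))
  for (ax in sig$axes) {
    sig$data[[ax]] <- sig$data[[ax]] - mean(sig$data[[ax]][seq_len(nb)])
  }
  amp <- signal_norm(sig)
  thr <- max(5 * sd(amp[seq_len(nb)]), 0.5)
  above <- amp > thr
  run <- stats::filter(as.numeric(above), rep(1, 5), sides = 1)
  onset <- which(run == 5)[1] - 4L
  if (is.na(onset)) abort("no contact onset found.", class = "painlimits_no_contact")
  sig$offset_removed <- TRUE
  sig$onset_index <- onset
  sig$onset_threshold <- thr
  sig
}

signal_norm <- function(sig) {
  m <- as.matrix(sig$data[, sig$axes])
  sqrt(rowSums(m^2))
}

#' Compensate load-cell inertia
#'
#' Scales the measured force by `V_f = 1 + m_I/m_B` to recover the force that
#' acted at the contact-body tip: during an impact only the pendulum-body
#' mass acts on the load cell, so the reading underestimates the tip force by
#' that factor. A processed flag guards against applying the factor twice.
#'
#' @param sig A `force_signal` with `m_B` and `m_I` set.
#' @return The compensated `force_signal`.
#' @export
compensate_inertia <- function(sig) {
  if (isTRUE(sig$inertia_compensated)) {
    abort("inertia compensation already applied.", class = "painlimits_invalid_argument")
  }
  if (is.na(sig$m_B) || is.na(sig$m_I) || sig$m_B <= 0 || sig$m_I < 0) {
    abort("`m_B` > 0 and `m_I` >= 0 are required.", class = "painlimits_invalid_argument")
  }
  v_f <- 1 + sig$m_I / sig$m_B
  for (ax in sig$axes) sig$data[[ax]] <- sig$data[[ax]] * v_f
  sig$inertia_compensated <- TRUE
  sig
}

#' Maximum contact force
#'
#' The limit measurand for force-based conditions: the maximum over time of
#' the Euclidean norm of the (processed) force signal. In algometer mode the
#' maximum is restricted to samples up to the switch-press event, which is
#' the force that evoked the painful feeling under a monotone ramp.
#'
#' @param sig A processed `force_signal`.
#' @param mode `"impact"` (global maximum) or `"algometer"` (maximum up to
#'   `event_index`).
#' @return Maximum contact force in N.
#' @export
max_contact_force <- function(sig, mode = c("impact", "algometer")) {
  mode <- match.arg(mode)
  amp <- signal_norm(sig)
  if (mode == "algometer") {
    if (is.na(sig$event_index)) {
      abort("algometer mode requires an event index.", class = "painlimits_missing_event")
    }
    amp <- amp[seq_len(sig$event_index)]
  }
  max(amp)
}
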