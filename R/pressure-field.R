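# Pressure-image conditioning: per-view Gaussian blur, blind-spot spline
# interpolation along the face's outer contours, calibration of the pressure
# integral to the measured contact force, and peak-pressure extraction.

gaussian_kernel_3x3 <- function(variance = 2 / pi) {
  d <- (-1):1
  k <- outer(d, d, function(a, b) exp(-(a^2 + b^2) / (2 * variance)))
  k / sum(k)
}

# Kernel-weighted local average of `x` over the cells flagged in `ind`,
# renormalized by the locally available weight (so a constant field stays
# constant at view borders).
masked_blur <- function(x, ind, kernel) {
  n1 <- nrow(x); n2 <- ncol(x)
  num <- matrix(0, n1, n2)
  den <- matrix(0, n1, n2)
  for (di in (-1):1) {
    for (dj in (-1):1) {
      w <- kernel[di + 2, dj + 2]
      src_i <- max(1, 1 - di):min(n1, n1 - di)
      src_j <- max(1, 1 - dj):min(n2, n2 - dj)
      dst_i <- src_i + di
      dst_j <- src_j + dj
      num[dst_i, dst_j] <- num[dst_i, dst_j] +
        w * x[src_i, src_j] * ind[src_i, src_j]
      den[dst_i, dst_j] <- den[dst_i, dst_j] + w * ind[src_i, src_j]
    }
  }
  out <- num / pmax(den, .Machine$double.eps)
  out[!ind] <- x[!ind]
  out
}

#' Blur a pressure frame separately per sensor view
#'
#' Applies the film manufacturer's 3 x 3 Gaussian blur (variance `2/pi`)
#' independently within each of the sensor's five views (one overhead, four
#' lateral). Values in a lateral view are first reduced to the fraction the
#' sensor records along that view's normal (the per-cell projection factor of
#' the geometry); the blurred views are then reassembled into one frame.
#'
#' @param frame Numeric matrix of sensel pressures (N/cm^2).
#' @param geometry A [film_geometry()] (supplies view labels and projection
#'   factors).
#' @param variance Kernel variance (default `2/pi`).
#' @return The blurred frame matrix.
#' @export
blur_per_view <- function(frame, geometry, variance = 2 / pi) {
  if (!all(dim(frame) == geometry$n_side)) {
    abort("frame does not match the geometry.", class = "painlimits_invalid_argument")
  }
  k <- gaussian_kernel_3x3(variance)
  x <- frame * geometry$projection
  out <- matrix(0, nrow(frame), ncol(frame))
  for (v in unique(as.vector(geometry$view))) {
    ind <- geometry$view == v
    blurred <- masked_blur(x, ind, k)
    out[ind] <- blurred[ind]
  }
  out
}

#' Fill pressure-film blind spots by contour spline interpolation
#'
#' The film does not cover the rounded corners of the face. For each closed
#' outer contour of the face, the covered sensel values are mapped over their
#' position along the contour's perimeter; the gaps are closed with a
#' periodic cubic spline and the blind-spot sensels take the interpolated
#' values. Covered sensels are returned unchanged.
#'
#' @param frame Numeric matrix of sensel pressures.
#' @param geometry A [film_geometry()].
#' @return The fully covered frame matrix.
#' @export
interpolate_blind_spots <- function(frame, geometry) {
  if (all(geometry$coverage)) return(frame)
  out <- frame
  for (k in 0:max(geometry$ring)) {
    path <- ring_path(geometry, k)
    if (nrow(path) == 0) next
    idx <- cbind(path[, 1], path[, 2])
    covered <- geometry$coverage[idx]
    if (all(covered)) next
    if (sum(covered) < 4) {
      abort("a contour has fewer than 4 covered sensels.",
            class = "painlimits_underdetermined_interpolation")
    }
    len <- nrow(path)
    pos <- seq_len(len)
    pc <- pos[covered]
    vc <- frame[idx][covered]
    f <- splinefun(c(pc, pc[1] + len), c(vc, vc[1]), method = "periodic")
    miss <- pos[!covered]
    eval_at <- ifelse(miss < pc[1], miss + len, miss)
    out[idx[!covered, , drop = FALSE]] <- f(eval_at)
  }
  out
}

#' Calibrate a pressure frame to the measured contact force
#'
#' Scales all sensel values by one factor so that the pressure integral
#' (sensel sum times sensel area) equals the contact force measured at the
#' same instant. Applied after blurring and interpolation, this guarantees
#' force conservation regardless of earlier smoothing.
#'
#' @param frame Fully covered frame matrix.
#' @param geometry A [film_geometry()].
#' @param contact_force Contact force in N at the frame's instant (> 0).
#' @return The calibrated frame matrix.
#' @export
calibrate_to_force <- function(frame, geometry, contact_force) {
  if (contact_force <= 0) {
    abort("`contact_force` must be > 0.", class = "painlimits_invalid_argument")
  }
  total <- sum(frame) * geometry$sensel_area_cm2
  if (total <= 0) {
    abort("zero frame cannot be calibrated to a positive force.",
          class = "painlimits_calibration_impossible")
  }
  frame * (contact_force / total)
}

#' Peak pressure of a processed frame stack
#'
#' The limit measurand for pressure-based conditions: the maximum sensel
#' value over all frames and positions.
#'
#' @param frames List of processed frame matrices, or a `pressure_stack`.
#' @return Peak pressure in N/cm^2.
#' @export
peak_pressure <- function(frames) {
  if (inherits(frames, "pressure_stack")) frames <- frames$frames
  if (!length(frames)) abort("empty frame stack.", class = "painlimits_invalid_argument")
  max(vapply(frames, max, numeric(1)))
}

#' Process a raw pressure stack
#'
#' Canonical per-frame pipeline: per-view blur, blind-spot interpolation,
#' calibration to the simultaneous contact force.
#'
#' @param stack A `pressure_stack`.
#' @param contact_forces Contact force in N per frame.
#' @return The stack with processed frames.
#' @export
process_pressure_stack <- function(stack, contact_forces) {
  if (length(contact_forces) != length(stack$frames)) {
    abort("one contact force per frame is required.", class = "painlimits_invalid_argument")
  }
  stack$frames <- purrr::map2(stack$frames, contact_forces, function(fr, f) {
    fr <- blur_per_view(fr, stack$geometry)
    fr <- interpolate_blind_spots(fr, stack$geometry)
    calibrate_to_force(fr, stack$geometry, f)
  })
  stack
}
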