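#' Helical twist from the crossover distance
#'
#' In projection, a twisted amyloid filament completes a half-turn over
#' the crossover distance `d`, visible as the period of the alternating
#' apparent width.  The twist per asymmetric unit follows as
#' `rise * 180 / d` degrees.  Amyloid filaments are almost always
#' left-handed, so the value is returned with a negative sign.
#'
#' @param crossover_A crossover distance in Angstrom (> 0).
#' @param rise_A helical rise in Angstrom (> 0); the canonical
#'   cross-beta spacing is 4.75.
#' @return signed twist in degrees (negative = left-handed).
#' @examples
#' round(twist_from_crossover(720), 2)   # -1.19
#' round(twist_from_crossover(750), 2)   # -1.14
#' twist_from_crossover(855)             # -1 exactly
#' @export
twist_from_crossover <- function(crossover_A, rise_A = 4.75) {
  if (!is.finite(crossover_A) || crossover_A <= 0)
    stop("crossover_A must be > 0")
  if (!is.finite(rise_A) || rise_A <= 0)
    stop("rise_A must be > 0")
  -(rise_A * 180) / crossover_A
}

#' Crossover distance from the helical twist
#'
#' Inverse of [twist_from_crossover()]; the sign of the twist is
#' ignored.
#'
#' @param twist_deg twist per asymmetric unit in degrees (nonzero).
#' @param rise_A helical rise in Angstrom (> 0).
#' @return crossover distance in Angstrom.
#' @export
crossover_from_twist <- function(twist_deg, rise_A = 4.75) {
  if (!is.finite(twist_deg) || twist_deg == 0)
    stop("twist_deg must be nonzero")
  if (!is.finite(rise_A) || rise_A <= 0)
    stop("rise_A must be > 0")
  (rise_A * 180) / abs(twist_deg)
}

#' Inter-particle distance along a filament
#'
#' The extraction spacing is the helical rise times the number of
#' unique asymmetric units between consecutive extracted segments
#' (three beta-rungs works well in most cases: 3 * 4.75 = 14.25 A,
#' conventionally quoted as 14.2 A).
#'
#' @param rise_A helical rise in Angstrom (> 0).
#' @param n_asu positive integer, number of unique asymmetric units.
#' @return spacing in Angstrom.
#' @export
interparticle_distance <- function(rise_A = 4.75, n_asu = 3L) {
  if (!is.finite(rise_A) || rise_A <= 0) stop("rise_A must be > 0")
  n_asu <- as.integer(n_asu)
  if (is.na(n_asu) || n_asu < 1L) stop("n_asu must be >= 1")
  rise_A * n_asu
}

#' Pixel size after Fourier down-scaling of extracted boxes
#'
#' Down-scaling an extracted box from `box_px` to `downscaled_box_px`
#' pixels enlarges the pixel size by the same ratio.
#'
#' @param pixel_A original pixel size in Angstrom (> 0).
#' @param box_px extraction box size in pixels.
#' @param downscaled_box_px down-scaled box size in pixels,
#'   `<= box_px`.
#' @return down-scaled pixel size in Angstrom.
#' @examples
#' downscaled_pixel_size(0.824, 768, 128)   # 4.944
#' @export
downscaled_pixel_size <- function(pixel_A, box_px, downscaled_box_px) {
  if (!is.finite(pixel_A) || pixel_A <= 0) stop("pixel_A must be > 0")
  box_px <- as.integer(box_px)
  downscaled_box_px <- as.integer(downscaled_box_px)
  if (is.na(box_px) || box_px < 1L) stop("box_px must be >= 1")
  if (is.na(downscaled_box_px) || downscaled_box_px < 1L)
    stop("downscaled_box_px must be >= 1")
  if (downscaled_box_px > box_px)
    stop("downscaled_box_px must not exceed box_px")
  pixel_A * box_px / downscaled_box_px
}

#' Picking radius in down-sampled pixels
#'
#' The picking radius is half the particle diameter (which should
#' reflect the average filament width) expressed in down-sampled score
#' map pixels, rounded to the nearest integer and floored at 1.
#'
#' @param diameter_A particle diameter in Angstrom (> 0).
#' @param downscaled_pixel_A down-sampled pixel size in Angstrom (> 0).
#' @return integer radius in down-sampled pixels, >= 1.
#' @examples
#' radius_pixels(120, 4.94)   # 12
#' @export
radius_pixels <- function(diameter_A, downscaled_pixel_A) {
  if (!is.finite(diameter_A) || diameter_A <= 0)
    stop("diameter_A must be > 0")
  if (!is.finite(downscaled_pixel_A) || downscaled_pixel_A <= 0)
    stop("downscaled_pixel_A must be > 0")
  max(1L, as.integer(round(diameter_A / 2 / downscaled_pixel_A)))
}

#' Corrected pixel size from an observed helical rise
#'
#' A miscalibrated magnification shows up as a refined helical rise
#' that deviates from the expected 4.75 A cross-beta spacing.
#' Attributing the deviation entirely to the pixel-size calibration,
#' the corrected pixel size is the nominal one scaled so that the rise
#' becomes 4.75 A again.
#'
#' @param nominal_pixel_A calibrated (nominal) pixel size in Angstrom.
#' @param observed_rise_A helical rise refined under the nominal pixel
#'   size, in Angstrom.
#' @param true_rise_A the physically expected rise (default 4.75 A).
#' @return corrected pixel size in Angstrom.
#' @export
corrected_pixel_size <- function(nominal_pixel_A, observed_rise_A,
                                 true_rise_A = 4.75) {
  if (!is.finite(nominal_pixel_A) || nominal_pixel_A <= 0)
    stop("nominal_pixel_A must be > 0")
  if (!is.finite(observed_rise_A) || observed_rise_A <= 0)
    stop("observed_rise_A must be > 0")
  if (!is.finite(true_rise_A) || true_rise_A <= 0)
    stop("true_rise_A must be > 0")
  nominal_pixel_A * true_rise_A / observed_rise_A
}

# wrap an angle in degrees to (-180, 180]
.wrap_deg <- function(a) {
  a <- a %% 360
  a[a > 180] <- a[a > 180] - 360
  a
}

#' Sample particle records along a filament trace
#'
#' Places particle extraction positions along the straight line from
#' the trace start to its end, spaced `spacing_A` Angstrom apart in arc
#' length, starting at the trace start and never overshooting the end.
#' Each record carries the orientational priors used by helical
#' refinement: the in-plane angle prior `psi_prior_deg` is
#' `-atan2(dy, dx)` of the trace direction in degrees (image y runs
#' downward), wrapped to (-180, 180]; the tilt prior is 90 degrees
#' because filaments lie in the image plane.  The track length is the
#' distance from the trace start in Angstrom.
#'
#' @param trace one-row data frame (or list) with `x_start`, `y_start`,
#'   `x_end`, `y_end` in micrograph pixels and `tube_id`.
#' @param spacing_A inter-particle distance in Angstrom (> 0); see
#'   [interparticle_distance()].
#' @param pixel_A micrograph pixel size in Angstrom (> 0).
#' @return data frame with columns `x`, `y`, `tube_id`,
#'   `psi_prior_deg`, `tilt_prior_deg`, `track_length_A`.
#' @examples
#' tr <- data.frame(x_start = 0, y_start = 0, x_end = 30, y_end = 0,
#'                  tube_id = 1)
#' sample_particles(tr, spacing_A = 14.25, pixel_A = 1)
#' @export
sample_particles <- function(trace, spacing_A, pixel_A) {
  if (!is.finite(spacing_A) || spacing_A <= 0) stop("spacing_A must be > 0")
  if (!is.finite(pixel_A) || pixel_A <= 0) stop("pixel_A must be > 0")
  dx <- trace$x_end - trace$x_start
  dy <- trace$y_end - trace$y_start
  len_px <- sqrt(dx^2 + dy^2)
  if (len_px <= 0) stop("trace has zero length")
  len_A <- len_px * pixel_A
  ts_A <- seq(0, by = spacing_A, length.out = floor(len_A / spacing_A) + 1L)
  frac <- ts_A / len_A
  psi <- .wrap_deg(-atan2(dy, dx) * 180 / pi)
  data.frame(
    x = trace$x_start + frac * dx,
    y = trace$y_start + frac * dy,
    tube_id = if (is.null(trace$tube_id)) 1L else as.integer(trace$tube_id),
    psi_prior_deg = psi,
    tilt_prior_deg = 90,
    track_length_A = ts_A)
}

#' Sample particles along every trace of a micrograph
#'
#' Convenience wrapper applying [sample_particles()] to each row of a
#' trace table, in `tube_id` order.
#'
#' @param traces data frame of traces as produced by
#'   [extract_traces()].
#' @inheritParams sample_particles
#' @return one combined particle data frame.
#' @export
sample_all_particles <- function(traces, spacing_A, pixel_A) {
  if (nrow(traces) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      tube_id = integer(0), psi_prior_deg = numeric(0),
                      tilt_prior_deg = numeric(0),
                      track_length_A = numeric(0)))
  traces <- traces[order(traces$tube_id), , drop = FALSE]
  out <- lapply(seq_len(nrow(traces)), function(i)
    sample_particles(traces[i, ], spacing_A, pixel_A))
  do.call(rbind, out)
}
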