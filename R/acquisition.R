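#' Plane-wave acquisition configuration
#'
#' Describes the compounded plane-wave Doppler acquisition assumed throughout
#' the pipeline: a linear array transmitting tilted plane waves at `prf`,
#' compounded `num_angles` at a time into IQ frames at
#' `frame_rate_in_ensemble`, collected in ensembles of `ensemble_len` frames
#' every `ensemble_interval` seconds.
#'
#' @param center_frequency Transmit centre frequency, Hz.
#' @param num_angles Number of compounding angles (odd, symmetric about 0).
#' @param angle_span Half-span of the angle fan, degrees; angles are equally
#'   spaced on `[-angle_span, +angle_span]`.
#' @param prf Pulse repetition frequency, Hz. Must equal
#'   `num_angles * frame_rate_in_ensemble`.
#' @param ensemble_len Frames per Doppler ensemble (>= 2).
#' @param frame_rate_in_ensemble Compounded frame rate within an ensemble, Hz.
#' @param ensemble_interval Seconds between successive ensembles.
#' @param num_elements Number of array elements.
#' @param pitch Element pitch, metres.
#' @param speed_of_sound Medium sound speed, m/s.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(center_frequency = 16e6,
                               num_angles = 5,
                               angle_span = 14,
                               prf = 5000,
                               ensemble_len = 400,
                               frame_rate_in_ensemble = 1000,
                               ensemble_interval = 2.5,
                               num_elements = 128,
                               pitch = 1e-4,
                               speed_of_sound = 1540) {
  if (ensemble_len < 2) stop("ensemble_len must be >= 2", call. = FALSE)
  if (ensemble_interval <= 0)
    stop("ensemble_interval must be positive", call. = FALSE)
  if (prf != num_angles * frame_rate_in_ensemble)
    stop(sprintf("prf (%g) must equal num_angles * frame_rate_in_ensemble (%g * %g = %g)",
                 prf, num_angles, frame_rate_in_ensemble,
                 num_angles * frame_rate_in_ensemble), call. = FALSE)
  stopifnot(center_frequency > 0, num_elements >= 2, pitch > 0,
            speed_of_sound > 0, angle_span >= 0, num_angles >= 1)
  structure(
    list(center_frequency = center_frequency,
         num_angles = num_angles,
         angle_span = angle_span,
         prf = prf,
         ensemble_len = ensemble_len,
         frame_rate_in_ensemble = frame_rate_in_ensemble,
         ensemble_interval = ensemble_interval,
         num_elements = num_elements,
         pitch = pitch,
         speed_of_sound = speed_of_sound),
    class = "acquisition_config")
}

#' Compounding angle list for an acquisition
#'
#' Equally spaced, symmetric about 0 (a single angle is 0).
#'
#' @param acq An [acquisition_config()] object.
#' @return Numeric vector of angles in degrees.
#' @export
compounding_angles <- function(acq) {
  stopifnot(inherits(acq, "acquisition_config"))
  if (acq$num_angles == 1L) return(0)
  seq(-acq$angle_span, acq$angle_span, length.out = acq$num_angles)
}

#' Element lateral positions (metres), centred on the array
#' @param acq An [acquisition_config()] object.
#' @return Numeric vector of length `num_elements`.
#' @export
element_positions <- function(acq) {
  stopifnot(inherits(acq, "acquisition_config"))
  (seq_len(acq$num_elements) - 1 - (acq$num_elements - 1) / 2) * acq$pitch
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> %g MHz, %d angles +/-%g deg, PRF %g Hz\n",
    x$center_frequency / 1e6, x$num_angles, x$angle_span, x$prf))
  cat(sprintf("  ensembles: %d frames @ %g Hz every %g s; %d elements, pitch %g um\n",
              x$ensemble_len, x$frame_rate_in_ensemble, x$ensemble_interval,
              x$num_elements, x$pitch * 1e6))
  invisible(x)
}
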