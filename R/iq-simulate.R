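# IQ Doppler ensemble simulation: blood tones confined to the vessel mask,
# low-rank slowly varying tissue clutter, and complex white noise.

#' IQ Doppler ensemble
#'
#' A complex `depth x lateral x slow-time` array with acquisition metadata.
#'
#' @param values Complex 3-D array.
#' @param frame_rate Slow-time frame rate, Hz.
#' @param timestamp Session time of the first frame, seconds.
#' @param aliased Logical flag: some simulated velocity exceeded the Nyquist
#'   limit of the slow-time sampling.
#' @return Object of class `iq_ensemble` (a classed array).
#' @export
iq_ensemble <- function(values, frame_rate, timestamp = 0, aliased = FALSE) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (!is.complex(values)) storage.mode(values) <- "complex"
  structure(values, frame_rate = frame_rate, timestamp = timestamp,
            aliased = aliased, class = c("iq_ensemble", "array"))
}

#' @export
print.iq_ensemble <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<iq_ensemble> %d x %d px, %d frames @ %g Hz, t = %g s%s\n",
              d[1], d[2], d[3], attr(x, "frame_rate"), attr(x, "timestamp"),
              if (isTRUE(attr(x, "aliased"))) " [aliased]" else ""))
  invisible(x)
}

#' Simulate one IQ Doppler ensemble
#'
#' Each vessel pixel carries a Doppler tone
#' `a * sqrt(m(t)) * exp(i(2 pi f_d n / fr + phi0 + jitter_n))` with Doppler
#' shift `f_d = 2 v f_c / c`, where the CBV multiplier `m(t)` applies to
#' pixels in the active ROI only. Every pixel additionally carries
#' rank-`clutter_rank` clutter (frozen smooth spatial modes times slow,
#' sub-2 Hz temporal modes redrawn per ensemble) and i.i.d. complex Gaussian
#' noise. Deterministic given `(scene$seed, t_ensemble)`.
#'
#' Velocities whose Doppler shift reaches the slow-time Nyquist rate are not
#' clipped; the ensemble is flagged `aliased` and a warning is raised.
#'
#' @param scene A [hemodynamic_scene()].
#' @param acq An [acquisition_config()].
#' @param t_ensemble Session time of the ensemble, seconds.
#' @param return_components Also return the separate blood / clutter / noise
#'   arrays (ground truth for filter tests).
#' @return An [iq_ensemble()], or a list
#'   `(total, blood, clutter, noise)` of ensembles when
#'   `return_components = TRUE`.
#' @export
simulate_iq_ensemble <- function(scene, acq, t_ensemble = 0,
                                 return_components = FALSE) {
  stopifnot(inherits(scene, "hemodynamic_scene"),
            inherits(acq, "acquisition_config"), t_ensemble >= 0)
  d <- scene$grid_shape[1]; l <- scene$grid_shape[2]
  n <- acq$ensemble_len
  fr <- acq$frame_rate_in_ensemble
  npix <- d * l
  vsl <- which(scene$vessel_mask)
  p_ref <- scene$blood_amplitude^2
  if (p_ref == 0) p_ref <- 1  # reference for clutter/noise when blood is off

  f_d <- 2 * scene$blood_velocity_map[vsl] * acq$center_frequency /
    acq$speed_of_sound
  aliased <- any(f_d >= fr / 2)
  if (aliased)
    warning("simulated Doppler shift at or above Nyquist (", fr / 2,
            " Hz): ensemble flagged as aliased", call. = FALSE)

  .with_seed(.stream_seed(scene$seed, t_ensemble), {
    blood <- matrix(0 + 0i, npix, n)
    if (scene$blood_amplitude > 0 && length(vsl) > 0) {
      m <- cbv_multiplier(t_ensemble, scene$timecourse)
      gain <- ifelse(scene$roi_active[vsl], m, 1)
      amp <- scene$blood_amplitude_map[vsl] * sqrt(gain)
      ph <- outer(f_d, 0:(n - 1)) * (2 * pi / fr) + scene$blood_phase0[vsl]
      if (scene$phase_jitter_sd > 0) {
        jit <- matrix(stats::rnorm(length(vsl) * n, 0, scene$phase_jitter_sd),
                      length(vsl), n)
        ph <- ph + t(apply(jit, 1, cumsum))
      }
      blood[vsl, ] <- amp * exp(1i * ph)
    }

    clutter <- matrix(0 + 0i, npix, n)
    if (scene$clutter_rank > 0 && is.finite(scene$clutter_to_blood_db)) {
      p_clutter <- p_ref * 10^(scene$clutter_to_blood_db / 10)
      tt <- (0:(n - 1)) / fr
      # one slow temporal band per mode (drift / respiration-like / faster
      # wobble, all below 2 Hz) with 1/r power weights: distinct, physically
      # plausible components with a clean singular-value hierarchy
      bands <- list(c(0.02, 0.4), c(0.4, 1.0), c(1.0, 2.0))
      w <- (1 / seq_len(scene$clutter_rank))
      w <- w / sum(w)
      G <- vapply(seq_len(scene$clutter_rank), function(r) {
        band <- bands[[(r - 1) %% length(bands) + 1]]
        g <- rowSums(vapply(1:3, function(j) {
          f <- sample(c(-1, 1), 1) * stats::runif(1, band[1], band[2])
          a <- stats::runif(1, 0.5, 1)
          a * exp(1i * (2 * pi * f * tt + stats::runif(1, 0, 2 * pi)))
        }, complex(n)))
        g / sqrt(mean(Mod(g)^2))
      }, complex(n))
      U <- vapply(scene$clutter_modes, as.vector, complex(npix))
      clutter <- (U * rep(sqrt(p_clutter * w), each = npix)) %*% t(G)
    }

    noise <- matrix(0 + 0i, npix, n)
    if (is.finite(scene$noise_to_blood_db)) {
      sig <- sqrt(p_ref * 10^(scene$noise_to_blood_db / 10) / 2)
      noise <- matrix(complex(real = stats::rnorm(npix * n, 0, sig),
                              imaginary = stats::rnorm(npix * n, 0, sig)),
                      npix, n)
    }
  })

  shape3 <- function(m) iq_ensemble(array(m, dim = c(d, l, n)),
                                    frame_rate = fr, timestamp = t_ensemble,
                                    aliased = aliased)
  total <- shape3(blood + clutter + noise)
  if (!return_components) return(total)
  list(total = total, blood = shape3(blood), clutter = shape3(clutter),
       noise = shape3(noise))
}

#' Simulate a time-compressed imaging session
#'
#' Ensembles are spaced `ensemble_interval * time_compression` seconds apart
#' in session time, so the multi-hour protocol (30 min baseline, drug
#' response, decay) fits in a desk-scale number of ensembles while every
#' epoch boundary keeps its physiological position. The ground-truth active
#' multiplier at each timestamp is recorded for recovery tests.
#'
#' @param scene A [hemodynamic_scene()].
#' @param acq An [acquisition_config()].
#' @param n_ensembles Number of ensembles (>= 1).
#' @param time_compression Cadence compression factor (default 60).
#' @param keep_iq Materialise all ensembles in memory (`$iq` list). With the
#'   default `FALSE` the session stays lazy: use [session_ensemble()].
#' @return An object of class `fus_session`: timestamps, truth multipliers,
#'   scene, acquisition, and optionally the IQ data.
#' @export
simulate_session <- function(scene, acq, n_ensembles,
                             time_compression = 60, keep_iq = FALSE) {
  stopifnot(inherits(scene, "hemodynamic_scene"),
            inherits(acq, "acquisition_config"),
            n_ensembles >= 1, time_compression > 0)
  timestamps <- (seq_len(n_ensembles) - 1) * acq$ensemble_interval *
    time_compression
  truth <- cbv_multiplier(timestamps, scene$timecourse)
  ses <- structure(
    list(scene = scene, acq = acq, timestamps = timestamps,
         truth_multiplier = truth, time_compression = time_compression,
         n_ensembles = as.integer(n_ensembles), iq = NULL),
    class = "fus_session")
  if (keep_iq)
    ses$iq <- lapply(timestamps, function(t)
      simulate_iq_ensemble(scene, acq, t))
  ses
}

#' Materialise the k-th ensemble of a session
#'
#' @param session A [simulate_session()] result.
#' @param k Ensemble index (1-based).
#' @return An [iq_ensemble()].
#' @export
session_ensemble <- function(session, k) {
  stopifnot(inherits(session, "fus_session"),
            k >= 1, k <= session$n_ensembles)
  if (!is.null(session$iq)) return(session$iq[[k]])
  simulate_iq_ensemble(session$scene, session$acq, session$timestamps[k])
}

#' @export
print.fus_session <- function(x, ...) {
  cat(sprintf("<fus_session> %d ensembles every %g s (compression %gx), span %g s\n",
              x$n_ensembles, x$acq$ensemble_interval * x$time_compression,
              x$time_compression, max(x$timestamps)))
  cat(sprintf("  truth multiplier: max %.3f at t = %g s\n",
              max(x$truth_multiplier),
              x$timestamps[which.max(x$truth_multiplier)]))
  invisible(x)
}
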