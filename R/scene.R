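# Synthetic hemodynamic scenes: the ground-truth world every downstream
# stage is tested against. Scene-level randomness (vessel geometry,
# velocities, clutter spatial modes, blood phase offsets) is frozen at
# construction from `seed`; per-ensemble randomness is drawn from a stream
# seed derived deterministically from (seed, ensemble time).

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-ensemble stream seed, kept below 2^31.
.stream_seed <- function(seed, t_ensemble) {
  (abs(seed) %% 65011 + 1) * 31627 +
    (round(t_ensemble * 1000) %% 999983)
}

# Smooth complex spatial field: sum of a few low-order 2D cosine products
# with random phases; unit RMS. Used for clutter spatial modes.
.smooth_field <- function(d, l, n_terms = 4L) {
  zx <- seq(0, 1, length.out = d)
  zy <- seq(0, 1, length.out = l)
  f <- matrix(0 + 0i, d, l)
  for (j in seq_len(n_terms)) {
    kx <- sample(0:2, 1)
    ky <- sample(0:2, 1)
    ph <- runif(2, 0, 2 * pi)
    amp <- runif(1, 0.5, 1)
    f <- f + amp * exp(1i * runif(1, 0, 2 * pi)) *
      outer(cos(2 * pi * kx * zx + ph[1]), cos(2 * pi * ky * zy + ph[2]))
  }
  f / sqrt(mean(Mod(f)^2))
}

#' Synthetic hemodynamic scene
#'
#' Defines the ground truth used by the IQ simulator: a vessel mask with
#' per-pixel blood velocities and amplitudes, a low-rank tissue-clutter
#' model, additive complex white noise, active/control regions of interest,
#' and the drug-response time course. All scene-level randomness is frozen
#' at construction, so the same seed always yields the same world.
#'
#' Power ratios are given in dB relative to the reference blood power
#' `blood_amplitude^2`; `-Inf` switches a component off entirely.
#'
#' @param grid_shape `c(depth_px, lateral_px)` of the imaging grid.
#' @param vessel_mask Optional logical matrix; when `NULL` a default vascular
#'   pattern is drawn (denser within the two ROIs, sparse elsewhere).
#' @param roi_active,roi_control Optional logical matrices (motor-cortex
#'   analogue and a non-responding control region); defaults are rectangles.
#' @param blood_velocity_range Range of per-pixel blood speeds, m/s.
#' @param blood_amplitude Linear blood echo amplitude scale.
#' @param amplitude_jitter Half-width of the multiplicative uniform jitter on
#'   per-pixel blood amplitudes (0.3 means U(0.7, 1.3)).
#' @param clutter_rank Number of spatiotemporal clutter modes.
#' @param clutter_to_blood_db Clutter power relative to blood, dB.
#' @param noise_to_blood_db Noise power relative to blood, dB.
#' @param phase_jitter_sd Per-frame standard deviation (radians) of the
#'   random-walk phase jitter decorrelating blood pixels.
#' @param timecourse A [timecourse_params()] object.
#' @param seed Integer seed freezing the scene.
#' @return An object of class `hemodynamic_scene`.
#' @export
hemodynamic_scene <- function(grid_shape = c(64, 64),
                              vessel_mask = NULL,
                              roi_active = NULL,
                              roi_control = NULL,
                              blood_velocity_range = c(1e-3, 10e-3),
                              blood_amplitude = 1,
                              amplitude_jitter = 0.3,
                              clutter_rank = 3L,
                              clutter_to_blood_db = 40,
                              noise_to_blood_db = -10,
                              phase_jitter_sd = 0.2,
                              timecourse = timecourse_params(),
                              seed = 1L) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 4),
            inherits(timecourse, "timecourse_params"),
            blood_amplitude >= 0, clutter_rank >= 0)
  for (r in list(clutter_to_blood_db, noise_to_blood_db))
    if (is.na(r) || is.nan(r) || r == Inf)
      stop("dB ratios must be finite or -Inf (off)", call. = FALSE)
  d <- grid_shape[1]; l <- grid_shape[2]

  .with_seed(seed, {
    if (is.null(roi_active)) {
      roi_active <- matrix(FALSE, d, l)
      roi_active[max(2, round(d * 0.15)):round(d * 0.40),
                 max(2, round(l * 0.20)):round(l * 0.55)] <- TRUE
    }
    if (is.null(roi_control)) {
      roi_control <- matrix(FALSE, d, l)
      roi_control[round(d * 0.60):round(d * 0.85),
                  round(l * 0.45):round(l * 0.80)] <- TRUE
    }
    if (is.null(vessel_mask)) {
      vessel_mask <- matrix(stats::runif(d * l) < 0.06, d, l)
      vessel_mask[roi_active] <- stats::runif(sum(roi_active)) < 0.35
      vessel_mask[roi_control] <- stats::runif(sum(roi_control)) < 0.35
    }
    stopifnot(dim(vessel_mask) == c(d, l), dim(roi_active) == c(d, l),
              dim(roi_control) == c(d, l))
    if (!any(vessel_mask)) stop("vessel_mask is empty", call. = FALSE)
    if (!any(roi_active & vessel_mask))
      stop("roi_active contains no vessel pixels", call. = FALSE)

    nv <- sum(vessel_mask)
    velocity <- matrix(0, d, l)
    velocity[vessel_mask] <- stats::runif(nv, blood_velocity_range[1],
                                          blood_velocity_range[2])
    amp <- matrix(0, d, l)
    amp[vessel_mask] <- blood_amplitude *
      stats::runif(nv, 1 - amplitude_jitter, 1 + amplitude_jitter)
    phase0 <- matrix(0, d, l)
    phase0[vessel_mask] <- stats::runif(nv, 0, 2 * pi)
    clutter_modes <- if (clutter_rank > 0)
      lapply(seq_len(clutter_rank), function(r) .smooth_field(d, l))
    else list()
  })

  structure(
    list(grid_shape = c(d, l),
         vessel_mask = vessel_mask,
         roi_active = roi_active,
         roi_control = roi_control,
         blood_velocity_map = velocity,
         blood_amplitude_map = amp,
         blood_amplitude = blood_amplitude,
         blood_phase0 = phase0,
         clutter_rank = as.integer(clutter_rank),
         clutter_modes = clutter_modes,
         clutter_to_blood_db = clutter_to_blood_db,
         noise_to_blood_db = noise_to_blood_db,
         phase_jitter_sd = phase_jitter_sd,
         timecourse = timecourse,
         seed = as.integer(seed)),
    class = "hemodynamic_scene")
}

#' @export
print.hemodynamic_scene <- function(x, ...) {
  cat(sprintf("<hemodynamic_scene> %dx%d px, %d vessel px, clutter rank %d (%g dB), noise %g dB, seed %d\n",
              x$grid_shape[1], x$grid_shape[2], sum(x$vessel_mask),
              x$clutter_rank, x$clutter_to_blood_db, x$noise_to_blood_db,
              x$seed))
  invisible(x)
}

#' Ground-truth blood power map at a given session time
#'
#' Per-pixel expected blood power `amp^2 * m(t)` for responding pixels
#' (active-ROI vessels) and `amp^2` elsewhere on the vessel mask.
#'
#' @param scene A [hemodynamic_scene()].
#' @param t Session time, seconds.
#' @return Matrix of expected blood power.
#' @export
true_blood_power <- function(scene, t = 0) {
  stopifnot(inherits(scene, "hemodynamic_scene"))
  m <- cbv_multiplier(t, scene$timecourse)
  gain <- ifelse(scene$roi_active & scene$vessel_mask, m, 1)
  scene$blood_amplitude_map^2 * gain
}
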