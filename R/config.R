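# Pipeline configuration: a nested list (or YAML file) validated against
# the default tree. Unknown keys and cross-field violations are collected
# exhaustively and reported together.

#' Default pipeline configuration
#'
#' The default tree describes the package's reference harmaline scenario:
#' a 64 x 64 grid, 70 ensembles of 400 frames at the compressed 2.5 s x 60
#' cadence, 30 min baseline, +160 percent peak CBV response, rank-3 clutter
#' 40 dB above blood and noise 10 dB below blood.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    acquisition = list(
      center_frequency = 16e6, num_angles = 5L, angle_span = 14,
      prf = 5000, ensemble_len = 400L, frame_rate_in_ensemble = 1000,
      ensemble_interval = 2.5, num_elements = 128L, pitch = 1e-4,
      speed_of_sound = 1540),
    scene = list(
      grid_shape = c(64L, 64L), blood_amplitude = 1,
      blood_velocity_range = c(1e-3, 10e-3), amplitude_jitter = 0.3,
      clutter_rank = 3L, clutter_to_blood_db = 40, noise_to_blood_db = -10,
      phase_jitter_sd = 0.2),
    timecourse = list(
      t_baseline_end = 1800, peak_fractional_increase = 1.6,
      rise_tau = 180, decay_tau = 7200, suppression_enabled = FALSE,
      t_suppressor = 3000, suppression_depth = 0.8, rebound_tau = 600),
    session = list(n_ensembles = 70L, time_compression = 60),
    filter = list(method = "energy_knee", fixed_k = NULL,
                  low_cut_margin = 1L, noise_tail_frac = 0.25),
    mapping = list(baseline_t_start = 0, baseline_t_end = 1800,
                   smooth_kernel = 10L, floor_quantile = 0.01),
    stats = list(half_window = 5L, t1 = "peak", t2 = "late"),
    ephys = list(enabled = FALSE, fs_raw = 20000, tremor_freqs = c(5, 30),
                 tremor_amps = c(1, 0.7), tremor_mod_gain = 1,
                 line_freq = 60, line_amp = 0.5, pink_noise_level = 0.3,
                 duration = 180, window_len = 10, step = 5,
                 time_bandwidth = 3, n_tapers = 5L,
                 baseline = c(0, 20)),
    io = list(store_iq = FALSE))
}

# Merge user values over defaults, recording unknown keys with their path.
.merge_config <- function(defaults, user, path = "", unknown) {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      unknown$keys <- c(unknown$keys, full)
    } else if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (is.list(user[[key]]))
        defaults[[key]] <- .merge_config(defaults[[key]], user[[key]],
                                         full, unknown)
      else unknown$keys <- c(unknown$keys,
                             paste0(full, " (expected a section)"))
    } else if (!is.null(user[[key]])) {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate and normalise a pipeline configuration
#'
#' Reads YAML when given a path, injects defaults for every omitted key,
#' rejects unknown keys by name, and checks cross-field invariants
#' (`prf = num_angles * frame_rate_in_ensemble`, positive intervals and
#' time constants, baseline window before the injection, ...). All
#' violations are reported together, not first-only.
#'
#' @param config A nested list, a YAML file path, or `NULL`/empty for pure
#'   defaults.
#' @return The normalised configuration list (class `microdoppler_config`).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (inherits(config, "microdoppler_config")) config <- unclass(config)
  stopifnot(is.list(config))
  unknown <- new.env(); unknown$keys <- character()
  cfg <- .merge_config(default_config(), config, "", unknown)
  errors <- character()
  if (length(unknown$keys))
    errors <- c(errors, paste0("unknown config key: ", unknown$keys))

  a <- cfg$acquisition
  if (a$prf != a$num_angles * a$frame_rate_in_ensemble)
    errors <- c(errors, sprintf(
      "acquisition: prf (%g) != num_angles * frame_rate_in_ensemble (%g * %g = %g)",
      a$prf, a$num_angles, a$frame_rate_in_ensemble,
      a$num_angles * a$frame_rate_in_ensemble))
  if (a$ensemble_interval <= 0)
    errors <- c(errors, "acquisition: ensemble_interval must be positive")
  if (a$ensemble_len < 2)
    errors <- c(errors, "acquisition: ensemble_len must be >= 2")
  tc <- cfg$timecourse
  if (tc$rise_tau <= 0 || tc$decay_tau <= 0)
    errors <- c(errors, "timecourse: rise_tau and decay_tau must be positive")
  if (cfg$session$n_ensembles < 1)
    errors <- c(errors, "session: n_ensembles must be >= 1")
  if (cfg$session$time_compression <= 0)
    errors <- c(errors, "session: time_compression must be positive")
  if (!cfg$filter$method %in% c("energy_knee", "fixed"))
    errors <- c(errors, "filter: method must be 'energy_knee' or 'fixed'")
  if (cfg$filter$noise_tail_frac <= 0 || cfg$filter$noise_tail_frac >= 1)
    errors <- c(errors, "filter: noise_tail_frac must lie in (0, 1)")
  if (cfg$mapping$baseline_t_end <= cfg$mapping$baseline_t_start)
    errors <- c(errors, "mapping: baseline window must have positive length")
  if (cfg$mapping$baseline_t_end > tc$t_baseline_end)
    errors <- c(errors,
                "mapping: baseline window must end by timecourse$t_baseline_end")
  if (cfg$mapping$smooth_kernel < 1)
    errors <- c(errors, "mapping: smooth_kernel must be >= 1")
  if (cfg$stats$half_window < 0)
    errors <- c(errors, "stats: half_window must be >= 0")
  if (cfg$ephys$enabled && cfg$ephys$fs_raw < 4000)
    errors <- c(errors, "ephys: fs_raw must be >= 4 kHz")

  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  structure(cfg, class = "microdoppler_config")
}
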