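# Pipeline orchestration: simulate -> SVD clutter filter -> microDoppler ->
# noise-bias removal -> activation mapping -> ROI statistics, with the
# optional electrophysiology arm, logging and a run manifest. One config
# seed fans out deterministically to per-stage seeds (scene = seed,
# ephys = seed + 7001; per-ensemble noise streams derive from the scene
# seed and the ensemble time), so any stage can be rerun in isolation.

.stage_seeds <- function(seed) {
  list(scene = as.integer(seed), ephys = as.integer(seed) + 7001L)
}

#' Build the scene described by a configuration
#'
#' @param cfg A validated configuration ([validate_config()]).
#' @return A [hemodynamic_scene()].
#' @export
scene_from_config <- function(cfg) {
  cfg <- validate_config(cfg)
  tc <- cfg$timecourse
  hemodynamic_scene(
    grid_shape = cfg$scene$grid_shape,
    blood_velocity_range = cfg$scene$blood_velocity_range,
    blood_amplitude = cfg$scene$blood_amplitude,
    amplitude_jitter = cfg$scene$amplitude_jitter,
    clutter_rank = cfg$scene$clutter_rank,
    clutter_to_blood_db = cfg$scene$clutter_to_blood_db,
    noise_to_blood_db = cfg$scene$noise_to_blood_db,
    phase_jitter_sd = cfg$scene$phase_jitter_sd,
    timecourse = timecourse_params(
      t_baseline_end = tc$t_baseline_end,
      peak_fractional_increase = tc$peak_fractional_increase,
      rise_tau = tc$rise_tau, decay_tau = tc$decay_tau,
      suppression_enabled = tc$suppression_enabled,
      t_suppressor = tc$t_suppressor,
      suppression_depth = tc$suppression_depth,
      rebound_tau = tc$rebound_tau),
    seed = .stage_seeds(cfg$seed)$scene)
}

#' Build the acquisition described by a configuration
#'
#' @param cfg A validated configuration ([validate_config()]).
#' @return An [acquisition_config()].
#' @export
acquisition_from_config <- function(cfg) {
  cfg <- validate_config(cfg)
  do.call(acquisition_config, cfg$acquisition)
}

#' Filter one session and assemble the microDoppler series
#'
#' Streams the ensembles of a (lazy) session through [svd_filter()] (global
#' singular-order threshold chosen per ensemble), reconstructs the full
#' above-threshold band, removes the noise bias estimated from the
#' high-order residual, and collects the noise-corrected microDoppler
#' images. Returns the series plus per-ensemble diagnostics.
#'
#' @param session A [simulate_session()] result.
#' @param cfg Validated configuration (its `filter` section is used).
#' @return List: `series` ([md_series()]), `diagnostics` data frame
#'   (ensemble, low_cut, clamp fraction), `singular_values` matrix
#'   (order x ensemble).
#' @export
microdoppler_from_session <- function(session, cfg = default_config()) {
  cfg <- validate_config(cfg)
  n <- session$acq$ensemble_len
  tail_dim <- max(4L, round(cfg$filter$noise_tail_frac * n))
  imgs <- vector("list", session$n_ensembles)
  low_cuts <- integer(session$n_ensembles)
  clamp <- numeric(session$n_ensembles)
  svmat <- matrix(NA_real_, min(n, prod(session$scene$grid_shape)),
                  session$n_ensembles)
  for (k in seq_len(session$n_ensembles)) {
    ens <- session_ensemble(session, k)
    res <- svd_filter(ens, low_cut = NULL, high_cut = n - tail_dim,
                      select_method = cfg$filter$method,
                      fixed_k = cfg$filter$fixed_k,
                      low_cut_margin = cfg$filter$low_cut_margin)
    low_cuts[k] <- res$low_cut
    svmat[seq_along(res$singular_values), k] <- res$singular_values
    # the high cut only exposes the noise tail; the image keeps all orders
    # above low_cut
    full <- iq_ensemble(unclass(res$filtered) + unclass(res$residual),
                        frame_rate = attr(res$filtered, "frame_rate"),
                        timestamp = attr(res$filtered, "timestamp"))
    raw <- power_doppler(full, ensemble_index = k)
    prof <- estimate_noise_profile(res, "high_order_residual",
                                   target_dim = n - res$low_cut)
    img <- remove_noise_bias(raw, prof)
    clamp[k] <- attr(img, "clamp_frac")
    imgs[[k]] <- img
  }
  list(series = md_series(imgs),
       diagnostics = data.frame(ensemble = seq_len(session$n_ensembles),
                                timestamp = session$timestamps,
                                low_cut = low_cuts,
                                clamp_frac = clamp),
       singular_values = svmat)
}

# Resolve the configured contrast time points against a smoothed trace.
# "peak" is the post-injection maximum of the smoothed trace (global
# maximum when the session is all baseline), clamped so its +/-h window
# fits the session and stays clear of the late window.
.contrast_times <- function(cfg, trace, session) {
  h <- cfg$stats$half_window
  n <- nrow(trace)
  i2 <- n - h
  t2 <- cfg$stats$t2
  if (identical(t2, "late")) t2 <- trace$time[i2] else i2 <- which.min(abs(trace$time - t2))
  t1 <- cfg$stats$t1
  if (identical(t1, "peak")) {
    cand <- which(trace$time > cfg$timecourse$t_baseline_end)
    if (!length(cand)) cand <- seq_len(n)
    i1 <- cand[which.max(trace$smoothed[cand])]
    i1 <- min(max(i1, h + 1), n - h)
    if (abs(i1 - i2) <= 2 * h) i1 <- max(h + 1, i2 - 2 * h - 1)
    t1 <- trace$time[i1]
  }
  list(t1 = as.numeric(t1), t2 = as.numeric(t2))
}

#' Run the full pipeline described by a configuration
#'
#' Simulates the session, filters and maps it, extracts ROI traces and
#' time-point contrasts, optionally runs the electrophysiology arm, and
#' writes the session container, TIFF stacks, CSV tables, a log and a JSON
#' run manifest into `out_dir`. Any stage failure stops the run with the
#' manifest marking the failed stage; outputs of completed stages are kept.
#'
#' @param config Configuration list, YAML path, or `NULL` for defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results: `session`,
#'   `series`, `activation`, `traces`, `contrasts`, `ephys`, `manifest`.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  manifest <- list(package_version = as.character(utils::packageVersion("microdoppler")),
                   seed = cfg$seed, stage_seeds = .stage_seeds(cfg$seed),
                   config = unclass(cfg), started = format(Sys.time()),
                   stages = list())
  logline <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  save_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    manifest$stages[[name]] <<- list(status = "running")
    save_manifest()
    out <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      save_manifest()
      logline("stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = round(dt, 2))
    logline("stage ", name, " ok (", round(dt, 1), " s)")
    out
  }

  sim <- stage("simulate", {
    scene <- scene_from_config(cfg)
    acq <- acquisition_from_config(cfg)
    simulate_session(scene, acq, cfg$session$n_ensembles,
                     time_compression = cfg$session$time_compression)
  })

  md <- stage("filter_map", microdoppler_from_session(sim, cfg))

  act <- stage("activation", {
    bl <- baseline_image(md$series,
                         baseline_spec(cfg$mapping$baseline_t_start,
                                       cfg$mapping$baseline_t_end))
    activation_map(md$series, bl, vessel_mask = sim$scene$vessel_mask,
                   floor_quantile = cfg$mapping$floor_quantile)
  })

  traces <- stage("roi_traces", {
    tr <- list(active = roi_trace(act, sim$scene$roi_active),
               control = roi_trace(act, sim$scene$roi_control))
    lapply(tr, smooth_trace, kernel_len = cfg$mapping$smooth_kernel)
  })

  contrasts <- stage("stats", {
    tp <- .contrast_times(cfg, traces$active, sim)
    lapply(traces, function(tr) {
      run_contrast(tr, timepoint_contrast(tp$t1, tp$t2,
                                          half_window = cfg$stats$half_window))
    })
  })

  ephys <- if (cfg$ephys$enabled) stage("ephys", {
    ep <- cfg$ephys
    params <- ephys_scene_params(
      fs_raw = ep$fs_raw, tremor_freqs = ep$tremor_freqs,
      tremor_amps = ep$tremor_amps, tremor_mod_gain = ep$tremor_mod_gain,
      line_freq = ep$line_freq, line_amp = ep$line_amp,
      pink_noise_level = ep$pink_noise_level, duration = ep$duration,
      time_compression = cfg$session$time_compression,
      seed = .stage_seeds(cfg$seed)$ephys)
    raw <- simulate_lfp(params, sim$scene$timecourse)
    pre <- preprocess_lfp(raw, line_freq = ep$line_freq)
    spec <- multitaper_spectrogram(pre, window_len = ep$window_len,
                                   step = ep$step,
                                   time_bandwidth = ep$time_bandwidth,
                                   n_tapers = ep$n_tapers)
    norm <- normalize_baseline(spec, ep$baseline)
    list(raw = raw, preprocessed = pre, spectrogram = norm,
         bands = list(tremor_low = band_power(norm, c(4, 6)),
                      tremor_high = band_power(norm, c(28, 32))))
  }) else NULL

  stage("export", {
    write_session(sim, file.path(out_dir, "session.rds"),
                  include_iq = isTRUE(cfg$io$store_iq),
                  ephys = ephys$raw)
    export_md_tiff(md$series, file.path(out_dir, "microdoppler.tif"),
                   file.path(out_dir, "timestamps.csv"))
    export_fam_tiff(act, file.path(out_dir, "fam.tif"))
    export_traces_csv(traces, file.path(out_dir, "roi_traces.csv"))
    utils::write.csv(do.call(rbind, lapply(contrasts, `[[`, "summary")),
                     file.path(out_dir, "contrasts.csv"), row.names = FALSE)
    utils::write.csv(cbind(order = seq_len(nrow(md$singular_values)),
                           as.data.frame(md$singular_values)),
                     file.path(out_dir, "singular_values.csv"),
                     row.names = FALSE)
    utils::write.csv(md$diagnostics,
                     file.path(out_dir, "filter_diagnostics.csv"),
                     row.names = FALSE)
    export_preview_png(md$series, file.path(out_dir, "microdoppler_preview.png"))
    if (!is.null(ephys)) {
      utils::write.csv(
        data.frame(time = ephys$bands$tremor_low$time,
                   band_4_6 = ephys$bands$tremor_low$power,
                   band_28_32 = ephys$bands$tremor_high$power),
        file.path(out_dir, "ephys_bandpower.csv"), row.names = FALSE)
      export_spectrogram_tiff(ephys$spectrogram,
                              file.path(out_dir, "spectrogram.tif"),
                              file.path(out_dir, "spectrogram_axes.csv"))
    }
    NULL
  })

  logline("session low_cut median: ",
          stats::median(md$diagnostics$low_cut))
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% c("manifest.json", "log.txt")]
  manifest$outputs <- lapply(stats::setNames(outputs, basename(outputs)),
                             function(f) list(md5 = unname(tools::md5sum(f)),
                                              bytes = file.size(f)))
  manifest$finished <- format(Sys.time())
  save_manifest()
  invisible(list(session = sim, series = md$series,
                 diagnostics = md$diagnostics, activation = act,
                 traces = traces, contrasts = contrasts, ephys = ephys,
                 manifest = manifest))
}
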