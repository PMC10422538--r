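# Session container and standard-format exports. The on-disk container is a
# single RDS file whose named components mirror the pipeline's dataset
# layout (iq, timestamps, truth/multiplier, masks/*, ephys/raw, acquisition
# attributes); images export to multi-page 32-bit float TIFF and traces,
# spectra and statistics to CSV.

#' Write a session container
#'
#' @param session A [simulate_session()] result.
#' @param path Output file path (`.rds`).
#' @param include_iq Store the full IQ array (large); default metadata,
#'   masks and truth only.
#' @param ephys Optional [lfp_recording()] stored under `$ephys`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, include_iq = FALSE, ephys = NULL) {
  stopifnot(inherits(session, "fus_session"))
  iq <- NULL
  if (include_iq) {
    d <- session$scene$grid_shape
    n <- session$acq$ensemble_len
    iq <- array(0 + 0i, c(d, n, session$n_ensembles))
    for (k in seq_len(session$n_ensembles))
      iq[, , , k] <- unclass(session_ensemble(session, k))
  }
  container <- list(
    layout_version = 1L,
    iq = iq,
    timestamps = session$timestamps,
    truth = list(multiplier = session$truth_multiplier),
    masks = list(vessel = session$scene$vessel_mask,
                 roi_active = session$scene$roi_active,
                 roi_control = session$scene$roi_control),
    acquisition = unclass(session$acq),
    scene_seed = session$scene$seed,
    time_compression = session$time_compression,
    ephys = if (!is.null(ephys)) list(raw = ephys$samples, fs = ephys$fs))
  saveRDS(container, path)
  invisible(path)
}

#' Read a session container written by [write_session()]
#' @param path Container path.
#' @return The container list.
#' @export
read_session <- function(path) {
  x <- readRDS(path)
  stopifnot(is.list(x), !is.null(x$timestamps))
  x
}

# Write a stack of matrices as a multi-page 32-bit float TIFF. TIFF float
# pages are stored on [0, 1], so the stack is affinely rescaled and the
# (offset, scale) pair recorded in a sidecar CSV next to the file:
# original = offset + scale * stored.
.write_tiff_stack <- function(mats, path) {
  vals <- unlist(lapply(mats, function(m) m[is.finite(m)]))
  lo <- if (length(vals)) min(vals) else 0
  hi <- if (length(vals)) max(vals) else 1
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(mats, function(m) {
    m[!is.finite(m)] <- lo
    (m - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  utils::write.csv(data.frame(offset = lo, scale = scale),
                   paste0(path, ".scale.csv"), row.names = FALSE)
  invisible(path)
}

#' Read back a TIFF stack written by the package's exporters
#'
#' Restores the original units using the sidecar scale file when present.
#'
#' @param path TIFF path.
#' @return List of matrices.
#' @export
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".scale.csv")
  if (file.exists(sidecar)) {
    sc <- utils::read.csv(sidecar)
    pages <- lapply(pages, function(m) sc$offset + sc$scale * m)
  }
  pages
}

#' Export a microDoppler series as multi-page TIFF plus a timestamp CSV
#'
#' @param series An [md_series()].
#' @param tiff_path Output TIFF path (one 32-bit float page per timestamp).
#' @param csv_path Optional CSV of frame timestamps.
#' @return `tiff_path`, invisibly.
#' @export
export_md_tiff <- function(series, tiff_path, csv_path = NULL) {
  stopifnot(inherits(series, "md_series"))
  nt <- dim(series$power)[3]
  .write_tiff_stack(lapply(seq_len(nt), function(k) series$power[, , k]),
                    tiff_path)
  if (!is.null(csv_path))
    utils::write.csv(data.frame(page = seq_len(nt),
                                timestamp = series$timestamps),
                     csv_path, row.names = FALSE)
  invisible(tiff_path)
}

#' Export an activation (FAM) series as multi-page TIFF
#'
#' Invalid pixels are written as 0 in the TIFF (TIFF float pages carry no
#' mask); the validity map is available from the `activation_series` itself.
#'
#' @param act An [activation_map()] result.
#' @param tiff_path Output TIFF path.
#' @return `tiff_path`, invisibly.
#' @export
export_fam_tiff <- function(act, tiff_path) {
  stopifnot(inherits(act, "activation_series"))
  nt <- dim(act$percent)[3]
  .write_tiff_stack(lapply(seq_len(nt), function(k) act$percent[, , k]),
                    tiff_path)
  invisible(tiff_path)
}

#' Write a log-compressed (dB) preview PNG of a microDoppler series
#'
#' Renders the time-mean microDoppler image on a dB scale (floor at
#' `dynamic_range` below the maximum) for quick visual inspection of the
#' recovered vasculature; quantitative work should use the TIFF stacks.
#'
#' @param series An [md_series()].
#' @param path Output PNG path.
#' @param dynamic_range Displayed dynamic range in dB.
#' @return `path`, invisibly.
#' @export
export_preview_png <- function(series, path, dynamic_range = 40) {
  stopifnot(inherits(series, "md_series"), dynamic_range > 0)
  avg <- apply(series$power, c(1, 2), mean)
  top <- max(avg)
  if (top <= 0) top <- 1
  db <- 10 * log10(pmax(avg / top, 10^(-dynamic_range / 10)))
  png::writePNG((db + dynamic_range) / dynamic_range, path)
  invisible(path)
}

#' Export a spectrogram as TIFF power plus CSV axes
#'
#' @param spec A `spectrogram`.
#' @param tiff_path Output TIFF (single 32-bit float page, time x frequency).
#' @param axes_csv_path CSV with the time and frequency axes.
#' @return `tiff_path`, invisibly.
#' @export
export_spectrogram_tiff <- function(spec, tiff_path, axes_csv_path = NULL) {
  stopifnot(inherits(spec, "spectrogram"))
  .write_tiff_stack(list(spec$power), tiff_path)
  if (!is.null(axes_csv_path)) {
    n <- max(length(spec$times), length(spec$freqs))
    utils::write.csv(
      data.frame(index = seq_len(n),
                 time_s = c(spec$times, rep(NA, n - length(spec$times))),
                 freq_hz = c(spec$freqs, rep(NA, n - length(spec$freqs)))),
      axes_csv_path, row.names = FALSE)
  }
  invisible(tiff_path)
}

#' Export ROI traces as CSV
#'
#' One row per timestamp with raw and smoothed percent change and the valid
#' pixel count, for each named trace.
#'
#' @param traces Named list of smoothed [roi_trace()] data frames (with a
#'   `smoothed` column).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_traces_csv <- function(traces, path) {
  stopifnot(is.list(traces), !is.null(names(traces)))
  rows <- do.call(rbind, lapply(names(traces), function(nm) {
    tr <- traces[[nm]]
    data.frame(roi = nm, timestamp = tr$time, percent = tr$percent,
               smoothed = if ("smoothed" %in% names(tr)) tr$smoothed
                          else NA_real_,
               n_valid = tr$n_valid)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
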