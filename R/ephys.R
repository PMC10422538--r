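# Electrophysiology arm: simulated tremor-band LFP, preprocessing
# (decimation, band-pass, line notches) and baseline-normalised multitaper
# spectrograms with band-power traces.

#' LFP recording container
#'
#' @param samples Real numeric vector of samples.
#' @param fs Sampling rate, Hz.
#' @param t0 Time of the first sample, seconds.
#' @return Object of class `lfp_recording`.
#' @export
lfp_recording <- function(samples, fs, t0 = 0) {
  stopifnot(is.numeric(samples), fs > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Ephys scene parameters
#'
#' Tremor-band oscillators (default 5 and 30 Hz) whose amplitudes are
#' modulated by the same CBV time course that drives the imaging arm, plus
#' 60 Hz line contamination and 1/f (pink) background noise. Like the
#' imaging session, the trace is time-compressed: sample time `t` maps to
#' session time `t * time_compression` when the time course is evaluated.
#'
#' @param fs_raw Raw sampling rate, Hz (default 20 kHz).
#' @param tremor_freqs Oscillator frequencies, Hz.
#' @param tremor_amps Baseline oscillator amplitudes (recycled).
#' @param tremor_mod_gain Gain coupling the oscillator amplitude to the CBV
#'   elevation: amplitude factor `1 + gain * (m(t) - 1)`.
#' @param line_freq,line_amp Line contamination frequency (Hz) and amplitude.
#' @param pink_noise_level RMS of the pink-noise background.
#' @param duration Trace duration, seconds.
#' @param time_compression Session-time compression factor (default 60).
#' @param seed Integer seed.
#' @return Object of class `ephys_scene_params`.
#' @export
ephys_scene_params <- function(fs_raw = 20000,
                               tremor_freqs = c(5, 30),
                               tremor_amps = c(1, 0.7),
                               tremor_mod_gain = 1,
                               line_freq = 60,
                               line_amp = 0.5,
                               pink_noise_level = 0.3,
                               duration = 180,
                               time_compression = 60,
                               seed = 1L) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (any(tremor_freqs >= fs_raw / 2))
    stop("tremor_freqs must be below fs_raw/2", call. = FALSE)
  stopifnot(fs_raw > 0, pink_noise_level >= 0, line_amp >= 0,
            time_compression > 0)
  structure(list(fs_raw = fs_raw, tremor_freqs = tremor_freqs,
                 tremor_amps = rep_len(tremor_amps, length(tremor_freqs)),
                 tremor_mod_gain = tremor_mod_gain,
                 line_freq = line_freq, line_amp = line_amp,
                 pink_noise_level = pink_noise_level, duration = duration,
                 time_compression = time_compression,
                 seed = as.integer(seed)),
            class = "ephys_scene_params")
}

# Pink (1/f amplitude) noise of length n, unit RMS, via spectral shaping.
.pink_noise <- function(n) {
  nf <- n %/% 2
  mag <- 1 / sqrt(seq_len(nf))
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = ph)
  full <- c(0 + 0i, spec,
            if (n %% 2 == 0) Re(spec[nf]) + 0i else complex(0),
            Conj(rev(spec[seq_len(nf - if (n %% 2 == 0) 1 else 0)])))
  x <- Re(stats::fft(full[seq_len(n)], inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Simulate a raw LFP trace
#'
#' `x(t) = sum_f A_f [1 + g (m(tc) - 1)] sin(2 pi f t + phi_f)
#'  + pink noise + line sinusoid`, with `m` the CBV multiplier evaluated at
#' compressed session time `tc = t * time_compression`. Deterministic given
#' the scene seed.
#'
#' @param params An [ephys_scene_params()].
#' @param timecourse A [timecourse_params()].
#' @return An [lfp_recording()] at `params$fs_raw`.
#' @export
simulate_lfp <- function(params, timecourse = timecourse_params()) {
  stopifnot(inherits(params, "ephys_scene_params"),
            inherits(timecourse, "timecourse_params"))
  n <- round(params$duration * params$fs_raw)
  t <- (0:(n - 1)) / params$fs_raw
  m <- cbv_multiplier(t * params$time_compression, timecourse)
  .with_seed(params$seed, {
    x <- numeric(n)
    for (j in seq_along(params$tremor_freqs)) {
      phi <- stats::runif(1, 0, 2 * pi)
      x <- x + params$tremor_amps[j] *
        (1 + params$tremor_mod_gain * (m - 1)) *
        sin(2 * pi * params$tremor_freqs[j] * t + phi)
    }
    if (params$pink_noise_level > 0)
      x <- x + params$pink_noise_level * .pink_noise(n)
    if (params$line_amp > 0)
      x <- x + params$line_amp * sin(2 * pi * params$line_freq * t)
  })
  lfp_recording(x, params$fs_raw)
}

# Zero-phase second-order notch (RBJ biquad) at f0 with quality factor q.
.notch_filtfilt <- function(x, fs, f0, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  signal::filtfilt(signal::Arma(b = b, a = a), x)
}

#' Preprocess a raw LFP recording
#'
#' Anti-aliased decimation to `fs_target` (FIR low-pass + subsampling when
#' the rate ratio is an integer; otherwise a resampling path with a
#' warning), zero-phase band-pass (`band`), and zero-phase second-order
#' notches at the line frequency and its harmonics up to the band edge.
#'
#' @param rec An [lfp_recording()] with `fs >= 4000`.
#' @param fs_target Output rate, Hz (default 2000).
#' @param band Pass band, Hz (default `c(0.1, 500)`).
#' @param line_freq Line frequency for the notch comb, Hz.
#' @param notch_q Notch quality factor.
#' @return The preprocessed [lfp_recording()] at `fs_target`.
#' @export
preprocess_lfp <- function(rec, fs_target = 2000, band = c(0.1, 500),
                           line_freq = 60, notch_q = 30) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (rec$fs < 4000) stop("input sampling rate must be >= 4 kHz",
                          call. = FALSE)
  x <- rec$samples
  r <- rec$fs / fs_target
  # anti-alias FIR sized to the rate ratio; normalised to exact unit DC
  # gain (short windowed-sinc kernels at narrow cutoffs are otherwise off
  # by several percent)
  anti_alias <- function(ratio) {
    co <- signal::fir1(max(48L, 10L * ceiling(ratio)), 0.8 / ratio)
    signal::Ma(unclass(co) / sum(co))
  }
  if (abs(r - round(r)) < 1e-9) {
    r <- round(r)
    x <- signal::filtfilt(anti_alias(r), x)
    x <- x[seq(1, length(x), by = r)]
  } else {
    warning("input rate is not an integer multiple of ", fs_target,
            " Hz: using interpolation resampling", call. = FALSE)
    x <- signal::filtfilt(anti_alias(r), x)
    told <- (seq_along(x) - 1) / rec$fs
    tnew <- seq(0, told[length(told)], by = 1 / fs_target)
    x <- stats::approx(told, x, xout = tnew)$y
  }
  nyq <- fs_target / 2
  hp <- signal::butter(2, band[1] / nyq, type = "high")
  x <- signal::filtfilt(hp, x)
  if (band[2] < nyq) {
    lp <- signal::butter(4, band[2] / nyq, type = "low")
    x <- signal::filtfilt(lp, x)
  }
  harmonics <- seq(line_freq, min(band[2], nyq * 0.999), by = line_freq)
  for (f0 in harmonics) x <- .notch_filtfilt(x, fs_target, f0, notch_q)
  lfp_recording(x, fs_target, rec$t0)
}

#' Multitaper spectrogram
#'
#' Sliding-window average of tapered periodograms using DPSS tapers
#' ([dpss_tapers()]); each window is demeaned before tapering. Power is in
#' units of signal^2 per Hz, one-sided.
#'
#' @param rec An [lfp_recording()].
#' @param window_len Window length, seconds.
#' @param step Window step, seconds.
#' @param time_bandwidth Time-bandwidth product NW.
#' @param n_tapers Number of tapers (at most `2 NW - 1`).
#' @return Object of class `spectrogram`: `power` (time x frequency),
#'   `times` (window centres, s), `freqs` (Hz),
#'   `normalization = "raw"`.
#' @export
multitaper_spectrogram <- function(rec, window_len = 10, step = 5,
                                   time_bandwidth = 3, n_tapers = 5) {
  stopifnot(inherits(rec, "lfp_recording"), window_len > 0, step > 0)
  if (n_tapers > 2 * time_bandwidth - 1)
    stop("n_tapers must be at most 2 * time_bandwidth - 1", call. = FALSE)
  L <- round(window_len * rec$fs)
  S <- max(1L, round(step * rec$fs))
  n <- length(rec$samples)
  if (L > n) stop("window longer than the recording", call. = FALSE)
  tapers <- dpss_tapers(L, time_bandwidth, n_tapers)
  starts <- seq(1L, n - L + 1L, by = S)
  nf <- L %/% 2 + 1
  scale <- rep(2, nf); scale[1] <- 1
  if (L %% 2 == 0) scale[nf] <- 1
  power <- matrix(0, length(starts), nf)
  for (w in seq_along(starts)) {
    xw <- rec$samples[starts[w]:(starts[w] + L - 1L)]
    xw <- xw - mean(xw)
    F <- stats::mvfft(tapers * xw)
    power[w, ] <- scale * rowMeans(Mod(F[seq_len(nf), , drop = FALSE])^2) /
      (rec$fs)
  }
  structure(list(power = power,
                 times = rec$t0 + (starts - 1 + (L - 1) / 2) / rec$fs,
                 freqs = (0:(nf - 1)) * rec$fs / L,
                 fs = rec$fs,
                 normalization = "raw",
                 invalid_freqs = logical(nf)),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d windows x %d freqs (0..%g Hz), %s\n",
              nrow(x$power), ncol(x$power), max(x$freqs), x$normalization))
  invisible(x)
}

#' Normalise a spectrogram by its baseline epoch
#'
#' Divides every time-frequency cell by that frequency's mean power over
#' the baseline window, yielding a dimensionless ratio spectrogram whose
#' baseline-epoch mean is 1 at every frequency. Frequencies with zero
#' baseline power are flagged invalid (`NA` column).
#'
#' @param spec A raw [multitaper_spectrogram()].
#' @param baseline `c(t_start, t_end)` in seconds (window centres).
#' @return The normalised `spectrogram` (`normalization = "baseline_ratio"`).
#' @export
normalize_baseline <- function(spec, baseline) {
  stopifnot(inherits(spec, "spectrogram"), length(baseline) == 2L)
  idx <- which(spec$times >= baseline[1] & spec$times <= baseline[2])
  if (!length(idx)) stop("baseline window contains no spectrogram windows",
                         call. = FALSE)
  base <- colMeans(spec$power[idx, , drop = FALSE])
  bad <- base <= 0
  out <- spec
  out$power <- sweep(spec$power, 2, ifelse(bad, NA_real_, base), `/`)
  out$invalid_freqs <- bad
  out$normalization <- "baseline_ratio"
  out
}

#' Band-power time series of a spectrogram
#'
#' Per-window mean over the frequency bins inside the band (inclusive).
#'
#' @param spec A `spectrogram`.
#' @param band `c(f_lo, f_hi)` in Hz.
#' @return Data frame with columns `time`, `power`.
#' @export
band_power <- function(spec, band) {
  stopifnot(inherits(spec, "spectrogram"), length(band) == 2L,
            band[2] >= band[1])
  cols <- which(spec$freqs >= band[1] & spec$freqs <= band[2])
  if (!length(cols)) stop("band contains no frequency bins", call. = FALSE)
  data.frame(time = spec$times,
             power = rowMeans(spec$power[, cols, drop = FALSE]))
}
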