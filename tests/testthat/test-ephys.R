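# LFP preprocessing, DPSS tapers, multitaper spectrograms, band power.

test_that("preprocessing decimates, passes the band, and notches line noise", {
  fs <- 20000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  mid <- seq(round(length(t) * 0.1), round(length(t) * 0.9)) / 10  # post-decim
  rms <- function(x) sqrt(mean(x^2))

  tone60 <- lfp_recording(sin(2 * pi * 60 * t), fs)
  out60 <- preprocess_lfp(tone60)
  expect_equal(out60$fs, 2000)
  expect_equal(length(out60$samples), length(t) / 10)   # L -> L/10
  expect_lt(rms(out60$samples[mid]) / rms(tone60$samples),
            10^(-30 / 20))                              # >= 30 dB notch

  tone5 <- lfp_recording(sin(2 * pi * 5 * t), fs)
  out5 <- preprocess_lfp(tone5)
  expect_lt(abs(rms(out5$samples[mid]) / (1 / sqrt(2)) - 1), 0.05)

  expect_error(preprocess_lfp(lfp_recording(rnorm(100), 1000)), "4 kHz")
  expect_warning(out <- preprocess_lfp(lfp_recording(rnorm(50000), 5000)),
                 "interpolation")
  expect_equal(out$fs, 2000)
})

test_that("DPSS tapers are orthonormal, concentration-ordered, and match a dense eigensolve", {
  n <- 64; nw <- 3; k <- 5
  V <- dpss_tapers(n, nw, k)
  expect_equal(crossprod(V), diag(k), tolerance = 1e-8)
  conc <- attr(V, "concentration")
  expect_true(all(diff(conc) < 1e-12))
  expect_gt(conc[1], 0.999)

  # independent route: dense eigendecomposition of the same tridiagonal
  t0 <- 0:(n - 1)
  Tm <- diag(((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * nw / n))
  off <- (t0[-1]) * (n - t0[-1]) / 2
  Tm[cbind(1:(n - 1), 2:n)] <- off
  Tm[cbind(2:n, 1:(n - 1))] <- off
  Ev <- eigen(Tm, symmetric = TRUE)$vectors[, 1:k]
  for (j in 1:k) expect_gt(abs(sum(V[, j] * Ev[, j])), 1 - 1e-8)
})

test_that("multitaper spectrogram localises tones and is flat for white noise", {
  fs <- 200
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  rec <- lfp_recording(sin(2 * pi * 5 * t), fs)
  sp <- multitaper_spectrogram(rec, window_len = 5, step = 2.5,
                               time_bandwidth = 3, n_tapers = 5)
  peak_f <- sp$freqs[apply(sp$power, 1, which.max)]
  expect_true(all(abs(peak_f - 5) <= 3 / 5 + 1e-9))   # within the NW band

  expect_true(all(multitaper_spectrogram(lfp_recording(numeric(2000), fs),
                                         window_len = 5, step = 5)$power == 0))

  set.seed(4)
  wn <- lfp_recording(rnorm(fs * 300), fs)
  spw <- multitaper_spectrogram(wn, window_len = 2.5, step = 2.5,
                                time_bandwidth = 3, n_tapers = 5)
  avg <- colMeans(spw$power)
  inner <- avg[spw$freqs > 2 & spw$freqs < 98]  # away from band edges
  expect_lt(max(inner) / min(inner), 2)

  # Parseval: integrated spectral power matches the signal variance
  tot <- mean(rowSums(spw$power) * (spw$freqs[2] - spw$freqs[1]))
  expect_lt(abs(tot / stats::var(wn$samples) - 1), 0.10)

  expect_error(multitaper_spectrogram(lfp_recording(rnorm(100), fs),
                                      window_len = 5), "longer")
  expect_error(multitaper_spectrogram(wn, window_len = 2, n_tapers = 9),
               "n_tapers")
})

test_that("baseline normalisation rescales each frequency to unit baseline mean", {
  fs <- 100
  set.seed(5)
  x <- rnorm(fs * 120)
  rec <- lfp_recording(x, fs)
  sp <- multitaper_spectrogram(rec, window_len = 4, step = 2)
  nb <- normalize_baseline(sp, c(0, 60))
  idx <- nb$times <= 60
  expect_equal(unname(colMeans(nb$power[idx, ])),
               rep(1, ncol(nb$power)), tolerance = 1e-9)
  # stationary signal stays near 1 outside the baseline too
  expect_lt(max(abs(colMeans(nb$power[!idx, ]) - 1)), 0.5)

  # doubled power at one frequency after the baseline -> ratio ~ 2
  y <- sin(2 * pi * 10 * seq_along(x) / fs)
  y[(60 * fs + 1):length(y)] <- sqrt(2) * y[(60 * fs + 1):length(y)]
  spy <- multitaper_spectrogram(lfp_recording(x / 4 + y, fs),
                                window_len = 4, step = 2)
  nby <- normalize_baseline(spy, c(0, 58))
  b10 <- band_power(nby, c(9, 11))
  expect_equal(stats::median(b10$power[b10$time > 64]), 2, tolerance = 0.25)

  expect_error(normalize_baseline(sp, c(500, 600)), "no spectrogram windows")
})

test_that("band power recovers the tremor time course", {
  pars <- ephys_scene_params(duration = 180, seed = 3)
  rec <- simulate_lfp(pars, timecourse_params())
  pre <- preprocess_lfp(rec)
  sp <- multitaper_spectrogram(pre, window_len = 10, step = 5)
  nb <- normalize_baseline(sp, c(0, 1800 / pars$time_compression))
  bp <- band_power(nb, c(4, 6))
  truth <- cbv_multiplier(bp$time * pars$time_compression,
                          timecourse_params())
  expect_gt(stats::cor(bp$power, truth), 0.8)
  # tremor band rises after the injection
  expect_gt(stats::median(bp$power[bp$time > 40 & bp$time < 90]), 2)
  expect_error(band_power(nb, c(1500, 1600)), "no frequency bins")
})

test_that("a step change lands in the correct spectrogram window", {
  fs <- 200
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 8 * t) * ifelse(t >= 60, 2, 1)
  sp <- multitaper_spectrogram(lfp_recording(x, fs), window_len = 4,
                               step = 2)
  bp <- band_power(sp, c(7, 9))
  mid <- (max(bp$power) + min(bp$power)) / 2
  t_cross <- bp$time[which(bp$power > mid)[1]]
  expect_lt(abs(t_cross - 60), 4 + 1e-9)   # within one window of the step
})
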