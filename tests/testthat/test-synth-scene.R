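# Synthetic scene generator: hemodynamic time course, IQ ensembles,
# sessions, LFP traces.

test_that("CBV multiplier is 1 through baseline, continuous, and peaks at the configured elevation", {
  p <- timecourse_params()
  t_base <- seq(0, p$t_baseline_end - 1e-6, length.out = 200)
  expect_identical(cbv_multiplier(t_base, p), rep(1, 200))
  expect_identical(cbv_multiplier(0, p), 1)

  # dense evaluation: maximum reaches 1 + A (to grid resolution) and the
  # curve is continuous across the injection boundary
  tg <- seq(0, 40000, by = 0.25)
  m <- cbv_multiplier(tg, p)
  expect_gte(max(m), 2.5)
  expect_lt(abs(max(m) - 2.6), 1e-4)
  expect_lt(max(abs(diff(m))), 0.01)
  expect_true(all(m >= 1 - 1e-12))
  # long-run return toward baseline
  expect_lt(cbv_multiplier(2e5, p), 1.001)
})

test_that("full suppression pulls the multiplier back to baseline and stays continuous", {
  p <- timecourse_params(suppression_enabled = TRUE, suppression_depth = 1)
  tg <- seq(p$t_suppressor - 200, p$t_suppressor + 2000, by = 0.05)
  m <- cbv_multiplier(tg, p)
  expect_lt(abs(min(m) - 1), 1e-6)    # elevation fully suppressed at the dip
  expect_lt(max(abs(diff(m))), 0.005) # no jump at suppressor onset
  expect_true(all(m >= 1 - 1e-12))
  # partial suppression: local dip then rebound around the suppressor epoch
  p2 <- timecourse_params(suppression_enabled = TRUE, suppression_depth = 0.8)
  tg2 <- seq(p2$t_suppressor, p2$t_suppressor + 3000, by = 1)
  m2 <- cbv_multiplier(tg2, p2)
  trough <- which.min(m2)
  expect_gt(trough, 1)
  expect_lt(trough, length(m2))
  expect_gt(max(m2[seq(trough, length(m2))]) - m2[trough], 0.2)
})

test_that("invalid time-course parameters are rejected", {
  expect_error(timecourse_params(rise_tau = -1), "positive")
  expect_error(timecourse_params(decay_tau = 0), "positive")
  expect_error(timecourse_params(suppression_enabled = TRUE,
                                 suppression_depth = 1.5), "\\[0, 1\\]")
  expect_error(cbv_multiplier(-1, timecourse_params()), "nonnegative")
})

test_that("blood Doppler shift follows f_d = 2 v f_c / c", {
  # v = 1 mm/s, f_c = 16 MHz, c = 1540 m/s -> f_d = 2*0.001*16e6/1540
  f_expected <- 2 * 1e-3 * 16e6 / 1540          # 20.779 Hz, by hand
  sc <- tiny_scene(blood_velocity_range = c(1e-3, 1e-3),
                   clutter_to_blood_db = -Inf, noise_to_blood_db = -Inf,
                   phase_jitter_sd = 0, amplitude_jitter = 0)
  acq <- tiny_acq()
  ens <- simulate_iq_ensemble(sc, acq, 0)
  px <- which(sc$vessel_mask, arr.ind = TRUE)[1, ]
  s <- ens[px[1], px[2], ]
  dphi <- Arg(s[-1] / s[-length(s)])
  f_measured <- mean(dphi) * acq$frame_rate_in_ensemble / (2 * pi)
  expect_equal(f_measured, f_expected, tolerance = 1e-6)
})

test_that("component switches produce exact zeros and deterministic output", {
  sc <- tiny_scene(blood_amplitude = 0, clutter_to_blood_db = -Inf,
                   noise_to_blood_db = -Inf)
  acq <- tiny_acq()
  expect_true(all(simulate_iq_ensemble(sc, acq, 0) == 0))

  sc2 <- tiny_scene(seed = 42)
  a <- simulate_iq_ensemble(sc2, acq, 300)
  b <- simulate_iq_ensemble(sc2, acq, 300)
  expect_identical(unclass(a), unclass(b))   # bit-identical repeat call
  c2 <- simulate_iq_ensemble(sc2, acq, 600)
  expect_false(identical(unclass(a), unclass(c2)))
})

test_that("blood-pixel power scales exactly with the CBV multiplier", {
  sc <- tiny_scene(clutter_to_blood_db = -Inf, noise_to_blood_db = -Inf)
  acq <- tiny_acq(ensemble_len = 400)
  t_peak <- 2468
  m <- cbv_multiplier(t_peak, sc$timecourse)
  ens <- simulate_iq_ensemble(sc, acq, t_peak)
  p <- power_doppler(ens)$power
  act <- sc$roi_active & sc$vessel_mask
  expect_lt(max(abs(p[act] / (sc$blood_amplitude_map[act]^2 * m) - 1)), 0.02)
  other <- sc$vessel_mask & !sc$roi_active
  expect_lt(max(abs(p[other] / sc$blood_amplitude_map[other]^2 - 1)), 0.02)
})

test_that("blood-free, noise-free ensembles have Casorati rank at most clutter_rank", {
  sc <- tiny_scene(blood_amplitude = 0, noise_to_blood_db = -Inf,
                   clutter_rank = 3)
  ens <- simulate_iq_ensemble(sc, tiny_acq(), 0)
  sv <- svd(unclass(to_casorati(ens)), nu = 0, nv = 0)$d
  expect_lt(sv[4] / sv[1], 1e-8)
})

test_that("aliased velocities are flagged, not clipped", {
  sc <- tiny_scene(blood_velocity_range = c(25e-3, 30e-3))  # f_d > 500 Hz
  expect_warning(ens <- simulate_iq_ensemble(sc, tiny_acq(), 0), "aliased")
  expect_true(attr(ens, "aliased"))
})

test_that("sessions carry compressed timestamps and ground-truth multipliers", {
  sc <- tiny_scene()
  acq <- tiny_acq()
  ses <- simulate_session(sc, acq, 3, time_compression = 1)
  expect_equal(ses$timestamps, c(0, 2.5, 5))

  base_tc <- timecourse_params(t_baseline_end = 1e9)
  ses0 <- simulate_session(tiny_scene(timecourse = base_tc), acq, 10,
                           time_compression = 60)
  expect_identical(ses0$truth_multiplier, rep(1, 10))

  # default harmaline cadence samples the peak to within the spec band
  ses1 <- simulate_session(sc, acq, 70, time_compression = 60)
  expect_gte(max(ses1$truth_multiplier), 2.5)
  expect_lte(max(ses1$truth_multiplier), 2.6)
  # lazy and materialised access agree
  expect_identical(unclass(session_ensemble(ses1, 3)),
                   unclass(simulate_iq_ensemble(sc, acq, ses1$timestamps[3])))
})

test_that("simulated LFP carries tremor tones modulated by the time course", {
  # single tone, no noise: dominant DFT bin at 5 Hz
  pars <- ephys_scene_params(fs_raw = 4000, tremor_freqs = 5,
                             tremor_amps = 1, pink_noise_level = 0,
                             line_amp = 0, duration = 20, seed = 2)
  base_tc <- timecourse_params(t_baseline_end = 1e9)
  rec <- simulate_lfp(pars, base_tc)
  sp <- Mod(stats::fft(rec$samples))^2
  freqs <- (seq_along(sp) - 1) * rec$fs / length(sp)
  expect_equal(freqs[which.max(sp[1:2000])], 5, tolerance = 0.11)

  # zero modulation gain -> stationary amplitude despite the drug response
  pars0 <- ephys_scene_params(fs_raw = 4000, tremor_freqs = 5,
                              tremor_mod_gain = 0, pink_noise_level = 0,
                              line_amp = 0, duration = 120, seed = 2)
  rec0 <- simulate_lfp(pars0, timecourse_params())
  early <- sqrt(mean(rec0$samples[1:80000]^2))
  late <- sqrt(mean(rec0$samples[280001:360000]^2))
  expect_equal(late / early, 1, tolerance = 0.02)

  # default modulation: post-injection 5 Hz band power exceeds baseline
  pars1 <- ephys_scene_params(fs_raw = 4000, tremor_freqs = 5,
                              pink_noise_level = 0, line_amp = 0,
                              duration = 120, seed = 2)
  rec1 <- simulate_lfp(pars1, timecourse_params())
  # baseline ends at 1800/60 = 30 s of trace time
  bandpow <- function(x) mean(x^2)
  expect_gt(bandpow(rec1$samples[rec1$fs * 45 + 1:(rec1$fs * 30)]),
            2 * bandpow(rec1$samples[1:(rec1$fs * 25)]))
  # determinism
  expect_identical(simulate_lfp(pars1, timecourse_params())$samples,
                   rec1$samples)
})
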