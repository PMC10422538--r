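# Baseline imaging, activation maps, ROI traces, smoothing, recovery.

mk_series <- function(mats, dt = 2.5) {
  md_series(lapply(seq_along(mats), function(k)
    md_image(mats[[k]], timestamp = (k - 1) * dt, ensemble_index = k)))
}

test_that("baseline image is the pixel-wise mean over the window", {
  ser <- mk_series(list(matrix(2, 2, 2), matrix(4, 2, 2), matrix(6, 2, 2)))
  expect_true(all(baseline_image(ser, baseline_spec(0, 10)) == 4))
  cser <- mk_series(rep(list(matrix(3, 2, 2)), 5))
  expect_true(all(baseline_image(cser, baseline_spec(0, 100)) == 3))
  expect_error(baseline_image(ser, baseline_spec(100, 200)), "no images")
  expect_error(baseline_image(ser, baseline_spec(0, 3)), "at least 3")
})

test_that("activation maps are percent change with a validity floor", {
  base <- matrix(c(1, 2, 4, 1e-9), 2, 2)
  ser <- mk_series(list(base, base, base, 2.6 * base, 0.5 * base))
  bl <- baseline_image(ser, baseline_spec(0, 5))
  act <- activation_map(ser, bl, floor = 0.5)
  expect_false(act$valid[2, 2])                  # below floor -> invalid
  expect_true(all(is.na(act$percent[2, 2, ])))
  expect_true(all(abs(act$percent[, , 1][act$valid]) < 1e-9))   # P = B -> 0%
  expect_equal(act$percent[, , 4][act$valid], rep(160, 3),
               tolerance = 1e-9)                 # P = 2.6 B -> +160%
  expect_equal(act$percent[, , 5][act$valid], rep(-50, 3),
               tolerance = 1e-9)                 # P = B/2 -> -50%
  expect_error(activation_map(ser, bl, floor = 0), "positive")
})

test_that("ROI traces average valid pixels only and ignore invalid values", {
  base <- matrix(1, 4, 4); base[1, 1] <- 1e-12
  mats <- list(base, base, base, 1.1 * base)
  ser <- mk_series(mats)
  act <- activation_map(ser, baseline_image(ser, baseline_spec(0, 6)),
                        floor = 0.5)
  mask <- matrix(TRUE, 4, 4)
  tr <- roi_trace(act, mask)
  expect_equal(tr$percent[4], 10, tolerance = 1e-9)
  expect_equal(tr$n_valid, rep(15L, 4))

  one <- matrix(FALSE, 4, 4); one[2, 3] <- TRUE
  tr1 <- roi_trace(act, one)
  expect_equal(tr1$percent, act$percent[2, 3, ])

  # relabeling invalid pixels leaves the trace unchanged
  ser2 <- ser; ser2$power[1, 1, ] <- 1e6
  act2 <- activation_map(ser2, act$baseline_image, floor = 0.5)
  expect_equal(roi_trace(act2, mask)$percent, tr$percent)

  none <- matrix(FALSE, 4, 4); none[1, 1] <- TRUE
  expect_error(roi_trace(act, none), "no valid")
})

test_that("moving-average smoothing uses shrinking edge windows", {
  x <- c(5, 1, 4, 1, 5)
  expect_identical(smooth_trace(x, 1), x)
  expect_identical(smooth_trace(rep(2, 8), 5), rep(2, 8))
  expect_error(smooth_trace(x, 6), "exceeds")

  # unit impulse spreads to a 1/k plateau over the kernel support
  imp <- rep(0, 40); imp[20] <- 1
  sm <- smooth_trace(imp, 10)
  expect_equal(sum(sm > 0), 10)
  expect_equal(max(sm), 0.1, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)   # interior mass preserved

  # shrinking edges: first value averages the first ceil(k/2) samples
  y <- 1:10
  expect_equal(smooth_trace(y, 4)[1], mean(1:3))
  expect_equal(smooth_trace(y, 4)[10], mean(9:10))
})

test_that("the harmaline scenario recovers its evoked peak across seeds", {
  # reduced-scale replicas of the default scenario; the spec of the
  # smoothing kernel and cadence is identical, so the smoothed-peak
  # attenuation matches the full-scale behaviour
  peaks <- vapply(11:20, function(sd) {
    run <- if (sd == 11) shared_reduced_run() else
      run_pipeline(reduced_cfg(seed = sd), file.path(tempdir(), paste0("rec", sd)))
    max(run$traces$active$smoothed)
  }, numeric(1))
  med <- stats::median(peaks)
  expect_gte(med, 145)
  expect_lte(med, 175)
})

test_that("the propranolol arm dips after the suppressor and rebounds", {
  cfg <- reduced_cfg(seed = 21)
  cfg$timecourse <- list(suppression_enabled = TRUE, t_suppressor = 3000,
                         suppression_depth = 0.9, rebound_tau = 1200)
  run <- run_pipeline(cfg, file.path(tempdir(), "md-suppress"))
  tr <- run$traces$active
  sup <- tr$time >= 3000
  i_min <- which(sup)[which.min(tr$smoothed[sup])]
  expect_gt(i_min, which(sup)[1])               # dip after suppressor onset
  after <- tr$smoothed[tr$time > tr$time[i_min]]
  expect_gt(length(after), 3)
  # rebound clears the trough by at least twice the trace noise scale
  resid_sd <- stats::sd(tr$percent[tr$time <= 1800])
  expect_gt(max(after) - tr$smoothed[i_min], 2 * resid_sd)
})
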