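# MicroDoppler image formation, noise profiles, bias removal.

test_that("power Doppler is the per-pixel mean squared magnitude", {
  ens <- iq_ensemble(array(2i, c(3, 4, 5)), 1000)
  expect_true(all(power_doppler(ens)$power == 4))
  expect_true(all(power_doppler(iq_ensemble(array(0i, c(3, 4, 5)),
                                            1000))$power == 0))

  # constant-amplitude rotating phasor: power = a^2 exactly
  a <- 1.7
  ph <- array(runif(2 * 2 * 50, 0, 2 * pi), c(2, 2, 50))
  ens2 <- iq_ensemble(array(a * exp(1i * ph), c(2, 2, 50)), 1000)
  expect_equal(max(abs(power_doppler(ens2)$power - a^2)), 0,
               tolerance = 1e-12)

  bad <- array(0i, c(2, 2, 3)); bad[1, 1, 1] <- NA
  expect_error(power_doppler(iq_ensemble(bad, 1000), ensemble_index = 7),
               "ensemble 7")
})

test_that("power images scale with |c|^2 when the ensemble is scaled by c", {
  set.seed(8)
  ens <- iq_ensemble(array(complex(real = rnorm(60), imaginary = rnorm(60)),
                           c(3, 4, 5)), 1000)
  cc <- 2 - 1i
  ens2 <- iq_ensemble(unclass(ens) * cc, 1000)
  expect_equal(power_doppler(ens2)$power,
               Mod(cc)^2 * power_doppler(ens)$power, tolerance = 1e-12)
})

test_that("noise profiles are unbiased and linear in the true noise power", {
  acq <- acquisition_config()   # 400 frames
  mk_noise <- function(db, seed) {
    sc <- hemodynamic_scene(grid_shape = c(32, 32), blood_amplitude = 0,
                            clutter_to_blood_db = -Inf,
                            noise_to_blood_db = db, seed = seed)
    simulate_iq_ensemble(sc, acq, 0)
  }
  ens <- mk_noise(-10, 2)       # sigma^2 = 0.1
  img <- power_doppler(ens)

  # vessel-free depth profile on a homogeneous noise field: flat at sigma^2
  prof <- estimate_noise_profile(img, "vessel_free_region",
                                 mask = matrix(TRUE, 32, 32))
  expect_lt(max(abs(prof / 0.1 - 1)), 0.10)

  # high-order residual estimator, Marchenko-Pastur rescaled
  res <- svd_filter(ens, low_cut = 0, high_cut = 300)
  prof2 <- estimate_noise_profile(res, "high_order_residual",
                                  target_dim = 400)
  expect_lt(abs(mean(prof2) / 0.1 - 1), 0.10)

  # doubling the noise power doubles both estimates
  ens2 <- mk_noise(-7, 3)       # sigma^2 ~ 0.1995
  img2 <- power_doppler(ens2)
  prof_b <- estimate_noise_profile(img2, "vessel_free_region",
                                   mask = matrix(TRUE, 32, 32))
  expect_lt(abs(mean(prof_b) / mean(prof) - 10^0.3), 0.10 * 10^0.3)
  res2 <- svd_filter(ens2, low_cut = 0, high_cut = 300)
  prof2b <- estimate_noise_profile(res2, "high_order_residual",
                                   target_dim = 400)
  expect_lt(abs(mean(prof2b) / mean(prof2) - 10^0.3), 0.10 * 10^0.3)

  # zero input -> zero profile
  sc0 <- hemodynamic_scene(grid_shape = c(16, 16), blood_amplitude = 0,
                           clutter_to_blood_db = -Inf,
                           noise_to_blood_db = -Inf, seed = 1)
  img0 <- power_doppler(simulate_iq_ensemble(sc0, tiny_acq(), 0))
  expect_true(all(estimate_noise_profile(img0, "vessel_free_region",
                                         mask = matrix(TRUE, 16, 16)) == 0))
  expect_error(estimate_noise_profile(img, "vessel_free_region",
                                      mask = matrix(FALSE, 32, 32)), "mask")
})

test_that("bias removal subtracts, clamps at zero, and keeps diagnostics", {
  img <- md_image(matrix(c(1, 2, 0.5, 3), 2, 2), timestamp = 1)
  same <- remove_noise_bias(img, matrix(0, 2, 2))
  expect_equal(same$power, img$power)

  clamped <- remove_noise_bias(img, matrix(10, 2, 2))
  expect_true(all(clamped$power == 0))
  expect_equal(attr(clamped, "clamp_frac"), 1)

  part <- remove_noise_bias(img, c(0.75, 1.5))  # per-depth broadcast
  expect_equal(part$power, matrix(c(0.25, 0.5, 0, 1.5), 2, 2))
  expect_equal(attr(part, "subtracted"), matrix(c(0.75, 1.5), 2, 2))
  expect_error(remove_noise_bias(img, matrix(-1, 2, 2)), "nonnegative")
})

test_that("noise-only images are flattened to near zero by bias removal", {
  sc <- hemodynamic_scene(grid_shape = c(32, 32), blood_amplitude = 0,
                          clutter_to_blood_db = -Inf,
                          noise_to_blood_db = -10, seed = 9)
  img <- power_doppler(simulate_iq_ensemble(sc, acquisition_config(), 0))
  prof <- estimate_noise_profile(img, "vessel_free_region",
                                 mask = matrix(TRUE, 32, 32))
  corrected <- remove_noise_bias(img, prof)
  expect_lt(mean(corrected$power), 0.05 * mean(img$power))
})

test_that("series assembly preserves order, cadence and image count", {
  imgs <- lapply(1:4, function(k)
    md_image(matrix(k, 2, 2), timestamp = (k - 1) * 2.5,
             ensemble_index = k))
  ser <- md_series(imgs)
  expect_equal(dim(ser$power), c(2, 2, 4))
  expect_equal(ser$timestamps, c(0, 2.5, 5, 7.5))
  expect_error(md_series(imgs[c(2, 1)]), "increasing")
})

test_that("vessel-pixel power after bias removal is proportional to the multiplier", {
  # default scene, ensembles sampled across the whole drug response
  sc <- hemodynamic_scene(seed = 14)
  acq <- acquisition_config()
  cfg <- validate_config(NULL)
  times <- seq(0, 9000, by = 1500)
  act <- sc$roi_active & sc$vessel_mask
  pow <- vapply(times, function(t) {
    res <- svd_filter(simulate_iq_ensemble(sc, acq, t), low_cut = NULL,
                      high_cut = 300,
                      low_cut_margin = cfg$filter$low_cut_margin)
    full <- iq_ensemble(unclass(res$filtered) + unclass(res$residual), 1000, t)
    img <- remove_noise_bias(
      power_doppler(full),
      estimate_noise_profile(res, "high_order_residual",
                             target_dim = 400 - res$low_cut))
    mean(img$power[act])
  }, numeric(1))
  m <- cbv_multiplier(times, sc$timecourse)
  fit <- stats::lm(pow ~ m)
  a_true <- mean(sc$blood_amplitude_map[act]^2)
  expect_lt(abs(stats::coef(fit)[["m"]] / a_true - 1), 0.10)
  expect_gt(summary(fit)$r.squared, 0.95)
})
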