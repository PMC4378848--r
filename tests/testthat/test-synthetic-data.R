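test_that("all generators are bit-identical under the same seed", {
  expect_identical(sim_turbidity_trace(seed = 3)$absorbance,
                   sim_turbidity_trace(seed = 3)$absorbance)
  expect_false(identical(sim_turbidity_trace(seed = 3)$absorbance,
                         sim_turbidity_trace(seed = 4)$absorbance))
  expect_identical(sim_compression_trace(seed = 3)$force_N,
                   sim_compression_trace(seed = 3)$force_N)
  a <- sim_fiber_image(image_px = 64, n_fibers = 3, seed = 3)
  b <- sim_fiber_image(image_px = 64, n_fibers = 3, seed = 3)
  expect_identical(unclass(a), unclass(b))
  s1 <- sim_frap_sequence(image_px = 32, stripe_width_px = 48, seed = 3)
  s2 <- sim_frap_sequence(image_px = 32, stripe_width_px = 48, seed = 3)
  expect_identical(s1$frames, s2$frames)
  expect_identical(sim_property_table(reps = 2, seed = 3),
                   sim_property_table(reps = 2, seed = 3))
})

test_that("noiseless turbidity trace matches the logistic closed form", {
  ht <- 333 * 3.6  # half-time on the 3.6 s sampling grid
  tr <- sim_turbidity_trace(plateau_abs = 1, half_time_s = ht,
                            steepness = 0.01, initial_abs = 0.1,
                            noise_sd = 0, duration_s = 3600)
  i <- which.min(abs(tr$time_s - ht))
  expect_lt(abs(tr$time_s[i] - ht), 1e-9)
  expect_equal(tr$absorbance[i], 0.1 + 0.5, tolerance = 1e-9)    # midpoint
  expect_equal(tail(tr$absorbance, 1), 0.1 + 1, tolerance = 1e-8) # asymptote
})

test_that("invalid turbidity specs are rejected naming the field", {
  expect_error(sim_turbidity_trace(plateau_abs = -1), "plateau_abs")
  expect_error(sim_turbidity_trace(half_time_s = 0), "half_time_s")
  expect_error(sim_turbidity_trace(noise_sd = -0.1), "noise_sd")
  expect_error(sim_turbidity_trace(dt_s = 0), "dt_s")
})

test_that("noiseless compression trace yields the exact generating modulus", {
  tr <- sim_compression_trace(true_modulus_Pa = 3000, noise_rms_N = 0)
  res <- analyze_compression(tr)
  expect_true(res$valid)
  expect_equal(res$modulus_Pa, 3000, tolerance = 1e-3)  # within 0.1%
  expect_equal(res$contact_position_mm,
               attr(tr, "truth")$contact_position_mm,
               tolerance = attr(tr, "meta")$speed_mm_s)  # one sample spacing
})

test_that("compression artifacts and geometry are parameterized", {
  tr <- sim_compression_trace(artifacts = list(list(type = "drift", magnitude = 0.01)),
                              noise_rms_N = 0)
  base <- sim_compression_trace(noise_rms_N = 0)
  expect_gt(max(tr$force_N - base$force_N), 0.009)
  expect_error(sim_compression_trace(artifacts = list(list(type = "nope", magnitude = 1))),
               "unknown artifact")
  thin <- sim_compression_trace(thickness_mm = 8.5 - 0.585, noise_rms_N = 0)
  expect_equal(attr(thin, "truth")$contact_position_mm, 0.3 + 0.585)
})

test_that("fiber image generator validates its spec", {
  expect_error(sim_fiber_image(fiber_diameter_um = 0.05), "fiber_diameter_um")
  expect_error(sim_fiber_image(occlusion_fraction = 1), "occlusion_fraction")
  img <- sim_fiber_image(image_px = 64, n_fibers = 0, background_noise_sd = 0)
  expect_true(all(unclass(img) == 0))
})

test_that("frozen FRAP field (D = 0) repeats the bleach profile", {
  sq <- sim_frap_sequence(true_D_um2_s = 0, image_px = 64,
                          stripe_width_px = 96, noise_sd = 0,
                          background_heterogeneity_sd = 0)
  post <- sq$frames[, , (sq$n_pre + 1):dim(sq$frames)[3]]
  for (i in 2:dim(post)[3])
    expect_equal(post[, , i], post[, , 1], tolerance = 1e-12)
})

test_that("bleached amount is conserved under zero-boundary-flux diffusion", {
  # D small enough that no bleached material reaches the frame edge
  sq <- sim_frap_sequence(true_D_um2_s = 2, image_px = 128,
                          stripe_width_px = 192, noise_sd = 0,
                          background_heterogeneity_sd = 0)
  post <- sq$frames[, , (sq$n_pre + 1):dim(sq$frames)[3]]
  deficit <- vapply(seq_len(dim(post)[3]),
                    function(i) sum(sq$truth$baseline - post[, , i]),
                    numeric(1))
  expect_equal(deficit, rep(deficit[1], length(deficit)),
               tolerance = 1e-6)
})

test_that("analytic FRAP forward model agrees with a finite-difference oracle", {
  # full 512 px field so the analytic (infinite-domain) solution has
  # negligible boundary flux over the comparison horizon
  D <- 49.02; px <- 0.439; n <- 512
  sq <- sim_frap_sequence(true_D_um2_s = D, image_px = n, pixel_size_um = px,
                          noise_sd = 0,
                          background_heterogeneity_sd = 0, t_first_s = 0)
  post <- sq$frames[, , (sq$n_pre + 1):dim(sq$frames)[3]]
  profile0 <- sq$truth$baseline - rowMeans(post[, , 1])  # rect at t = 0
  t_last <- (dim(post)[3] - 1) * sq$frame_dt_s
  oracle <- fd_diffuse_1d(profile0, D, px, t_last)
  actual <- sq$truth$baseline - rowMeans(post[, , dim(post)[3]])
  expect_equal(actual, oracle, tolerance = 0.01)
})

test_that("frap spec invariants are enforced", {
  expect_error(sim_frap_sequence(true_D_um2_s = -1), "true_D_um2_s")
  expect_error(sim_frap_sequence(image_px = 512, stripe_width_px = 256),
               "stripe_width_px")
})

test_that("noiseless property tables refit to the generating coefficients", {
  mods <- published_models()
  tab <- sim_property_table(
    noise_sd = c(t_half_min = 0, modulus_Pa = 0, pore_diameter_um = 0,
                 diffusivity_um2_s = 0), reps = 1)
  for (prop in names(mods)) {
    f <- fit_property_model(tab, prop)
    truth <- mods[[prop]]$coefficients
    expect_equal(f$coefficients[names(truth)], truth, tolerance = 1e-9)
  }
})

test_that("property table generation validates design and reps", {
  expect_error(sim_property_table(reps = 0), "reps")
  bad_design <- fabrication_design()
  bad_design$concentration_mg_ml <- c(4, 12)  # 12 mg/ml is out of range
  expect_error(sim_property_table(design = bad_design), "concentration_mg_ml")
})
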