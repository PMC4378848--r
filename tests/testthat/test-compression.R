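test_that("contact is found at the exact onset of a noiseless ramp", {
  tr <- sim_compression_trace(start_gap_mm = 0.4, noise_rms_N = 0)
  ct <- detect_contact(tr)
  dpos <- diff(tr$position_mm[1:2])
  expect_lte(abs(ct$contact_position_mm - 0.4), dpos + 1e-12)
})

test_that("pure noise yields no contact", {
  pos <- seq(0, 2, by = 0.001)
  set.seed(1)
  tr <- tibble::tibble(position_mm = pos, force_N = rnorm(length(pos), 0, 1e-4))
  expect_error(detect_contact(tr), "no contact detected")
})

test_that("contact detection is sample-accurate when the rise resolves the threshold", {
  # a stiff sample at coarse sampling crosses 5 x RMS within a sample or two
  # of true contact, so the detector should land within 3 samples of truth
  hits <- vapply(1:100, function(s) {
    tr <- sim_compression_trace(true_modulus_Pa = 11000, sample_rate_hz = 1,
                                noise_rms_N = 1e-4, start_gap_mm = 0.3, seed = s)
    ct <- detect_contact(tr)
    dpos <- diff(tr$position_mm[1:2])
    abs(ct$contact_position_mm - 0.3) / dpos
  }, numeric(1))
  expect_gte(mean(hits <= 3), 0.95)
})

test_that("detection delay for soft gels stays well inside the thickness rule", {
  # for compliant samples the force rises slowly, so the threshold crossing
  # trails true contact; the resulting thickness bias must be small relative
  # to the 5% (425 um) validity tolerance
  errs <- vapply(1:20, function(s) {
    tr <- sim_compression_trace(true_modulus_Pa = 3000, seed = s)
    abs(detect_contact(tr)$contact_position_mm - 0.3)
  }, numeric(1))
  expect_lt(max(errs), 0.425 / 4)
})

test_that("thickness rule is two-sided with a strict 5% boundary", {
  # 585 um (6.9%) short of nominal: fail
  r <- validate_thickness(0.3 + 0.585, platen_start_height_mm = 8.8)
  expect_false(r$pass)
  # exact nominal: pass
  expect_true(validate_thickness(0.3, platen_start_height_mm = 8.8)$pass)
  # deviation exactly 425 um = 5%: rule is "greater than", so pass
  expect_true(validate_thickness(0.3 + 0.425, platen_start_height_mm = 8.8)$pass)
  expect_true(validate_thickness(0.3 - 0.425, platen_start_height_mm = 8.8)$pass)
  expect_false(validate_thickness(0.3 + 0.426, platen_start_height_mm = 8.8)$pass)
})

test_that("stress-strain conversion does the unit arithmetic", {
  tr <- tibble::tibble(position_mm = seq(0, 2, by = 0.01),
                       force_N = seq(0, 2, by = 0.01) / 2)
  cv <- to_stress_strain(tr, contact_position_mm = 0,
                         measured_thickness_mm = 8.5, plug_area_mm2 = 50.3)
  # 1.0 N over 50.3 mm^2 -> 19881 Pa
  i <- which(abs(tr$force_N - 1.0) < 1e-9)
  expect_equal(cv$stress_Pa[i], 1 / 50.3e-6, tolerance = 1e-9)
  expect_equal(cv$stress_Pa[i], 19881, tolerance = 1e-4)
  # 1.7 mm over 8.5 mm -> 20% strain
  j <- which(abs(tr$position_mm - 1.7) < 1e-9)
  expect_equal(cv$strain[j], 0.20, tolerance = 1e-12)
  # origin at contact
  expect_equal(cv$strain[1], 0)
  expect_equal(cv$stress_Pa[1], 0)
})

test_that("robust loess reproduces polynomials and rejects outliers", {
  x <- seq(0, 0.2, length.out = 200)
  lin <- tibble::tibble(strain = x, stress_Pa = 500 + 3000 * x)
  sm <- robust_smooth(lin)
  expect_equal(sm$stress_Pa, lin$stress_Pa, tolerance = 1e-7)

  const <- tibble::tibble(strain = x, stress_Pa = rep(42, 200))
  expect_equal(robust_smooth(const)$stress_Pa, const$stress_Pa, tolerance = 1e-9)

  out <- lin
  out$stress_Pa[100] <- out$stress_Pa[100] + 5000  # single large outlier
  smo <- robust_smooth(out)
  near <- 90:110
  expect_lt(max(abs(smo$stress_Pa[near] - lin$stress_Pa[near]) /
                  lin$stress_Pa[near]), 0.01)

  expect_error(robust_smooth(lin[1:10, ]), ">= 20 samples")
})

test_that("modulus regression is exact on linear data and propagates sign", {
  x <- seq(0, 0.2, length.out = 500)
  cv <- tibble::tibble(strain = x, stress_Pa = 3320 * x)
  f <- fit_modulus(cv)
  expect_equal(f$modulus_Pa, 3320, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  neg <- tibble::tibble(strain = x, stress_Pa = -8617 * x)
  expect_equal(fit_modulus(neg)$modulus_Pa, -8617, tolerance = 1e-9)

  expect_error(fit_modulus(cv, strain_lo = 0.5, strain_hi = 0.6), "strain window")
})

test_that("validation applies the three rules in order", {
  row <- function(th, E, r2) tibble::tibble(measured_thickness_mm = th,
                                            modulus_Pa = E, r_squared = r2)
  expect_equal(validate_result(row(7.9, 3320, 0.99))$rejection_reason, "thickness")
  expect_equal(validate_result(row(8.5, -8617, 0.99))$rejection_reason, "negative_modulus")
  expect_equal(validate_result(row(8.5, 3320, 0.065))$rejection_reason, "low_r2")
  v <- validate_result(row(8.5, 3320, 0.99))
  expect_true(v$valid)
  expect_equal(v$rejection_reason, "none")
  # thickness failure outranks the later rules
  expect_equal(validate_result(row(7.9, -10, 0.1))$rejection_reason, "thickness")
})

test_that("batch aggregation averages valid samples only", {
  rows <- dplyr::bind_rows(
    tibble::tibble(modulus_Pa = 3320, valid = TRUE),
    tibble::tibble(modulus_Pa = -8617, valid = FALSE),
    tibble::tibble(modulus_Pa = 150, valid = FALSE),
    tibble::tibble(modulus_Pa = 9000, valid = FALSE)
  )
  s <- summarize_moduli(rows)
  expect_equal(s$n_valid, 1)
  expect_equal(s$n_total, 4)
  expect_equal(s$mean_modulus_Pa, 3320)
  expect_equal(s$se_modulus_Pa, 0)

  none <- summarize_moduli(dplyr::mutate(rows, valid = FALSE))
  expect_true(is.na(none$mean_modulus_Pa))
  expect_false(none$any_valid)

  dup <- summarize_moduli(dplyr::bind_rows(rows[1, ], rows[1, ]))
  expect_equal(dup$se_modulus_Pa, 0)
})

test_that("pipeline recovers generator moduli within 5% under noise", {
  for (E in c(500, 3000, 11000)) {
    res <- analyze_compression(sim_compression_trace(true_modulus_Pa = E, seed = 42))
    expect_true(res$valid)
    expect_equal(res$modulus_Pa, E, tolerance = 0.05)
  }
})

test_that("adding artifacts never converts an invalid decision to valid", {
  arts <- list(
    list(list(type = "bubble_spike", magnitude = 0.05, location = 0.5)),
    list(list(type = "drift", magnitude = 0.01)),
    list(list(type = "nonlinearity", magnitude = 0.05))
  )
  # invalid by negative modulus
  for (a in arts) {
    tr <- sim_compression_trace(true_modulus_Pa = -2000, artifacts = a, seed = 1)
    expect_false(analyze_compression(tr)$valid)
  }
  # invalid by thickness
  for (a in arts) {
    tr <- sim_compression_trace(thickness_mm = 7.9, artifacts = a, seed = 1)
    expect_false(analyze_compression(tr)$valid)
  }
})
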