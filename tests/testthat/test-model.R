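test_that("coded units map the experimental corners to 0 and 1", {
  upper <- nondimensionalize(tibble::tibble(
    concentration_mg_ml = 10, temperature_C = 37, pH = 8.4,
    hydrodynamic_radius_nm = 1.4))
  expect_equal(unlist(upper[c("c_prime", "t_prime", "ph_prime", "inv_rh_prime")]),
               c(c_prime = 1, t_prime = 1, ph_prime = 1, inv_rh_prime = 1),
               tolerance = 1e-12)
  lower <- nondimensionalize(tibble::tibble(
    concentration_mg_ml = 4, temperature_C = 23, pH = 7.4,
    hydrodynamic_radius_nm = 8.5))
  expect_equal(unlist(lower[c("c_prime", "t_prime", "ph_prime", "inv_rh_prime")]),
               c(c_prime = 0, t_prime = 0, ph_prime = 0, inv_rh_prime = 0),
               tolerance = 1e-12)
  expect_equal(nondimensionalize(tibble::tibble(concentration_mg_ml = 6))$c_prime,
               1 / 3, tolerance = 1e-12)
})

test_that("out-of-domain conditions error naming the parameter", {
  expect_error(nondimensionalize(tibble::tibble(concentration_mg_ml = 12)),
               "concentration_mg_ml")
  expect_error(nondimensionalize(tibble::tibble(pH = 9)), "pH")
  ok <- nondimensionalize(tibble::tibble(pH = 9), override = TRUE)
  expect_gt(ok$ph_prime, 1)
})

test_that("decode inverts the coded transform including inverse radius", {
  cond <- tibble::tibble(concentration_mg_ml = c(4, 7, 10),
                         temperature_C = c(23, 30, 37),
                         pH = c(7.4, 7.9, 8.4),
                         hydrodynamic_radius_nm = c(8.5, 4.5, 1.4))
  codes <- nondimensionalize(cond)
  back <- decode_condition(codes[c("c_prime", "t_prime", "ph_prime", "inv_rh_prime")])
  expect_equal(back$concentration_mg_ml, cond$concentration_mg_ml, tolerance = 1e-9)
  expect_equal(back$hydrodynamic_radius_nm, cond$hydrodynamic_radius_nm,
               tolerance = 1e-9)
})

test_that("two-pass fit recovers published structure from noiseless tables", {
  mods <- published_models()
  zero_noise <- c(t_half_min = 0, modulus_Pa = 0, pore_diameter_um = 0,
                  diffusivity_um2_s = 0)
  tab <- sim_property_table(noise_sd = zero_noise, reps = 1)

  fE <- fit_property_model(tab, "modulus_Pa")
  expect_equal(fE$coefficients[names(mods$modulus_Pa$coefficients)],
               mods$modulus_Pa$coefficients, tolerance = 1e-9)
  expect_setequal(fE$terms, c("c_prime", "t_prime", "ph_prime"))

  # the half-time model drops pH but keeps the concentration x temperature
  # interaction (and its main effects, by hierarchy)
  fT <- fit_property_model(tab, "t_half_min")
  expect_setequal(fT$terms, c("c_prime", "t_prime", "c_prime:t_prime"))
  expect_equal(fT$coefficients[names(mods$t_half_min$coefficients)],
               mods$t_half_min$coefficients, tolerance = 1e-9)
})

test_that("rank-deficient designs error listing aliased terms", {
  tab <- tidyr::expand_grid(concentration_mg_ml = c(4, 10), temperature_C = c(23, 37))
  tab$pH <- ifelse(tab$concentration_mg_ml == 4, 7.4, 8.4)  # aliased with C
  tab$property <- "modulus_Pa"
  tab$value <- 100 + tab$concentration_mg_ml
  expect_error(fit_property_model(tab, "modulus_Pa"), "aliased")
})

test_that("true coefficients fall in 95% CIs in >= 90% of seeded refits", {
  mods <- published_models()["modulus_Pa"]
  truth <- mods$modulus_Pa$coefficients
  hits <- 0; total <- 0
  for (s in 1:100) {
    tab <- sim_property_table(models = mods, reps = 4, seed = s)
    f <- fit_property_model(tab, "modulus_Pa")
    ci <- confint(f$fit_full)
    for (nm in names(truth)) {
      total <- total + 1
      hits <- hits + (truth[[nm]] >= ci[nm, 1] && truth[[nm]] <= ci[nm, 2])
    }
  }
  expect_gte(hits / total, 0.90)
})

test_that("published models evaluate the printed equations", {
  mods <- published_models()
  base <- tibble::tibble(concentration_mg_ml = 4, temperature_C = 23,
                         pH = 7.4, hydrodynamic_radius_nm = 8.5)
  expect_equal(predict(mods$t_half_min, base)$.pred, 21.89, tolerance = 1e-9)
  expect_equal(predict(mods$modulus_Pa, base)$.pred, -853, tolerance = 1e-9)
  expect_equal(predict(mods$pore_diameter_um, base)$.pred, 2.236, tolerance = 1e-9)
  expect_equal(predict(mods$diffusivity_um2_s, base)$.pred, 49.02, tolerance = 1e-9)

  upper <- tibble::tibble(concentration_mg_ml = 10, temperature_C = 37, pH = 8.4)
  expect_equal(predict(mods$modulus_Pa, upper)$.pred,
               -853 + 5725 + 2720 + 2241, tolerance = 1e-9)

  # extrapolation is opt-in and flagged
  out <- tibble::tibble(concentration_mg_ml = 12, temperature_C = 23, pH = 7.4)
  expect_error(predict(mods$modulus_Pa, out), "override")
  p <- predict(mods$modulus_Pa, out, override = TRUE)
  expect_true(p$.extrapolated)

  # intervals need a data-fitted model
  expect_error(predict(mods$modulus_Pa, base, interval = "prediction"),
               "fitted from data")
})

test_that("both readings of the diffusivity interaction are available", {
  m1 <- published_models()$diffusivity_um2_s
  m2 <- published_models(interaction = "rescaled")$diffusivity_um2_s
  expect_equal(m1$coefficients[["ph_prime:inv_rh_prime"]], 0.37)
  expect_equal(m2$coefficients[["ph_prime:inv_rh_prime"]], 0.37 * 190.23,
               tolerance = 1e-4)
})

test_that("sensitivities are coefficient ratios with one unit entry each", {
  s <- sensitivity(published_models())
  get <- function(prop, term) s$sensitivity[s$property == prop & s$term == term]
  expect_equal(get("modulus_Pa", "t_prime"), 2720 / 5725, tolerance = 1e-9)
  expect_equal(get("modulus_Pa", "ph_prime"), 2241 / 5725, tolerance = 1e-9)
  expect_equal(get("pore_diameter_um", "t_prime"), -1)
  expect_equal(get("diffusivity_um2_s", "c_prime"), -21.1 / 190.23, tolerance = 1e-9)
  expect_equal(get("t_half_min", "c_prime"), -12.69 / 17.45, tolerance = 1e-9)
  ones <- dplyr::summarise(dplyr::group_by(s, property),
                           n1 = sum(abs(abs(sensitivity) - 1) < 1e-12))
  expect_true(all(ones$n1 == 1))
})

test_that("published models are monotone over the coded unit box", {
  mods <- published_models()
  g <- seq(0, 1, length.out = 21)
  co_E <- mods$modulus_Pa$coefficients
  expect_true(all(co_E[c("c_prime", "t_prime", "ph_prime")] > 0))
  expect_lt(mods$pore_diameter_um$coefficients[["t_prime"]], 0)
  # dt_half/dT' = -17.45 + 13.77 C' < 0 for all C' in [0, 1]
  expect_true(all(-17.45 + 13.77 * g < 0))
  expect_gt(mods$diffusivity_um2_s$coefficients[["inv_rh_prime"]], 0)
})

test_that("fit-predict round trip reproduces the generating equation", {
  mods <- published_models()["pore_diameter_um"]
  tab <- sim_property_table(models = mods, noise_sd = c(pore_diameter_um = 0),
                            reps = 1)
  f <- fit_property_model(tab, "pore_diameter_um")
  grid <- tidyr::expand_grid(concentration_mg_ml = c(4, 7, 10),
                             temperature_C = c(23, 37), pH = c(7.4, 8.0, 8.4))
  expect_equal(predict(f, grid)$.pred,
               predict(mods$pore_diameter_um, grid)$.pred, tolerance = 1e-9)
})

test_that("tidy and glance expose broom-style summaries", {
  tab <- sim_property_table(models = published_models()["modulus_Pa"],
                            reps = 2, seed = 1)
  f <- fit_property_model(tab, "modulus_Pa")
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  expect_true("(Intercept)" %in% td$term)
  gl <- glance(f)
  expect_equal(gl$property, "modulus_Pa")
  expect_true(gl$r.squared > 0.9)
  gp <- glance(published_models()$modulus_Pa)
  expect_equal(gp$r.squared, 0.504)
})
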