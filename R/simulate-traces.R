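#' Simulate a turbidity (absorbance vs. time) polymerization trace
#'
#' Generates a logistic sigmoid absorbance profile, the canonical shape of
#' collagen fibrillogenesis turbidity curves, with additive i.i.d. Gaussian
#' measurement noise:
#' \deqn{A(t) = A_0 + \Delta A / (1 + e^{-k (t - t_{1/2})}) + \epsilon}
#' The logistic family gives closed forms for every kinetic metric (half-time
#' \eqn{t_{1/2}}, peak rate \eqn{\Delta A\, k/4}, lag \eqn{t_{1/2} - 2/k}),
#' which makes it a convenient ground-truth generator for
#' [extract_kinetics()].
#'
#' @param plateau_abs total change in absorbance \eqn{\Delta A} (AU), > 0.
#' @param half_time_s polymerization half-time (s), > 0.
#' @param steepness logistic rate constant k (1/s), > 0.
#' @param initial_abs baseline absorbance (AU).
#' @param noise_sd standard deviation of additive Gaussian noise (AU), >= 0.
#' @param duration_s trace duration (s).
#' @param dt_s sampling interval (s); the spectrophotometric protocol samples
#'   every 3.6 s.
#' @param seed integer RNG seed; identical arguments and seed give a
#'   bit-identical trace.
#'
#' @return A tibble with columns `time_s`, `absorbance`, carrying attributes
#'   `meta` (wavelength, dt) and `truth` (the generating parameters).
#' @examples
#' tr <- sim_turbidity_trace(noise_sd = 0, seed = 1)
#' extract_kinetics(tr)
#' @export
sim_turbidity_trace <- function(plateau_abs = 0.8,
                                half_time_s = 21.89 * 60,
                                steepness = 0.01,
                                initial_abs = 0.05,
                                noise_sd = 0.004,
                                duration_s = 7200,
                                dt_s = 3.6,
                                seed = NULL) {
  check_number(plateau_abs, "plateau_abs", 0, strict_lower = TRUE)
  check_number(half_time_s, "half_time_s", 0, strict_lower = TRUE)
  check_number(steepness, "steepness", 0, strict_lower = TRUE)
  check_number(initial_abs, "initial_abs")
  check_number(noise_sd, "noise_sd", 0)
  check_number(duration_s, "duration_s", 0, strict_lower = TRUE)
  check_number(dt_s, "dt_s", 0, strict_lower = TRUE)

  time_s <- seq(0, duration_s, by = dt_s)
  mean_abs <- initial_abs + plateau_abs / (1 + exp(-steepness * (time_s - half_time_s)))
  noise <- if (noise_sd > 0) with_seed(seed, rnorm(length(time_s), 0, noise_sd)) else 0
  out <- tibble(time_s = time_s, absorbance = mean_abs + noise)
  attr(out, "meta") <- list(wavelength_nm = 405, dt_s = dt_s)
  attr(out, "truth") <- list(
    plateau_abs = plateau_abs, half_time_s = half_time_s,
    steepness = steepness, initial_abs = initial_abs,
    rate_au_per_s = plateau_abs * steepness / 4,
    lag_time_s = half_time_s - 2 / steepness,
    noise_sd = noise_sd, seed = seed
  )
  out
}

#' Simulate a confined-compression force-displacement trace
#'
#' Emulates a quasi-static confined-compression experiment on a linear-elastic
#' hydrogel plug: a pre-contact segment of pure load-cell noise while the
#' platen approaches the sample, then a linear force ramp
#' \eqn{F = E\,\varepsilon\,A} once contact is made, with optional artifact
#' injection (bubble escape spikes, signal drift, smooth nonlinearity) used to
#' exercise the downstream rejection rules of [analyze_compression()].
#'
#' The platen is positioned a known approach gap above the *nominal* sample
#' surface, so a sample thinner or thicker than nominal shifts the contact
#' position — exactly the signature the thickness validation rule keys on.
#'
#' @param true_modulus_Pa ground-truth compression modulus E (Pa). May be
#'   negative to exercise the negative-slope rejection rule.
#' @param thickness_mm actual sample thickness (mm), > 0.
#' @param nominal_thickness_mm nominal sample thickness (mm), default 8.5.
#' @param plug_area_mm2 confining plug cross-section (mm^2), default 50.3.
#' @param platen_speed_mm_s platen displacement rate (mm/s), default 0.0085.
#' @param noise_rms_N RMS load-cell noise (N); the default emulates a
#'   high-resolution low-force transducer.
#' @param start_gap_mm platen approach gap above the nominal sample surface (mm).
#' @param sample_rate_hz load-cell sampling rate (Hz).
#' @param max_strain final compressive strain reached (default 0.20).
#' @param artifacts optional list of artifact descriptors, each a list with
#'   `type` in `c("bubble_spike", "drift", "nonlinearity")`, `magnitude` (N),
#'   and for spikes `location` (fraction of the post-contact strain range) and
#'   optional `width` (fraction of samples).
#' @param seed integer RNG seed.
#'
#' @return A tibble with columns `position_mm` (platen travel) and `force_N`,
#'   with attributes `meta` (geometry: nominal thickness, plug area, platen
#'   start height above the chamber base, speed, nominal noise RMS) and
#'   `truth`.
#' @examples
#' tr <- sim_compression_trace(true_modulus_Pa = 3000, noise_rms_N = 1e-12)
#' analyze_compression(tr)
#' @export
sim_compression_trace <- function(true_modulus_Pa = 3000,
                                  thickness_mm = 8.5,
                                  nominal_thickness_mm = 8.5,
                                  plug_area_mm2 = 50.3,
                                  platen_speed_mm_s = 0.0085,
                                  noise_rms_N = 1e-4,
                                  start_gap_mm = 0.3,
                                  sample_rate_hz = 10,
                                  max_strain = 0.20,
                                  artifacts = NULL,
                                  seed = NULL) {
  check_number(true_modulus_Pa, "true_modulus_Pa")
  check_number(thickness_mm, "thickness_mm", 0, strict_lower = TRUE)
  check_number(nominal_thickness_mm, "nominal_thickness_mm", 0, strict_lower = TRUE)
  check_number(plug_area_mm2, "plug_area_mm2", 0, strict_lower = TRUE)
  check_number(platen_speed_mm_s, "platen_speed_mm_s", 0, strict_lower = TRUE)
  check_number(noise_rms_N, "noise_rms_N", 0)
  check_number(start_gap_mm, "start_gap_mm", 0, strict_lower = TRUE)
  check_number(max_strain, "max_strain", 0, strict_lower = TRUE)

  # platen starts (nominal thickness + gap) above the chamber base
  start_height_mm <- nominal_thickness_mm + start_gap_mm
  contact_mm <- start_height_mm - thickness_mm
  if (contact_mm <= 0)
    stopf("`thickness_mm` exceeds platen start height; increase `start_gap_mm`")
  travel_mm <- contact_mm + max_strain * thickness_mm
  dpos <- platen_speed_mm_s / sample_rate_hz
  position_mm <- seq(0, travel_mm, by = dpos)

  strain <- pmax(0, (position_mm - contact_mm) / thickness_mm)
  force_N <- true_modulus_Pa * strain * (plug_area_mm2 * 1e-6)

  post <- strain > 0
  for (a in artifacts %||% list()) {
    type <- a$type %||% stopf("artifact entry missing `type`")
    mag <- a$magnitude %||% stopf("artifact `%s` missing `magnitude`", type)
    switch(type,
      bubble_spike = {
        loc <- a$location %||% 0.5
        width <- a$width %||% 0.01
        center <- contact_mm + loc * max_strain * thickness_mm
        w_mm <- max(width * travel_mm, 2 * dpos)
        force_N <- force_N + mag * exp(-((position_mm - center)^2) / (2 * (w_mm / 2)^2)) * post
      },
      drift = {
        # load-signal drift over the compression phase (the pre-contact
        # baseline stays clean; baseline drift would defeat any threshold
        # detector, which is not the failure mode these artifacts exercise)
        force_N <- force_N +
          mag * pmax(0, position_mm - contact_mm) / (travel_mm - contact_mm)
      },
      nonlinearity = {
        # smooth low-frequency distortion over the post-contact strain range;
        # cycles/phase shape where the distortion falls within the strain span
        cyc <- a$cycles %||% 1
        ph <- a$phase %||% 0
        force_N <- force_N +
          mag * sin(2 * pi * cyc * strain / max_strain + ph) * post
      },
      stopf("unknown artifact type `%s`", type)
    )
  }

  if (noise_rms_N > 0)
    force_N <- force_N + with_seed(seed, rnorm(length(force_N), 0, noise_rms_N))

  out <- tibble(position_mm = position_mm, force_N = force_N)
  attr(out, "meta") <- list(
    nominal_thickness_mm = nominal_thickness_mm,
    plug_area_mm2 = plug_area_mm2,
    platen_start_height_mm = start_height_mm,
    speed_mm_s = platen_speed_mm_s,
    noise_rms_N = noise_rms_N
  )
  attr(out, "truth") <- list(
    true_modulus_Pa = true_modulus_Pa, thickness_mm = thickness_mm,
    contact_position_mm = contact_mm, seed = seed
  )
  out
}

#' Simulate a full-factorial fabrication-property dataset
#'
#' Draws property measurements from an empirical fabrication->property model
#' (by default the packaged published models, see [published_models()])
#' evaluated on a full-factorial design over the experimental parameter
#' ranges, plus additive Gaussian replicate noise. Used to exercise
#' [fit_property_model()] with known generating coefficients.
#'
#' @param models named list of `hydrogel_model` objects (one per property).
#' @param noise_sd named numeric vector of replicate noise standard deviations
#'   per property (same units as each property). Defaults emulate plausible
#'   experimental scatter: 2 min (half-time), 500 Pa (modulus), 0.25 um
#'   (pore diameter), 8 um^2/s (diffusivity).
#' @param design named list of factor levels; defaults to the experimental
#'   design (C = 4, 6, 8, 10 mg/ml; T = 23, 37 C; pH = 7.4, 7.9, 8.4;
#'   R_H = 1.4, 4.5, 6.0, 8.5 nm, diffusivity only).
#' @param reps replicates per design cell, >= 1.
#' @param seed integer RNG seed.
#'
#' @return A long tibble with the fabrication columns, `property`, `value`
#'   and `replicate`.
#' @examples
#' tab <- sim_property_table(reps = 2, seed = 1)
#' dplyr::count(tab, property)
#' @export
sim_property_table <- function(models = published_models(),
                               noise_sd = c(t_half_min = 2, modulus_Pa = 500,
                                            pore_diameter_um = 0.25,
                                            diffusivity_um2_s = 8),
                               design = fabrication_design(),
                               reps = 4,
                               seed = NULL) {
  reps <- check_count(reps, "reps", lower = 1L)
  stopifnot(is.list(models), length(models) > 0)
  # factors varied in the experiments for each property (pH is varied for
  # every modality even where the fitted model retains no pH term; radius
  # applies to diffusion only); unknown properties fall back to model factors
  experiment_factors <- list(
    t_half_min = c("concentration_mg_ml", "temperature_C", "pH"),
    modulus_Pa = c("concentration_mg_ml", "temperature_C", "pH"),
    pore_diameter_um = c("concentration_mg_ml", "temperature_C", "pH"),
    diffusivity_um2_s = c("concentration_mg_ml", "temperature_C", "pH",
                          "hydrodynamic_radius_nm")
  )
  with_seed(seed, {
    rows <- imap(models, function(model, prop) {
      facs <- experiment_factors[[prop]] %||% model_factors(model)
      facs <- union(facs, model_factors(model))
      levels <- design[facs]
      missing <- facs[vapply(levels, is.null, logical(1))]
      if (length(missing))
        stopf("design is missing levels for factor(s): %s",
              paste(missing, collapse = ", "))
      grid <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      grid <- as_tibble(grid[rep(seq_len(nrow(grid)), each = reps), , drop = FALSE])
      grid$replicate <- rep(seq_len(reps), length.out = nrow(grid))
      pred <- predict(model, grid)$.pred
      sdv <- noise_sd[[prop]] %||% 0
      grid$property <- prop
      grid$value <- pred + if (sdv > 0) rnorm(nrow(grid), 0, sdv) else 0
      grid
    })
    bind_rows(rows)
  })
}

#' Experimental fabrication design levels
#'
#' The full-factorial factor levels spanned by the characterization
#' experiments: collagen concentration, polymerization temperature and pH,
#' and probe hydrodynamic radius (diffusivity only).
#'
#' @return Named list of numeric level vectors.
#' @export
fabrication_design <- function() {
  list(
    concentration_mg_ml = c(4, 6, 8, 10),
    temperature_C = c(23, 37),
    pH = c(7.4, 7.9, 8.4),
    hydrodynamic_radius_nm = c(1.4, 4.5, 6.0, 8.5)
  )
}
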