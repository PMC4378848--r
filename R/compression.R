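#' Detect platen-sample contact in a force-displacement trace
#'
#' Contact is the position of the first sample whose force deviates from the
#' initial-window baseline by more than `threshold` times the sensor RMS
#' noise; all preceding samples lie within the band. The baseline is the mean
#' of the first `baseline_frac` of samples, and the RMS noise is estimated
#' from the same window when not supplied.
#'
#' @param trace data frame with columns `position_mm` (monotone increasing)
#'   and `force_N`.
#' @param noise_rms_N sensor RMS noise (N); estimated from the baseline
#'   window if `NULL`.
#' @param threshold detection threshold in multiples of the RMS noise
#'   (default 5).
#' @param baseline_frac fraction of initial samples used for the baseline
#'   and noise estimate (default 0.05).
#'
#' @return A list with `contact_position_mm`, `contact_index`, `baseline_N`,
#'   `noise_rms_N`.
#' @examples
#' tr <- sim_compression_trace(seed = 1)
#' detect_contact(tr)$contact_position_mm
#' @export
detect_contact <- function(trace, noise_rms_N = NULL, threshold = 5,
                           baseline_frac = 0.05) {
  trace <- as_tibble(trace)
  pos <- trace$position_mm
  f <- trace$force_N
  if (is.null(pos) || is.null(f))
    stopf("`trace` must have columns `position_mm` and `force_N`")
  if (any(diff(pos) <= 0)) stopf("`position_mm` must be strictly increasing")
  n <- length(f)
  nw <- max(10L, ceiling(baseline_frac * n))
  baseline <- mean(head(f, nw))
  rms <- noise_rms_N %||% attr(trace, "meta")$noise_rms_N %||% sd(head(f, nw))
  ix <- which(abs(f - baseline) > threshold * rms)
  ix <- ix[ix > nw]  # deviation inside the baseline window is not contact
  if (!length(ix)) stopf("no contact detected")
  list(contact_position_mm = pos[ix[1]], contact_index = ix[1],
       baseline_N = baseline, noise_rms_N = rms)
}

#' Validate sample thickness from the contact position
#'
#' The platen starts a known height above the chamber base, so the measured
#' sample thickness is that start height minus the platen travel at contact.
#' A sample whose thickness deviates from nominal by *more than*
#' `tolerance_fraction` (two-sided) fails; a deviation exactly at the
#' tolerance passes.
#'
#' @param contact_position_mm platen travel at contact (mm).
#' @param platen_start_height_mm platen start height above the chamber base
#'   (mm).
#' @param nominal_thickness_mm nominal sample thickness (mm, default 8.5).
#' @param tolerance_fraction allowed fractional deviation (default 0.05,
#'   i.e. 425 um at 8.5 mm nominal).
#'
#' @return One-row tibble: `measured_thickness_mm`, `deviation_mm`,
#'   `deviation_fraction`, `pass`.
#' @export
validate_thickness <- function(contact_position_mm, platen_start_height_mm,
                               nominal_thickness_mm = 8.5,
                               tolerance_fraction = 0.05) {
  measured <- platen_start_height_mm - contact_position_mm
  if (measured <= 0) stopf("contact position implies non-positive thickness")
  dev <- measured - nominal_thickness_mm
  frac <- abs(dev) / nominal_thickness_mm
  tibble(measured_thickness_mm = measured, deviation_mm = dev,
         deviation_fraction = frac,
         pass = frac <= tolerance_fraction + 1e-12)
}

#' Convert a force-displacement trace to compressive stress-strain
#'
#' Stress is the baseline-subtracted force divided by the confining plug
#' area; strain is platen travel past contact divided by the measured sample
#' thickness. Samples before contact are dropped, so the curve starts at the
#' origin.
#'
#' @inheritParams detect_contact
#' @param contact_position_mm platen travel at contact (mm).
#' @param measured_thickness_mm sample thickness used as the strain
#'   denominator (mm), > 0.
#' @param plug_area_mm2 plug cross-section (mm^2).
#' @param baseline_N force baseline subtracted before conversion (N).
#' @return Tibble with `strain` and `stress_Pa`.
#' @export
to_stress_strain <- function(trace, contact_position_mm, measured_thickness_mm,
                             plug_area_mm2 = 50.3, baseline_N = 0) {
  trace <- as_tibble(trace)
  check_number(measured_thickness_mm, "measured_thickness_mm", 0, strict_lower = TRUE)
  check_number(plug_area_mm2, "plug_area_mm2", 0, strict_lower = TRUE)
  if (contact_position_mm < min(trace$position_mm) ||
      contact_position_mm > max(trace$position_mm))
    stopf("contact position lies outside the trace")
  keep <- trace$position_mm >= contact_position_mm
  tibble(
    strain = (trace$position_mm[keep] - contact_position_mm) / measured_thickness_mm,
    stress_Pa = (trace$force_N[keep] - baseline_N) / (plug_area_mm2 * 1e-6)
  )
}

#' Robust loess smoothing of a stress-strain curve
#'
#' Locally weighted quadratic regression with tricube weights and iterated
#' bisquare robustification, over a large kernel covering `span_fraction` of
#' the data. The large span suppresses localized outliers (e.g. escaping
#' bubbles) while preserving the slow stress-strain trend; exactly
#' polynomial data of degree <= 2 are reproduced to numerical precision.
#'
#' @param curve data frame with `strain`, `stress_Pa` (>= 20 samples).
#' @param span_fraction kernel span as a fraction of the data (default 0.75).
#' @param iterations bisquare robustification iterations (default 5).
#' @return Tibble with `strain` and smoothed `stress_Pa`, same length as the
#'   input.
#' @export
robust_smooth <- function(curve, span_fraction = 0.75, iterations = 5) {
  curve <- as_tibble(curve)
  n <- nrow(curve)
  if (n < 20) stopf("need >= 20 samples to smooth (got %d)", n)
  if (span_fraction * n < 10)
    stopf("span covers too few points for a local quadratic fit")
  fit <- loess(stress_Pa ~ strain, data = curve, span = span_fraction,
               degree = 2, family = "symmetric",
               control = stats::loess.control(iterations = iterations,
                                              surface = "direct"))
  tibble(strain = curve$strain, stress_Pa = fitted(fit))
}

#' Fit the compression modulus over a strain window
#'
#' Ordinary least-squares regression of stress on strain over the
#' (inclusive) window, typically 5-15% strain where the confined-compression
#' response of collagen hydrogels is linear. The slope is the compression
#' modulus E; the window R^2 quantifies linearity and feeds the downstream
#' rejection rule.
#'
#' @param curve data frame with `strain`, `stress_Pa` (normally the
#'   loess-smoothed curve).
#' @param strain_lo,strain_hi window bounds (default 0.05 and 0.15),
#'   inclusive.
#' @return One-row tibble: `modulus_Pa`, `r_squared`, `n_window`.
#' @export
fit_modulus <- function(curve, strain_lo = 0.05, strain_hi = 0.15) {
  curve <- as_tibble(curve)
  keep <- curve$strain >= strain_lo & curve$strain <= strain_hi
  if (sum(keep) < 10)
    stopf("only %d samples in strain window [%g, %g]; need >= 10",
          sum(keep), strain_lo, strain_hi)
  fit <- ols_line(curve$strain[keep], curve$stress_Pa[keep])
  tibble(modulus_Pa = fit$slope, r_squared = fit$r_squared,
         n_window = sum(keep))
}

#' Apply the compression validity rules
#'
#' Applies, in order: the thickness rule (|deviation| <= 5% of nominal), the
#' positive-modulus rule (physics requires E > 0), and the linearity rule
#' (window R^2 >= 0.5, rejecting strong experimental artifacts). The first
#' failing rule is recorded as the rejection reason.
#'
#' @param result one-row data frame with `measured_thickness_mm`,
#'   `modulus_Pa`, `r_squared` (as produced inside [analyze_compression()]).
#' @param nominal_thickness_mm nominal thickness (mm).
#' @param tolerance_fraction thickness tolerance (default 0.05).
#' @param r2_min minimum regression R^2 (default 0.5).
#' @return The input with `valid` and `rejection_reason`
#'   (`"thickness"`, `"negative_modulus"`, `"low_r2"` or `"none"`) set.
#' @export
validate_result <- function(result, nominal_thickness_mm = 8.5,
                            tolerance_fraction = 0.05, r2_min = 0.5) {
  result <- as_tibble(result)
  frac <- abs(result$measured_thickness_mm - nominal_thickness_mm) /
    nominal_thickness_mm
  reason <- dplyr::case_when(
    frac > tolerance_fraction + 1e-12 ~ "thickness",
    result$modulus_Pa <= 0 ~ "negative_modulus",
    result$r_squared < r2_min ~ "low_r2",
    TRUE ~ "none"
  )
  result$valid <- reason == "none"
  result$rejection_reason <- reason
  result
}

#' Automated confined-compression modulus analysis
#'
#' Runs the full objective pipeline on a raw force-displacement trace:
#' contact detection (5 x RMS rule), thickness measurement from the contact
#' position, conversion to compressive stress-strain, robust loess smoothing
#' (75% kernel), linear regression of the smoothed curve over 5-15% strain,
#' and the ordered rejection rules (thickness, negative modulus, low R^2).
#'
#' Geometry defaults are taken from the trace's `meta` attribute when present
#' (as set by [sim_compression_trace()]); for external data supply them
#' explicitly.
#'
#' @inheritParams detect_contact
#' @param nominal_thickness_mm nominal sample thickness (mm).
#' @param plug_area_mm2 plug cross-section (mm^2).
#' @param platen_start_height_mm platen start height above the chamber base
#'   (mm); defaults to `nominal_thickness_mm + 0.3` if not recorded in the
#'   trace metadata.
#' @param thickness_tolerance allowed fractional thickness deviation.
#' @param strain_window regression window, `c(lo, hi)` strain.
#' @param span_fraction loess kernel span.
#' @param r2_min minimum window R^2 for validity.
#'
#' @return One-row tibble: `contact_position_mm`, `measured_thickness_mm`,
#'   `modulus_Pa`, `r_squared`, `valid`, `rejection_reason`. The
#'   stress-strain curves (raw and smoothed) are attached as attribute
#'   `curves` for plotting.
#' @examples
#' tr <- sim_compression_trace(true_modulus_Pa = 3000, seed = 2)
#' analyze_compression(tr)
#' @export
analyze_compression <- function(trace,
                                nominal_thickness_mm = NULL,
                                plug_area_mm2 = NULL,
                                platen_start_height_mm = NULL,
                                noise_rms_N = NULL,
                                threshold = 5,
                                thickness_tolerance = 0.05,
                                strain_window = c(0.05, 0.15),
                                span_fraction = 0.75,
                                r2_min = 0.5) {
  meta <- attr(trace, "meta") %||% list()
  nominal_thickness_mm <- nominal_thickness_mm %||% meta$nominal_thickness_mm %||% 8.5
  plug_area_mm2 <- plug_area_mm2 %||% meta$plug_area_mm2 %||% 50.3
  platen_start_height_mm <- platen_start_height_mm %||%
    meta$platen_start_height_mm %||% (nominal_thickness_mm + 0.3)

  contact <- detect_contact(trace, noise_rms_N = noise_rms_N, threshold = threshold)
  thick <- validate_thickness(contact$contact_position_mm,
                              platen_start_height_mm, nominal_thickness_mm,
                              thickness_tolerance)
  curve <- to_stress_strain(trace, contact$contact_position_mm,
                            thick$measured_thickness_mm, plug_area_mm2,
                            baseline_N = contact$baseline_N)
  smoothed <- robust_smooth(curve, span_fraction = span_fraction)
  fit <- fit_modulus(smoothed, strain_window[1], strain_window[2])

  result <- tibble(
    contact_position_mm = contact$contact_position_mm,
    measured_thickness_mm = thick$measured_thickness_mm,
    modulus_Pa = fit$modulus_Pa,
    r_squared = fit$r_squared
  )
  result <- validate_result(result, nominal_thickness_mm,
                            thickness_tolerance, r2_min)
  attr(result, "curves") <- list(raw = curve, smoothed = smoothed,
                                 strain_window = strain_window)
  result
}

#' Aggregate compression results over replicate samples
#'
#' Mean and standard error of the modulus over *valid* results only, with
#' counts of valid and total samples. With no valid samples the mean and SE
#' are `NA` and the batch is flagged.
#'
#' @param results tibble of per-sample rows as returned by
#'   [analyze_compression()] (stack with `dplyr::bind_rows()`).
#' @return One-row tibble: `n_total`, `n_valid`, `mean_modulus_Pa`,
#'   `se_modulus_Pa`, `any_valid`.
#' @export
summarize_moduli <- function(results) {
  results <- as_tibble(results)
  if (!nrow(results)) stopf("no results supplied")
  ok <- results[results$valid, , drop = FALSE]
  tibble(
    n_total = nrow(results),
    n_valid = nrow(ok),
    mean_modulus_Pa = if (nrow(ok)) mean(ok$modulus_Pa) else NA_real_,
    se_modulus_Pa = if (nrow(ok) > 1) sd(ok$modulus_Pa) / sqrt(nrow(ok))
                    else if (nrow(ok) == 1) 0 else NA_real_,
    any_valid = nrow(ok) > 0
  )
}

#' Plot a compression analysis
#'
#' Raw and loess-smoothed stress-strain curves with the regression window
#' and fitted modulus line.
#'
#' @param result output of [analyze_compression()] (with its `curves`
#'   attribute).
#' @return A ggplot object.
#' @export
plot_compression <- function(result) {
  curves <- attr(result, "curves")
  if (is.null(curves)) stopf("`result` carries no curves attribute")
  win <- curves$strain_window
  both <- bind_rows(
    mutate(curves$raw, which = "raw"),
    mutate(curves$smoothed, which = "smoothed")
  )
  ggplot(both, aes(x = .data$strain, y = .data$stress_Pa, color = .data$which)) +
    annotate("rect", xmin = win[1], xmax = win[2], ymin = -Inf, ymax = Inf,
             alpha = 0.08, fill = "steelblue") +
    geom_line() +
    scale_color_manual(values = c(raw = "grey60", smoothed = "black")) +
    labs(x = "compressive strain", y = "compressive stress (Pa)",
         title = sprintf("E = %.0f Pa, R² = %.3f (%s)",
                         result$modulus_Pa, result$r_squared,
                         ifelse(result$valid, "valid", result$rejection_reason)))
}
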