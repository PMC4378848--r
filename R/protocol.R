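#' Derived geometry of the characterization protocols
#'
#' Computes the handful of derived acquisition constants used throughout the
#' analysis pipelines from the primitive instrument settings: the confining
#' plug cross-section, the confined-compression strain rate, the pixel pitch
#' of the reflectance and FRAP optical configurations, and the bleach-stripe
#' width needed to suppress diffusion edge effects.
#'
#' @param plug_diameter_mm diameter of the confining nylon plug (mm).
#' @param platen_speed_mm_s platen displacement rate (mm/s).
#' @param nominal_thickness_mm nominal hydrogel sample height (mm).
#' @param reflectance_field_um,reflectance_px field size (um) and pixel count
#'   of the confocal reflectance configuration.
#' @param frap_field_um,frap_px field size (um) and pixel count of the FRAP
#'   configuration.
#' @param stripe_width_factor bleach-stripe width as a multiple of the image
#'   width (1.5 removes edge effects at the lateral image borders).
#'
#' @return A tibble with columns `quantity`, `value`, `units`.
#' @examples
#' protocol_geometry()
#' @export
protocol_geometry <- function(plug_diameter_mm = 8,
                              platen_speed_mm_s = 0.0085,
                              nominal_thickness_mm = 8.5,
                              reflectance_field_um = 112.5,
                              reflectance_px = 2048,
                              frap_field_um = 225,
                              frap_px = 512,
                              stripe_width_factor = 1.5) {
  check_number(plug_diameter_mm, "plug_diameter_mm", 0, strict_lower = TRUE)
  check_number(nominal_thickness_mm, "nominal_thickness_mm", 0, strict_lower = TRUE)
  tibble(
    quantity = c("plug_area_mm2", "strain_rate_pct_s",
                 "reflectance_pixel_nm", "frap_pixel_um", "bleach_stripe_px"),
    value = c(
      pi * (plug_diameter_mm / 2)^2,
      platen_speed_mm_s / nominal_thickness_mm * 100,
      reflectance_field_um / reflectance_px * 1000,
      frap_field_um / frap_px,
      stripe_width_factor * frap_px
    ),
    units = c("mm^2", "%/s", "nm/px", "um/px", "px")
  )
}
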