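# independent oracles used across tests; these never call the package
# implementations they are checked against

# explicit finite-difference integrator for 1-D diffusion with reflecting
# boundaries: independent oracle for the analytic FRAP forward model
fd_diffuse_1d <- function(profile0, D, dx, t_total, dt = NULL) {
  dt <- dt %||% (0.2 * dx^2 / (2 * D))
  n_steps <- ceiling(t_total / dt)
  dt <- t_total / n_steps
  r <- D * dt / dx^2
  stopifnot(r <= 0.5)
  u <- profile0
  n <- length(u)
  for (s in seq_len(n_steps)) {
    up <- c(u[2], u[seq_len(n - 1)])      # reflecting boundaries
    dn <- c(u[-1], u[n - 1])
    u <- u + r * (up - 2 * u + dn)
  }
  u
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# logistic turbidity closed forms
logistic_metrics <- function(plateau, half_time, k) {
  list(delta = plateau, t_half = half_time, rate = plateau * k / 4,
       lag = half_time - 2 / k)
}

# ideal binary mask of the rendered network: half-max threshold of the
# noiseless, occlusion-free rendering
ideal_fiber_mask <- function(image_px, n_fibers, seed,
                             fiber_diameter_um = 0.4, pixel_size_um = 0.0549) {
  clean <- sim_fiber_image(image_px = image_px, n_fibers = n_fibers,
                           fiber_diameter_um = fiber_diameter_um,
                           pixel_size_um = pixel_size_um,
                           occlusion_fraction = 0, background_noise_sd = 0,
                           seed = seed)
  structure(unclass(clean) >= 0.5, pixel_size_um = pixel_size_um,
            class = c("fiber_mask", "matrix", "array"))
}

# build a fiber_mask from a plain logical matrix
as_mask <- function(m, pixel_size_um = 1) {
  structure(m, pixel_size_um = pixel_size_um,
            class = c("fiber_mask", "matrix", "array"))
}

# build a frap_sequence from a frame array (already subtracted if n_pre = 0)
as_frap <- function(frames, frame_dt_s = 1.5, n_pre = 0L,
                    pixel_size_um = 0.439) {
  structure(list(frames = frames, frame_dt_s = frame_dt_s,
                 n_pre = as.integer(n_pre), pixel_size_um = pixel_size_um,
                 bleach_axis = "y"),
            class = "frap_sequence")
}
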