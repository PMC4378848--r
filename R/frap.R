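#' Subtract the mean pre-bleach frame from a FRAP sequence
#'
#' Averages the pre-bleach frames and subtracts the result from every
#' post-bleach frame, removing static background heterogeneity so the
#' bleached stripe appears as a negative-going Gaussian on an approximately
#' zero background.
#'
#' @param seq a `frap_sequence` (see [sim_frap_sequence()]) with at least
#'   one pre-bleach frame.
#' @return A `frap_sequence` containing only the background-subtracted
#'   post-bleach frames (`n_pre = 0`, attribute `subtracted = TRUE`).
#' @export
subtract_prebleach <- function(seq) {
  if (!inherits(seq, "frap_sequence")) stopf("`seq` must be a frap_sequence")
  if (seq$n_pre < 1) stopf("no pre-bleach frames to subtract")
  n_frames <- dim(seq$frames)[3]
  if (n_frames - seq$n_pre < 2) stopf("need >= 2 post-bleach frames")
  pre <- seq$frames[, , seq_len(seq$n_pre), drop = FALSE]
  pre_mean <- apply(pre, c(1, 2), mean)
  post_ix <- (seq$n_pre + 1):n_frames
  post <- array(0, dim = c(dim(pre_mean), length(post_ix)))
  for (i in seq_along(post_ix))
    post[, , i] <- seq$frames[, , post_ix[i]] - pre_mean
  out <- seq
  out$frames <- post
  out$n_pre <- 0L
  attr(out, "subtracted") <- TRUE
  out
}

# negative-Gaussian-with-offset profile fit for one frame
fit_gaussian_profile <- function(coord_um, profile) {
  off0 <- median(profile)
  i_min <- which.min(profile)
  a0 <- profile[i_min] - off0
  w <- pmax(off0 - profile, 0)
  s0 <- if (sum(w) > 0) {
    sqrt(sum(w * (coord_um - coord_um[i_min])^2) / sum(w))
  } else diff(range(coord_um)) / 10
  s0 <- max(s0, diff(coord_um[1:2]))
  df <- data.frame(x = coord_um, y = profile)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a * exp(-(x - mu)^2 / (2 * s^2)), data = df,
      start = list(b = off0, a = a0, mu = coord_um[i_min], s = s0),
      lower = c(b = -Inf, a = -Inf, mu = min(coord_um), s = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  res <- resid(fit)
  ss_tot <- sum((profile - mean(profile))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 0
  list(amplitude = unname(cf["a"]), center_um = unname(cf["mu"]),
       sigma_um = abs(unname(cf["s"])), offset = unname(cf["b"]),
       fit_r2 = r2, resid_sd = sd(res))
}

#' Fit per-frame Gaussian profiles to a bleached stripe
#'
#' Collapses each post-bleach frame to a 1-D intensity profile by averaging
#' along the stripe (the stripe spans the full image width, so the profile
#' depends only on the stripe-normal coordinate), then fits a Gaussian with
#' free amplitude, center, width and offset by nonlinear least squares. The
#' bleached stripe appears as a negative Gaussian after pre-bleach
#' subtraction; the offset absorbs any residual background.
#'
#' A frame is marked unusable when the fit fails to converge or the fitted
#' dip is not resolvable above the profile noise (no signal).
#'
#' @param seq a background-subtracted `frap_sequence`
#'   (see [subtract_prebleach()]); sequences with pre-bleach frames are
#'   subtracted automatically.
#' @param snr_min minimum |amplitude| / residual-noise ratio for a frame to
#'   count as signal (default 3).
#' @return Tibble with one row per post-bleach frame: `frame`, `t_s` (0 at
#'   the first post-bleach frame), `amplitude`, `center_um`, `sigma_um`,
#'   `offset`, `fit_r2`, `usable`.
#' @export
fit_profiles <- function(seq, snr_min = 3) {
  if (!inherits(seq, "frap_sequence")) stopf("`seq` must be a frap_sequence")
  if (seq$n_pre > 0) seq <- subtract_prebleach(seq)
  n_post <- dim(seq$frames)[3]
  npx <- dim(seq$frames)[1]
  coord_um <- (seq_len(npx) - 0.5) * seq$pixel_size_um

  rows <- map(seq_len(n_post), function(i) {
    fr <- seq$frames[, , i]
    profile <- if (identical(seq$bleach_axis, "y")) rowMeans(fr) else colMeans(fr)
    g <- fit_gaussian_profile(coord_um, profile)
    if (is.null(g))
      return(tibble(frame = i, t_s = (i - 1) * seq$frame_dt_s,
                    amplitude = NA_real_, center_um = NA_real_,
                    sigma_um = NA_real_, offset = NA_real_,
                    fit_r2 = NA_real_, usable = FALSE))
    noise <- max(g$resid_sd, 1e-12)
    usable <- is.finite(g$sigma_um) && g$sigma_um > 0 &&
      g$amplitude < 0 && abs(g$amplitude) / noise >= snr_min
    tibble(frame = i, t_s = (i - 1) * seq$frame_dt_s,
           amplitude = g$amplitude, center_um = g$center_um,
           sigma_um = g$sigma_um, offset = g$offset, fit_r2 = g$fit_r2,
           usable = usable)
  })
  bind_rows(rows)
}

#' Estimate the diffusion coefficient from Gaussian profile widths
#'
#' For 1-D diffusion normal to the bleached stripe the profile variance
#' grows linearly, sigma^2(t) = sigma_0^2 + 2 D t, so D is half the slope of
#' the regression of sigma^2 on time. Frames whose width jumps by more than
#' `sigma_jump_max` (relative change between consecutive usable frames) are
#' dropped first — a guard against unstable fits when diffusion outruns the
#' frame rate. Validity requires the overall regression R^2 >= `r2_min`
#' (default 0.9) and D >= 0; a negative fitted slope is reported as
#' `no_signal` (no resolvable spreading).
#'
#' @param fits per-frame profile fits from [fit_profiles()].
#' @param frame_dt_s frame interval (s); only needed if `fits` lacks `t_s`.
#' @param sigma_jump_max maximum acceptable relative change in sigma between
#'   consecutive frames (default 0.8).
#' @param r2_min minimum regression R^2 for validity (default 0.9).
#' @return One-row tibble: `D_um2_s`, `regression_r2`, `n_frames_used`,
#'   `valid`, `rejection_reason` (`"low_r2"`, `"sigma_jump"`, `"no_signal"`
#'   or `"none"`). The sigma^2-vs-time points used are attached as attribute
#'   `regression`.
#' @export
estimate_diffusivity <- function(fits, frame_dt_s = NULL,
                                 sigma_jump_max = 0.8, r2_min = 0.9) {
  fits <- as_tibble(fits)
  if (!"t_s" %in% names(fits)) {
    if (is.null(frame_dt_s)) stopf("supply `frame_dt_s` or a `t_s` column")
    fits$t_s <- (fits$frame - 1) * frame_dt_s
  }
  result <- function(D = NA_real_, r2 = NA_real_, n = 0L, reason, reg = NULL) {
    out <- tibble(D_um2_s = D, regression_r2 = r2, n_frames_used = n,
                  valid = identical(reason, "none"), rejection_reason = reason)
    attr(out, "regression") <- reg
    out
  }
  ok <- fits[fits$usable & is.finite(fits$sigma_um), , drop = FALSE]
  if (nrow(ok) == 0) return(result(reason = "no_signal"))
  if (nrow(ok) == 1) return(result(n = 1L, reason = "sigma_jump"))

  # sequential sigma-jump filter: compare each frame to the last kept one
  keep <- logical(nrow(ok))
  keep[1] <- TRUE
  last <- 1
  for (i in seq_len(nrow(ok))[-1]) {
    rel <- abs(ok$sigma_um[i] - ok$sigma_um[last]) / ok$sigma_um[last]
    if (rel <= sigma_jump_max) { keep[i] <- TRUE; last <- i }
  }
  ok <- ok[keep, , drop = FALSE]
  if (nrow(ok) < 2) return(result(n = nrow(ok), reason = "sigma_jump"))

  fit <- ols_line(ok$t_s, ok$sigma_um^2)
  D <- fit$slope / 2
  reg <- tibble(t_s = ok$t_s, sigma2_um2 = ok$sigma_um^2,
                fitted = fit$intercept + fit$slope * ok$t_s)
  reason <- if (fit$r_squared < r2_min) "low_r2"
            else if (D < 0) "no_signal" else "none"
  result(D, fit$r_squared, nrow(ok), reason, reg)
}

#' Full FRAP diffusivity analysis
#'
#' Pre-bleach subtraction, per-frame Gaussian profile fitting, and
#' variance-growth regression in one call.
#'
#' @inheritParams fit_profiles
#' @inheritParams estimate_diffusivity
#' @return One-row tibble as in [estimate_diffusivity()]; the per-frame
#'   profile fits are attached as attribute `profile_fits`.
#' @examples
#' seq <- sim_frap_sequence(true_D_um2_s = 30, image_px = 64,
#'                          stripe_width_px = 96, seed = 1)
#' analyze_frap(seq)
#' @export
analyze_frap <- function(seq, snr_min = 3, sigma_jump_max = 0.8, r2_min = 0.9) {
  fits <- fit_profiles(seq, snr_min = snr_min)
  out <- estimate_diffusivity(fits, sigma_jump_max = sigma_jump_max,
                              r2_min = r2_min)
  attr(out, "profile_fits") <- fits
  out
}

#' Stokes-Einstein diffusion coefficient
#'
#' Reference diffusivity of a spherical particle in a homogeneous fluid,
#' \eqn{D = k_B T / (6 \pi \eta R_H)}, in um^2/s. Used as a comparison
#' reference for measured dextran diffusivities.
#'
#' @param temperature_K absolute temperature (K), > 0.
#' @param viscosity_Pa_s dynamic viscosity (Pa s), > 0.
#' @param radius_nm hydrodynamic (Stokes) radius (nm), > 0.
#' @return Diffusion coefficient (um^2/s).
#' @examples
#' stokes_einstein_D(297, 0.91e-3, 1.4)  # ~171 um^2/s
#' @export
stokes_einstein_D <- function(temperature_K, viscosity_Pa_s, radius_nm) {
  check_number(temperature_K, "temperature_K", 0, strict_lower = TRUE)
  check_number(viscosity_Pa_s, "viscosity_Pa_s", 0, strict_lower = TRUE)
  check_number(radius_nm, "radius_nm", 0, strict_lower = TRUE)
  kB <- 1.380649e-23  # J/K
  D_m2_s <- kB * temperature_K / (6 * pi * viscosity_Pa_s * radius_nm * 1e-9)
  D_m2_s * 1e12
}

#' Plot the FRAP variance-growth regression
#'
#' @param result output of [analyze_frap()] or [estimate_diffusivity()].
#' @return A ggplot object.
#' @export
plot_frap_fit <- function(result) {
  reg <- attr(result, "regression")
  if (is.null(reg)) stopf("result carries no regression points (invalid fit?)")
  ggplot(reg, aes(x = .data$t_s, y = .data$sigma2_um2)) +
    geom_point() +
    geom_line(aes(y = .data$fitted), color = "steelblue") +
    labs(x = "time since first post-bleach frame (s)",
         y = expression(sigma^2 ~ (mu * m^2)),
         title = sprintf("D = %.1f µm²/s, R² = %.3f",
                         result$D_um2_s, result$regression_r2))
}
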