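#' Simulate a confocal-reflectance fiber network image
#'
#' Renders `n_fibers` randomly placed, gently curved fiber segments with a
#' Gaussian cross-section whose full width at half maximum equals the
#' ground-truth fiber diameter, composited by maximum intensity (reflectance
#' ridges do not add). Random occlusion gaps along each fiber emulate the
#' discontinuous appearance of reflectance fibers (out-of-plane fibers block
#' part of the reflected light), and additive Gaussian background noise
#' emulates detector noise.
#'
#' @param image_px pixels per side (square image).
#' @param pixel_size_um pixel pitch (um/px); default 0.0549 (112.5 um field
#'   over 2048 px).
#' @param fiber_diameter_um ground-truth fiber diameter (um); must exceed
#'   twice the pixel size to be resolvable.
#' @param n_fibers number of fibers (0 gives a fiber-free image).
#' @param occlusion_fraction fraction of each fiber's length removed by
#'   occlusion gaps, in \[0, 1).
#' @param background_noise_sd additive Gaussian noise SD (intensity units;
#'   fiber peak intensity is 1).
#' @param curvature bow of each fiber as a fraction of its length (0 gives
#'   straight fibers).
#' @param seed integer RNG seed.
#'
#' @return A `fiber_image`: numeric intensity matrix (rows = y) with
#'   attributes `pixel_size_um` and `truth` (diameter, per-fiber vertex
#'   polylines in pixel coordinates, Gaussian sigma in px).
#' @examples
#' img <- sim_fiber_image(image_px = 128, n_fibers = 4, seed = 1)
#' @export
sim_fiber_image <- function(image_px = 512,
                            pixel_size_um = 0.0549,
                            fiber_diameter_um = 0.4,
                            n_fibers = 12,
                            occlusion_fraction = 0.2,
                            background_noise_sd = 0.15,
                            curvature = 0.08,
                            seed = NULL) {
  image_px <- check_count(image_px, "image_px", lower = 16L)
  check_number(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  check_number(fiber_diameter_um, "fiber_diameter_um", 2 * pixel_size_um,
               strict_lower = TRUE)
  n_fibers <- check_count(n_fibers, "n_fibers", lower = 0L)
  check_number(occlusion_fraction, "occlusion_fraction", 0, 1, strict_upper = TRUE)
  check_number(background_noise_sd, "background_noise_sd", 0)

  diam_px <- fiber_diameter_um / pixel_size_um
  sigma_px <- diam_px / (2 * sqrt(2 * log(2)))  # FWHM -> Gaussian sigma

  with_seed(seed, {
    img <- matrix(0, image_px, image_px)
    # pixel-center coordinates; rows index y, columns x
    Y <- matrix(rep(seq_len(image_px), image_px), image_px)
    X <- matrix(rep(seq_len(image_px), each = image_px), image_px)

    # draw all fiber geometry first so the network layout is unchanged by
    # occlusion/noise settings under the same seed
    polylines <- map(seq_len(n_fibers), function(k) {
      cx <- runif(1, 1, image_px); cy <- runif(1, 1, image_px)
      ang <- runif(1, 0, pi)
      half <- image_px  # chord long enough to span the frame
      p0 <- c(cx - half * cos(ang), cy - half * sin(ang))
      p1 <- c(cx + half * cos(ang), cy + half * sin(ang))
      # quadratic bezier with a perpendicular bow
      nrm <- c(-sin(ang), cos(ang))
      bow <- curvature * (2 * half) * runif(1, -1, 1)
      pc <- (p0 + p1) / 2 + bow * nrm
      u <- seq(0, 1, length.out = 7)
      cbind(
        (1 - u)^2 * p0[1] + 2 * (1 - u) * u * pc[1] + u^2 * p1[1],
        (1 - u)^2 * p0[2] + 2 * (1 - u) * u * pc[2] + u^2 * p1[2]
      )
    })

    for (k in seq_len(n_fibers)) {
      verts <- polylines[[k]]
      best_d2 <- matrix(Inf, image_px, image_px)
      best_s <- matrix(0, image_px, image_px)
      s0 <- 0
      for (j in seq_len(nrow(verts) - 1)) {
        a <- verts[j, ]; b <- verts[j + 1, ]
        dx <- b[1] - a[1]; dy <- b[2] - a[2]
        len2 <- dx^2 + dy^2
        tt <- pmin(pmax(((X - a[1]) * dx + (Y - a[2]) * dy) / len2, 0), 1)
        d2 <- (X - (a[1] + tt * dx))^2 + (Y - (a[2] + tt * dy))^2
        upd <- d2 < best_d2
        best_d2[upd] <- d2[upd]
        best_s[upd] <- s0 + tt[upd] * sqrt(len2)
        s0 <- s0 + sqrt(len2)
      }
      visible <- matrix(TRUE, image_px, image_px)
      if (occlusion_fraction > 0) {
        gap_len <- 2 * diam_px
        n_gaps <- max(1L, round(occlusion_fraction * s0 / gap_len))
        starts <- runif(n_gaps, 0, s0 - gap_len)
        for (g in starts)
          visible <- visible & !(best_s >= g & best_s < g + gap_len)
      }
      contrib <- exp(-best_d2 / (2 * sigma_px^2)) * visible
      img <- pmax(img, contrib)
    }

    if (background_noise_sd > 0)
      img <- img + matrix(rnorm(image_px^2, 0, background_noise_sd),
                          image_px, image_px)

    structure(img,
              pixel_size_um = pixel_size_um,
              truth = list(fiber_diameter_um = fiber_diameter_um,
                           n_fibers = n_fibers, sigma_px = sigma_px,
                           polylines = polylines, seed = seed),
              class = c("fiber_image", "matrix", "array"))
  })
}

#' Simulate a stripe-bleach FRAP image sequence
#'
#' Pre-bleach frames are a uniform baseline plus a static smooth
#' heterogeneity field (emulating uneven background fluorescence) plus frame
#' noise. The bleach writes a horizontal stripe of the given height whose
#' width exceeds the image width, so the bleached profile depends only on
#' the stripe-normal coordinate and evolves by 1-D diffusion. Post-bleach
#' frames carry the exact analytic solution for a rectangular initial
#' deficit (superposition of error functions):
#' \deqn{u(y, t) = \tfrac{d}{2}\left[\mathrm{erf}\frac{h/2 - (y - y_0)}{\sqrt{4Dt}}
#'   + \mathrm{erf}\frac{h/2 + (y - y_0)}{\sqrt{4Dt}}\right]}
#' whose spatial variance grows as 2Dt, the signal exploited by
#' [estimate_diffusivity()].
#'
#' @param true_D_um2_s ground-truth diffusion coefficient (um^2/s), >= 0.
#' @param image_px image side (px), default 512.
#' @param pixel_size_um pixel pitch (um/px), default 0.439 (225 um over 512).
#' @param frame_dt_s frame interval (s), default 1.5.
#' @param n_pre,n_post pre- and post-bleach frame counts (defaults 5 and 5).
#' @param stripe_height_px bleached stripe height (px), default 10.
#' @param stripe_width_px bleached stripe width (px); must be >= `image_px`
#'   (the protocol uses 150% of the image width to suppress edge effects).
#' @param bleach_depth fraction of the baseline intensity removed inside the
#'   stripe, in \[0, 1\].
#' @param background_heterogeneity_sd SD of the static smooth background
#'   field (intensity units).
#' @param noise_sd per-frame Gaussian noise SD (intensity units).
#' @param baseline mean pre-bleach intensity.
#' @param t_first_s elapsed diffusion time at the first post-bleach frame
#'   (bleach-to-readout delay); default half a frame interval.
#' @param seed integer RNG seed.
#'
#' @return A `frap_sequence` object: list with `frames` (array
#'   y-by-x-by-frame), `frame_dt_s`, `n_pre`, `pixel_size_um`, `bleach_axis`
#'   (`"y"`), and `truth`.
#' @examples
#' seq <- sim_frap_sequence(true_D_um2_s = 49.02, image_px = 64, seed = 1,
#'                          stripe_width_px = 96)
#' analyze_frap(seq)
#' @export
sim_frap_sequence <- function(true_D_um2_s = 49.02,
                              image_px = 512,
                              pixel_size_um = 0.439,
                              frame_dt_s = 1.5,
                              n_pre = 5,
                              n_post = 5,
                              stripe_height_px = 10,
                              stripe_width_px = 768,
                              bleach_depth = 0.6,
                              background_heterogeneity_sd = 0.03,
                              noise_sd = 0.01,
                              baseline = 0.8,
                              t_first_s = frame_dt_s / 2,
                              seed = NULL) {
  check_number(true_D_um2_s, "true_D_um2_s", 0)
  image_px <- check_count(image_px, "image_px", lower = 16L)
  check_number(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  check_number(frame_dt_s, "frame_dt_s", 0, strict_lower = TRUE)
  n_pre <- check_count(n_pre, "n_pre", lower = 1L)
  n_post <- check_count(n_post, "n_post", lower = 2L)
  stripe_height_px <- check_count(stripe_height_px, "stripe_height_px", lower = 1L)
  if (stripe_width_px < image_px)
    stopf("`stripe_width_px` must be >= `image_px` (stripe must span the frame)")
  check_number(bleach_depth, "bleach_depth", 0, 1)
  check_number(background_heterogeneity_sd, "background_heterogeneity_sd", 0)
  check_number(noise_sd, "noise_sd", 0)

  with_seed(seed, {
    # static smooth heterogeneity: coarse Gaussian grid, bilinear upsample
    het <- if (background_heterogeneity_sd > 0) {
      g <- 8L
      coarse <- matrix(rnorm(g^2, 0, background_heterogeneity_sd), g, g)
      xi <- seq(1, g, length.out = image_px)
      i0 <- pmin(floor(xi), g - 1L); fr <- xi - i0
      up_rows <- coarse[i0, , drop = FALSE] * (1 - fr) +
                 coarse[i0 + 1L, , drop = FALSE] * fr
      t(t(up_rows[, i0, drop = FALSE]) * (1 - fr) +
        t(up_rows[, i0 + 1L, drop = FALSE]) * fr)
    } else matrix(0, image_px, image_px)

    y_um <- (seq_len(image_px) - 0.5) * pixel_size_um
    y0 <- mean(range(y_um))
    h_um <- stripe_height_px * pixel_size_um
    depth <- bleach_depth * baseline

    deficit_profile <- function(t_s) {
      if (true_D_um2_s * t_s <= 0) {
        depth * (abs(y_um - y0) <= h_um / 2)
      } else {
        s <- sqrt(4 * true_D_um2_s * t_s)
        depth / 2 * (erf((h_um / 2 - (y_um - y0)) / s) +
                     erf((h_um / 2 + (y_um - y0)) / s))
      }
    }

    n_frames <- n_pre + n_post
    frames <- array(0, dim = c(image_px, image_px, n_frames))
    for (i in seq_len(n_frames)) {
      base <- baseline + het
      if (i > n_pre) {
        t_s <- t_first_s + (i - n_pre - 1) * frame_dt_s
        base <- base - deficit_profile(t_s)  # constant along x
      }
      if (noise_sd > 0)
        base <- base + matrix(rnorm(image_px^2, 0, noise_sd), image_px)
      frames[, , i] <- base
    }

    structure(
      list(frames = frames, frame_dt_s = frame_dt_s, n_pre = n_pre,
           pixel_size_um = pixel_size_um, bleach_axis = "y",
           truth = list(true_D_um2_s = true_D_um2_s,
                        stripe_height_px = stripe_height_px,
                        bleach_depth = bleach_depth, baseline = baseline,
                        t_first_s = t_first_s, heterogeneity = het,
                        seed = seed)),
      class = "frap_sequence"
    )
  })
}

#' @export
print.frap_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frap_sequence> %d x %d px, %d pre + %d post frames, dt = %g s, %g um/px\n",
              d[1], d[2], x$n_pre, d[3] - x$n_pre, x$frame_dt_s, x$pixel_size_um))
  invisible(x)
}

#' @export
print.fiber_image <- function(x, ...) {
  cat(sprintf("<fiber_image> %d x %d px, %g um/px\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um")))
  invisible(x)
}
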