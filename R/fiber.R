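#' Configuration for the fiber segmentation pipeline
#'
#' Bundles the tunable parameters of the Frangi-based fiber enhancement and
#' cleanup. All length-like defaults derive from the expected fiber diameter
#' `D_exp`: vesselness scales span 0.5-2 `D_exp` in steps of 0.5 `D_exp`,
#' the small-object area threshold is the area of a circle of diameter
#' `D_exp`, and the morphological structuring disk has diameter `D_exp`/4.
#'
#' @param expected_diameter_um expected fiber diameter `D_exp` (um), default
#'   0.4.
#' @param frangi_beta blob-deviation correction constant (default 0.5, the
#'   value recommended for vesselness filtering).
#' @param scales_um vesselness filter scales (um).
#' @param scale_convention how a scale in um maps to the Gaussian sigma of
#'   the Hessian: `"diameter"` (default) treats the scale as an expected
#'   ridge FWHM, sigma_px = scale_px / 2.355; `"sigma"` treats it as the
#'   sigma directly. Both conventions bracket the same octave around
#'   `D_exp`.
#' @param min_object_area_um2 connected components smaller than this are
#'   removed after thresholding.
#' @param disk_diameter_um structuring-element diameter for morphological
#'   opening and closing.
#' @param prune_spurs remove skeleton spur branches shorter than `D_exp`
#'   before measuring diameters (default `FALSE`: spurs are kept).
#' @return A list of class `fiber_config`.
#' @export
fiber_config <- function(expected_diameter_um = 0.4,
                         frangi_beta = 0.5,
                         scales_um = expected_diameter_um * seq(0.5, 2, by = 0.5),
                         scale_convention = c("diameter", "sigma"),
                         min_object_area_um2 = pi * (expected_diameter_um / 2)^2,
                         disk_diameter_um = expected_diameter_um / 4,
                         prune_spurs = FALSE) {
  check_number(expected_diameter_um, "expected_diameter_um", 0, strict_lower = TRUE)
  check_number(frangi_beta, "frangi_beta", 0, strict_lower = TRUE)
  if (any(diff(scales_um) <= 0) || any(scales_um <= 0))
    stopf("`scales_um` must be positive and increasing")
  structure(list(expected_diameter_um = expected_diameter_um,
                 frangi_beta = frangi_beta, scales_um = scales_um,
                 scale_convention = match.arg(scale_convention),
                 min_object_area_um2 = min_object_area_um2,
                 disk_diameter_um = disk_diameter_um,
                 prune_spurs = prune_spurs),
            class = "fiber_config")
}

px_size_of <- function(image, pixel_size_um = NULL) {
  ps <- pixel_size_um %||% attr(image, "pixel_size_um")
  if (is.null(ps)) stopf("pixel size unknown: supply `pixel_size_um`")
  ps
}

#' Enhance fibers with a multi-scale Frangi vesselness filter
#'
#' Histogram-equalizes the image, then computes 2-D Frangi vesselness at
#' each scale: the scale-normalized Hessian's eigenvalues (|lambda1| <=
#' |lambda2|) give the blob-deviation ratio R_B = lambda1/lambda2 and the
#' structure norm S = sqrt(lambda1^2 + lambda2^2), combined as
#' \deqn{V = \exp(-R_B^2 / 2\beta^2)\,(1 - \exp(-S^2 / 2c^2))}
#' for bright ridges (lambda2 < 0; V = 0 otherwise), with beta = 0.5 and c
#' set to half the maximum Hessian norm of the image at that scale. The
#' final response is the maximum over scales.
#'
#' @param image numeric intensity matrix (a `fiber_image` or any 2-D grid).
#' @param cfg a [fiber_config()].
#' @param pixel_size_um pixel pitch (um/px); defaults to the image attribute.
#' @return Vesselness matrix in \[0, 1\], same shape as the input, with the
#'   pixel size attached.
#' @export
enhance_fibers <- function(image, cfg = fiber_config(), pixel_size_um = NULL) {
  ps <- px_size_of(image, pixel_size_um)
  x <- unclass(image)
  rng <- range(x)
  if (diff(rng) == 0) {
    warnf("constant image: vesselness response is zero everywhere")
    out <- matrix(0, nrow(x), ncol(x))
    attr(out, "pixel_size_um") <- ps
    return(out)
  }
  x <- (x - rng[1]) / diff(rng)
  x <- as.matrix(EBImage::equalize(EBImage::Image(x), range = c(0, 1),
                                   levels = 256))

  beta <- cfg$frangi_beta
  out <- matrix(0, nrow(x), ncol(x))
  for (scale_um in cfg$scales_um) {
    scale_px <- scale_um / ps
    sigma <- switch(cfg$scale_convention,
                    diameter = scale_px / (2 * sqrt(2 * log(2))),
                    sigma = scale_px)
    sigma <- max(sigma, 0.5)
    sm <- as.matrix(EBImage::gblur(EBImage::Image(x), sigma = sigma))
    # scale-normalized Hessian by central differences (rows = y, cols = x),
    # edge-replicated so borders do not fabricate curvature
    lxx <- (shift_mat_rep(sm, 0, -1) - 2 * sm + shift_mat_rep(sm, 0, 1)) * sigma^2
    lyy <- (shift_mat_rep(sm, -1, 0) - 2 * sm + shift_mat_rep(sm, 1, 0)) * sigma^2
    lxy <- (shift_mat_rep(sm, -1, -1) + shift_mat_rep(sm, 1, 1) -
            shift_mat_rep(sm, -1, 1) - shift_mat_rep(sm, 1, -1)) / 4 * sigma^2
    half_tr <- (lxx + lyy) / 2
    root <- sqrt(((lxx - lyy) / 2)^2 + lxy^2)
    mu1 <- half_tr + root
    mu2 <- half_tr - root
    big <- abs(mu1) >= abs(mu2)
    lam2 <- ifelse(big, mu1, mu2)  # larger magnitude
    lam1 <- ifelse(big, mu2, mu1)
    s2 <- lam1^2 + lam2^2
    c_const <- sqrt(max(s2)) / 2
    if (c_const == 0) next
    rb2 <- ifelse(lam2 != 0, (lam1 / lam2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * c_const^2)))
    v[lam2 >= 0] <- 0  # bright ridge: curvature across the ridge is negative
    out <- pmax(out, v)
  }
  attr(out, "pixel_size_um") <- ps
  out
}

#' Binarize a vesselness map and clean the fiber mask
#'
#' Thresholds the vesselness response with Otsu's method, removes connected
#' components smaller than the area of a circle of diameter `D_exp` (objects
#' unlikely to be fibers), then applies morphological opening followed by
#' closing with a disk of diameter `D_exp`/4 (rounded up to at least one
#' pixel) to remove tendrils and close holes.
#'
#' @param vesselness vesselness matrix from [enhance_fibers()].
#' @inheritParams enhance_fibers
#' @return A logical `fiber_mask` matrix (fiber = `TRUE`) with attributes
#'   `pixel_size_um` and `empty` (flag set when no foreground survives).
#' @export
binarize_fibers <- function(vesselness, cfg = fiber_config(),
                            pixel_size_um = NULL) {
  ps <- px_size_of(vesselness, pixel_size_um)
  v <- unclass(vesselness)
  rng <- range(v)
  empty_mask <- function() {
    m <- matrix(FALSE, nrow(v), ncol(v))
    warnf("empty fiber mask")
    structure(m, pixel_size_um = ps, empty = TRUE,
              class = c("fiber_mask", "matrix", "array"))
  }
  if (diff(rng) == 0) return(empty_mask())
  vn <- (v - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(vn), range = c(0, 1))
  mask <- vn > thr

  # area filter: objects smaller than a D_exp-diameter circle are removed
  min_area_px <- cfg$min_object_area_um2 / ps^2
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  areas <- tabulate(as.integer(lab))
  keep <- which(areas >= min_area_px)
  mask <- matrix(as.integer(lab) %in% keep, nrow(v), ncol(v))

  if (any(mask)) {
    disk_px <- max(1, ceiling(cfg$disk_diameter_um / ps))
    if (disk_px %% 2 == 0) disk_px <- disk_px + 1
    brush <- EBImage::makeBrush(disk_px, shape = "disc")
    m <- EBImage::Image(mask * 1)
    m <- EBImage::closing(EBImage::opening(m, brush), brush)
    mask <- as.matrix(m) > 0.5
  }
  if (!any(mask)) return(empty_mask())
  structure(mask, pixel_size_um = ps, empty = FALSE,
            class = c("fiber_mask", "matrix", "array"))
}

# Zhang-Suen morphological thinning, vectorised over the image
zs_thin <- function(mask, max_iter = 200L) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  neighbors <- function(m) {
    list(p2 = shift_mat(m, 1, 0),  p3 = shift_mat(m, 1, -1),
         p4 = shift_mat(m, 0, -1), p5 = shift_mat(m, -1, -1),
         p6 = shift_mat(m, -1, 0), p7 = shift_mat(m, -1, 1),
         p8 = shift_mat(m, 0, 1),  p9 = shift_mat(m, 1, 1))
  }
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (step in 1:2) {
      nb <- neighbors(m)
      b <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqs <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      a <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) a <- a + (seqs[[k]] == 0L & seqs[[k + 1]] == 1L)
      cond <- m == 1L & b >= 2 & b <= 6 & a == 1L
      cond <- cond & if (step == 1) {
        (nb$p2 * nb$p4 * nb$p6 == 0L) & (nb$p4 * nb$p6 * nb$p8 == 0L)
      } else {
        (nb$p2 * nb$p4 * nb$p8 == 0L) & (nb$p2 * nb$p6 * nb$p8 == 0L)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# remove skeleton branch tips shorter than min_len_px (optional, default off)
prune_skeleton <- function(skel, min_len_px) {
  for (i in seq_len(ceiling(min_len_px))) {
    nb <- shift_mat(skel * 1, 1, 0) + shift_mat(skel * 1, -1, 0) +
      shift_mat(skel * 1, 0, 1) + shift_mat(skel * 1, 0, -1) +
      shift_mat(skel * 1, 1, 1) + shift_mat(skel * 1, 1, -1) +
      shift_mat(skel * 1, -1, 1) + shift_mat(skel * 1, -1, -1)
    tips <- skel & nb <= 1
    if (!any(tips)) break
    skel[tips] <- FALSE
  }
  skel
}

#' Measure fiber diameters from a binary mask
#'
#' The Euclidean distance transform of the fiber foreground evaluated at the
#' skeleton (medial axis) gives the local fiber radius: the distance of the
#' central pixel of each fiber from the nearest background pixel. Diameters
#' are twice that, converted to um.
#'
#' @param mask logical fiber mask from [binarize_fibers()].
#' @inheritParams enhance_fibers
#' @return Tibble with one `diameter_um` per skeleton pixel (empty for an
#'   empty mask).
#' @export
fiber_diameters <- function(mask, cfg = fiber_config(), pixel_size_um = NULL) {
  ps <- px_size_of(mask, pixel_size_um)
  m <- unclass(mask)
  if (!any(m)) return(tibble(diameter_um = numeric()))
  dm <- as.matrix(EBImage::distmap(EBImage::Image(m * 1)))
  skel <- zs_thin(m)
  if (cfg$prune_spurs)
    skel <- prune_skeleton(skel, cfg$expected_diameter_um / ps)
  vals <- dm[skel]
  tibble(diameter_um = 2 * vals[vals > 0] * ps)
}

#' Measure pore diameters from a binary mask
#'
#' The Euclidean distance transform of the background evaluated at the
#' central point(s) of each pore -- the regional maxima of the distance map,
#' one sample per maximum plateau -- gives the pore radius: the distance of
#' the pore center from the nearest fiber pixel (inscribed-circle
#' convention). Diameters are twice that, in um.
#'
#' An all-background mask is degenerate: a single image-spanning pore is
#' reported and flagged via the `degenerate` attribute.
#'
#' @inheritParams fiber_diameters
#' @return Tibble with one `diameter_um` per pore; attribute `degenerate` is
#'   `TRUE` when the mask contains no fibers (or no background).
#' @export
pore_diameters <- function(mask, cfg = fiber_config(), pixel_size_um = NULL) {
  ps <- px_size_of(mask, pixel_size_um)
  m <- unclass(mask)
  if (all(m)) {
    out <- tibble(diameter_um = numeric())
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (!any(m)) {
    out <- tibble(diameter_um = ncol(m) * ps)  # one pore spanning the image
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  bg <- !m
  dm <- as.matrix(EBImage::distmap(EBImage::Image(bg * 1)))
  # regional maxima: pixels not dominated in their 8-neighborhood
  mx <- dm
  for (di in -1:1) for (dj in -1:1)
    if (di || dj) mx <- pmax(mx, shift_mat(dm, di, dj))
  peaks <- bg & dm > 0 & dm >= mx
  lab <- EBImage::bwlabel(EBImage::Image(peaks * 1))
  li <- as.integer(lab)
  vals <- vapply(seq_len(max(li)), function(k) max(dm[li == k]), numeric(1))
  out <- tibble(diameter_um = 2 * vals * ps)
  attr(out, "degenerate") <- FALSE
  out
}

#' Summarize fiber and pore morphometry of a mask
#'
#' @inheritParams fiber_diameters
#' @param fiber_d,pore_d precomputed diameter tibbles (computed if `NULL`).
#' @return One-row tibble: `mean_fiber_diameter_um`, `mean_pore_diameter_um`,
#'   `n_fiber_samples`, `n_pore_samples`, `degenerate`. The full diameter
#'   distributions are attached as attribute `distributions`.
#' @export
summarize_morphometry <- function(mask, cfg = fiber_config(),
                                  pixel_size_um = NULL,
                                  fiber_d = NULL, pore_d = NULL) {
  fiber_d <- fiber_d %||% fiber_diameters(mask, cfg, pixel_size_um)
  pore_d <- pore_d %||% pore_diameters(mask, cfg, pixel_size_um)
  degenerate <- isTRUE(attr(mask, "empty")) ||
    isTRUE(attr(pore_d, "degenerate")) || nrow(fiber_d) == 0
  out <- tibble(
    mean_fiber_diameter_um = if (nrow(fiber_d)) mean(fiber_d$diameter_um) else NA_real_,
    mean_pore_diameter_um = if (nrow(pore_d)) mean(pore_d$diameter_um) else NA_real_,
    n_fiber_samples = nrow(fiber_d),
    n_pore_samples = nrow(pore_d),
    degenerate = degenerate
  )
  attr(out, "distributions") <- list(fiber = fiber_d, pore = pore_d)
  out
}

#' Full fiber-structure analysis of a reflectance image
#'
#' Runs enhancement, binarization/cleanup and distance-map morphometry on a
#' single confocal reflectance image.
#'
#' @inheritParams enhance_fibers
#' @param keep_mask attach the binary mask as attribute `mask`.
#' @return One-row tibble as in [summarize_morphometry()].
#' @examples
#' img <- sim_fiber_image(image_px = 128, n_fibers = 6, seed = 1)
#' analyze_fiber_image(img)
#' @export
analyze_fiber_image <- function(image, cfg = fiber_config(),
                                pixel_size_um = NULL, keep_mask = FALSE) {
  ps <- px_size_of(image, pixel_size_um)
  v <- enhance_fibers(image, cfg, ps)
  mask <- binarize_fibers(v, cfg, ps)
  out <- summarize_morphometry(mask, cfg, ps)
  if (keep_mask) attr(out, "mask") <- mask
  out
}

#' Aggregate morphometry over an image batch
#'
#' Mean and standard error of per-image mean fiber and pore diameters, the
#' standard per-condition summary for replicate reflectance images.
#'
#' @param results tibble of per-image rows from [analyze_fiber_image()]
#'   (stack with `dplyr::bind_rows()`).
#' @return One-row tibble with batch means, SEs and image count.
#' @export
summarize_morphometry_batch <- function(results) {
  results <- as_tibble(results)
  ok <- results[!results$degenerate & is.finite(results$mean_fiber_diameter_um), ]
  n <- nrow(ok)
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  tibble(
    n_images = nrow(results), n_used = n,
    mean_fiber_diameter_um = mean(ok$mean_fiber_diameter_um),
    se_fiber_diameter_um = se(ok$mean_fiber_diameter_um),
    mean_pore_diameter_um = mean(ok$mean_pore_diameter_um),
    se_pore_diameter_um = se(ok$mean_pore_diameter_um)
  )
}

#' Plot fiber and pore diameter distributions
#'
#' @param morphometry output of [summarize_morphometry()] or
#'   [analyze_fiber_image()] (carrying the `distributions` attribute).
#' @param binwidth_um histogram bin width (um).
#' @return A ggplot object.
#' @export
plot_morphometry <- function(morphometry, binwidth_um = NULL) {
  dists <- attr(morphometry, "distributions")
  if (is.null(dists)) stopf("no `distributions` attribute found")
  df <- bind_rows(
    mutate(dists$fiber, which = "fiber"),
    mutate(dists$pore, which = "pore")
  )
  ggplot(df, aes(x = .data$diameter_um)) +
    geom_histogram(binwidth = binwidth_um, bins = if (is.null(binwidth_um)) 30 else NULL,
                   fill = "grey40") +
    facet_wrap(~which, scales = "free") +
    labs(x = "diameter (µm)", y = "count")
}
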