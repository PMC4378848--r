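test_that("constant image gives zero vesselness with a warning", {
  img <- matrix(0.5, 64, 64)
  expect_warning(v <- enhance_fibers(img, pixel_size_um = 0.0549), "constant")
  expect_true(all(v == 0))
})

test_that("vesselness peaks along the centerline of a synthetic ridge", {
  n <- 128; sig <- 3.1
  img <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-(i - 64)^2 / (2 * sig^2)))
  v <- enhance_fibers(img, pixel_size_um = 0.0549)
  peaks <- apply(v[, 20:108], 2, which.max)
  expect_true(all(abs(peaks - 64) <= 1))
})

test_that("binarization drops sub-fiber objects and keeps ribbons", {
  cfg <- fiber_config(expected_diameter_um = 0.4)
  ps <- 0.0549
  d_px <- 0.4 / ps  # ~7.3 px
  # an isolated blob of diameter D_exp/2: below the area threshold
  v <- matrix(0, 64, 64)
  ii <- as.matrix(expand.grid(1:64, 1:64))
  blob <- (ii[, 1] - 32)^2 + (ii[, 2] - 32)^2 <= (d_px / 4)^2
  v[ii[blob, ]] <- 1
  attr(v, "pixel_size_um") <- ps
  expect_warning(m <- binarize_fibers(v, cfg), "empty")
  expect_true(attr(m, "empty"))

  # a long ribbon of width D_exp with 1-px holes: retained, holes closed
  v2 <- matrix(0, 64, 64)
  rows <- 29:36
  v2[rows, 5:60] <- 1
  v2[32, c(20, 40)] <- 0  # pinholes
  attr(v2, "pixel_size_um") <- ps
  m2 <- binarize_fibers(v2, cfg)
  expect_false(attr(m2, "empty"))
  expect_true(all(m2[32, c(20, 40)]))
  expect_true(all(m2[rows, 30]))

  # all-background input is flagged empty
  v3 <- matrix(0, 64, 64)
  attr(v3, "pixel_size_um") <- ps
  expect_warning(m3 <- binarize_fibers(v3, cfg), "empty")
  expect_true(attr(m3, "empty"))
})

test_that("ribbon width is recovered from skeleton distances", {
  m <- matrix(FALSE, 40, 60)
  m[16:24, 5:55] <- TRUE  # 9 px wide ribbon
  d <- fiber_diameters(as_mask(m), pixel_size_um = 1)
  # interior skeleton distance ~ half width (distance-transform convention
  # counts to the nearest background pixel center: 5 px -> diameter 10)
  expect_equal(median(d$diameter_um), 9, tolerance = 0.15)

  # two ribbons of width w and 2w give a bimodal distribution
  m2 <- matrix(FALSE, 60, 60)
  m2[10:14, ] <- TRUE   # w = 5
  m2[40:49, ] <- TRUE   # 2w = 10
  d2 <- fiber_diameters(as_mask(m2), pixel_size_um = 1)
  km <- sort(stats::kmeans(d2$diameter_um, 2)$centers)
  expect_equal(km[1], 5, tolerance = 0.25)
  expect_equal(km[2], 10, tolerance = 0.25)

  expect_equal(nrow(fiber_diameters(as_mask(matrix(FALSE, 10, 10)),
                                    pixel_size_um = 1)), 0)
})

test_that("pore diameters follow the inscribed-circle convention", {
  # circular hole of diameter 20 in solid foreground
  m <- matrix(TRUE, 64, 64)
  ii <- as.matrix(expand.grid(1:64, 1:64))
  hole <- (ii[, 1] - 32)^2 + (ii[, 2] - 32)^2 <= 10^2
  m[ii[hole, ]] <- FALSE
  p <- pore_diameters(as_mask(m), pixel_size_um = 1)
  expect_equal(nrow(p), 1)
  expect_equal(p$diameter_um, 20, tolerance = 0.1)

  # checkerboard of square holes of side s: pore diameter ~ s
  s <- 11
  m2 <- matrix(TRUE, 88, 88)
  for (bi in 0:3) for (bj in 0:3)
    if ((bi + bj) %% 2 == 0)
      m2[(bi * 2 * s + 1):(bi * 2 * s + s), (bj * 2 * s + 1):(bj * 2 * s + s)] <- FALSE
  p2 <- pore_diameters(as_mask(m2), pixel_size_um = 1)
  expect_equal(median(p2$diameter_um), s, tolerance = 0.15)

  # all-background mask: one degenerate image-spanning pore
  p3 <- pore_diameters(as_mask(matrix(FALSE, 32, 32)), pixel_size_um = 2)
  expect_true(attr(p3, "degenerate"))
  expect_equal(p3$diameter_um, 64)
})

test_that("morphometry summary matches hand-computed means and flags empties", {
  m <- matrix(FALSE, 40, 40)
  m[18:22, ] <- TRUE
  s <- summarize_morphometry(as_mask(m, pixel_size_um = 0.1))
  d <- fiber_diameters(as_mask(m, pixel_size_um = 0.1))
  expect_equal(s$mean_fiber_diameter_um, mean(d$diameter_um))
  expect_equal(s$n_fiber_samples, nrow(d))

  s_empty <- summarize_morphometry(as_mask(matrix(FALSE, 16, 16), 1))
  expect_true(s_empty$degenerate)
  expect_true(is.na(s_empty$mean_fiber_diameter_um))
})

test_that("batch summary aggregates per-image means", {
  rows <- dplyr::bind_rows(
    tibble::tibble(mean_fiber_diameter_um = 0.40, mean_pore_diameter_um = 2.0,
                   n_fiber_samples = 100, n_pore_samples = 50, degenerate = FALSE),
    tibble::tibble(mean_fiber_diameter_um = 0.44, mean_pore_diameter_um = 2.4,
                   n_fiber_samples = 120, n_pore_samples = 60, degenerate = FALSE),
    tibble::tibble(mean_fiber_diameter_um = NA, mean_pore_diameter_um = NA,
                   n_fiber_samples = 0, n_pore_samples = 1, degenerate = TRUE)
  )
  b <- summarize_morphometry_batch(rows)
  expect_equal(b$n_images, 3)
  expect_equal(b$n_used, 2)
  expect_equal(b$mean_fiber_diameter_um, 0.42)
  expect_equal(b$se_fiber_diameter_um, stats::sd(c(0.40, 0.44)) / sqrt(2))
})

test_that("mean fiber diameter is stable under 90-degree rotation", {
  img <- sim_fiber_image(image_px = 256, n_fibers = 10, seed = 7)
  rot <- t(unclass(img))[, rev(seq_len(256))]
  attr(rot, "pixel_size_um") <- attr(img, "pixel_size_um")
  r0 <- analyze_fiber_image(img)
  r1 <- analyze_fiber_image(rot)
  expect_false(r0$degenerate)
  expect_false(r1$degenerate)
  expect_equal(r1$mean_fiber_diameter_um, r0$mean_fiber_diameter_um,
               tolerance = 0.05)
})

test_that("physical diameters are consistent across pixel sizes", {
  # same 0.8 um ribbon sampled at 0.1 and 0.2 um/px
  m_fine <- matrix(FALSE, 40, 60); m_fine[17:24, ] <- TRUE   # 8 px at 0.1
  m_coarse <- matrix(FALSE, 20, 30); m_coarse[9:12, ] <- TRUE # 4 px at 0.2
  d_fine <- median(fiber_diameters(as_mask(m_fine, 0.1))$diameter_um)
  d_coarse <- median(fiber_diameters(as_mask(m_coarse, 0.2))$diameter_um)
  expect_equal(d_fine, d_coarse, tolerance = 0.25)  # within discretization
})

test_that("pipeline recovers generated fiber geometry on a small network", {
  img <- sim_fiber_image(image_px = 256, n_fibers = 6, seed = 3)
  r <- analyze_fiber_image(img)
  expect_false(r$degenerate)
  expect_equal(r$mean_fiber_diameter_um, 0.4, tolerance = 0.25)
  expect_gt(r$n_fiber_samples, 100)
})
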