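# Membrane band sampling and joint intensity statistics.

test_that("band sampling reads a uniform annulus correctly", {
  # annulus of value 50 between radii 18 and 26 px, contour at r = 22
  size <- 120
  img <- matrix(0, size, size)
  for (row in 1:size) for (col in 1:size) {
    rho <- sqrt((row - 60)^2 + (col - 60)^2)
    if (rho > 18 && rho <= 26) img[row, col] <- 50
  }
  ct <- circle_contour(r = 22 * 0.1, n = 100, center = c(6, 6),
                       pixel_size_um = 0.1)
  pr <- sample_membrane(img, ct, band_width_um = 0.4)
  expect_true(all(abs(pr$raw - 50) / 50 < 0.02))
  expect_false(pr$clipped)
})

test_that("zero or sub-pixel band widths are rejected", {
  ct <- circle_contour(r = 2, n = 50, center = c(4, 4))
  img <- matrix(1, 80, 80)
  expect_error(sample_membrane(img, ct, band_width_um = 0),
               class = "mp_error_invalid_parameter")
  expect_error(sample_membrane(img, ct, band_width_um = 0.05),
               class = "mp_error_invalid_parameter")
})

test_that("a rendered patch reads close to the band-rasterization oracle", {
  cfg <- synth_config(image_size_px = c(160, 160), cell_radius_um = 5,
                      n_frames = 1, patch_birth_rate = 0,
                      drift_speed_um_s = 0, protrusion_amp_um = 0,
                      noise_poisson_scale = 0, noise_gauss_sd = 0, seed = 1)
  truth <- make_patch_schedule(cfg)
  truth$frames[[1]]$patches <- data.frame(
    lineage_id = 1L, theta_start = pi / 3, theta_end = 2 * pi / 3,
    width = pi / 3, origin = "de_novo")
  img <- render_frame(truth, 1, cfg, noise = FALSE)$patch
  mask <- segment_cell(img, 0.1, min_area_px = 500)
  ct <- extract_contour(mask, 100)
  pr <- sample_membrane(img, ct, 1.6, cyto_mean = 100)
  tp <- truth_point_indices(truth, 1, ct)
  inside <- tp[["1"]]
  inside <- inside[c(-1, -length(inside))]  # clear of the boundary
  outside <- setdiff(1:100, c(tp[["1"]], tp[["1"]] + 1, tp[["1"]] - 1))
  # oracle: mean of bilinear samples along the same normals, computed
  # against the raw pixel grid with an independent (dense) sampler
  nrm <- contour_normals(ct)
  oracle <- vapply(inside, function(i) {
    offs <- seq(-0.8, 0.8, by = 0.02)
    xs <- (ct$points[i, 1] + offs * nrm[i, 1]) / 0.1
    ys <- (ct$points[i, 2] + offs * nrm[i, 2]) / 0.1
    mean(membranepatch:::bilinear_sample(img, xs, ys))
  }, numeric(1)) / 100
  expect_lt(max(abs(pr$normalized[inside] - oracle)), 0.06)
  # patch points read close to patch_fold times the out-of-patch points
  ratio <- mean(pr$normalized[inside]) / mean(pr$normalized[outside])
  expect_lt(abs(ratio - mean(oracle) / mean(pr$normalized[outside])), 0.1)
  expect_gt(ratio, 2)
})

test_that("sampling is equivariant under whole-pixel translation", {
  img <- disk_image(120, cx = 55, cy = 55, r = 25, value = 80)
  ct <- circle_contour(r = 2.0, n = 60, center = c(5.5, 5.5),
                       pixel_size_um = 0.1)
  p1 <- sample_membrane(img, ct, band_width_um = 0.5)
  img2 <- matrix(0, 120, 120)
  img2[11:120, 6:120] <- img[1:110, 1:115]   # shift down 10, right 5 px
  ct2 <- ct
  ct2$points <- sweep(ct$points, 2, c(5 * 0.1, 10 * 0.1), `+`)
  ct2$centroid_um <- ct$centroid_um + c(0.5, 1.0)
  p2 <- sample_membrane(img2, ct2, band_width_um = 0.5)
  expect_equal(p1$raw, p2$raw, tolerance = 1e-10)
})

test_that("normalized profile of a patch-free noiseless cell is flat", {
  # sampled on the exact cell outline of a PSF-blurred render, so the
  # check isolates the band sampler from segmentation error and from the
  # pixel-lattice aliasing of razor-sharp synthetic edges (which alone
  # contributes ~+-5%; see the methods vignette)
  cfg <- synth_config(image_size_px = c(160, 160), cell_radius_um = 5,
                      n_frames = 1, patch_birth_rate = 0,
                      psf_sigma_um = 0.25,
                      drift_speed_um_s = 0, protrusion_amp_um = 0,
                      noise_poisson_scale = 0, noise_gauss_sd = 0, seed = 2)
  mv <- make_cell_movie(cfg)
  ctr <- mv$truth$frames[[1]]$centroid_um
  ct <- circle_contour(r = cfg$cell_radius_um, n = 100, center = ctr)
  pr <- sample_membrane(stack_frame(mv$stack, 1, "patch"), ct, 1.6,
                        cyto_mean = 100)
  v <- pr$normalized
  expect_true(all(abs(v - mean(v)) / mean(v) < 0.03))
  expect_lt(stats::sd(v) / mean(v), 0.015)
  # segmentation-derived contours on sharp renders stay within a looser
  # pixelation bound
  cfg2 <- cfg; cfg2$psf_sigma_um <- 0
  mv2 <- make_cell_movie(cfg2)
  fr <- measure_frame(mv2$stack, mv2$truth, 1)
  v2 <- fr$profile_patch$normalized
  expect_lt(stats::sd(v2) / mean(v2), 0.04)
})

test_that("joint histograms report correlations and flag degenerate input", {
  jh <- joint_histogram(1:50, 1:50)
  expect_equal(jh$pearson_r, 1)
  expect_equal(sum(jh$counts), 50)
  expect_equal(jh$n_points, 50)
  jc <- joint_histogram(rep(1, 20), rnorm(20))
  expect_true(jc$undefined)
  expect_true(is.na(jc$pearson_r))
  expect_error(joint_histogram(1:5, 1:4),
               class = "mp_error_invalid_parameter")
  expect_error(joint_histogram(1, 1), class = "mp_error_invalid_parameter")
})

test_that("anti-correlation flips sign when rings are placed inside patches", {
  rs <- vapply(c("exterior", "interior"), function(pl) {
    cfg <- small_config(seed = 31, n_frames = 6, ring_placement = pl)
    mv <- make_cell_movie(cfg)
    a <- c(); b <- c()
    for (f in 1:6) {
      fr <- measure_frame(mv$stack, mv$truth, f)
      a <- c(a, fr$profile_patch$normalized)
      b <- c(b, fr$profile_ring$normalized)
    }
    cor(a, b)
  }, numeric(1))
  expect_lt(rs[["exterior"]], -0.2)
  expect_gt(rs[["interior"]], 0.2)
})
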