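# Contour registration, signed normal speed, kymographs, tracking.

test_that("registration recovers identity, rotation and translation", {
  c1 <- circle_contour(r = 5, n = 100, center = c(8, 8))
  corr <- register_contours(c1, c1)
  expect_equal(corr$offset, 0)
  expect_equal(max(abs(corr$displacement_um)), 0, tolerance = 1e-9)
  # contour rotated by 10 indices
  c2 <- c1
  c2$points <- c1$points[c(91:100, 1:90), ]
  corr2 <- register_contours(c1, c2)
  expect_equal(corr2$offset, 10)
  # pure translation of 1 um
  c3 <- c1
  c3$points <- sweep(c1$points, 2, c(1, 0), `+`)
  c3$centroid_um <- c1$centroid_um + c(1, 0)
  corr3 <- register_contours(c1, c3)
  expect_lt(abs(mean(sqrt(rowSums(corr3$displacement_um^2))) - 1) / 1, 0.05)
  # centroid jumps beyond the cell radius are tracking failures
  c4 <- c1
  c4$points <- sweep(c1$points, 2, c(7, 0), `+`)
  c4$centroid_um <- c1$centroid_um + c(7, 0)
  expect_error(register_contours(c1, c4), class = "mp_error_tracking_lost")
})

test_that("signed speed matches the analytic field for affine motions", {
  c1 <- circle_contour(r = 5, n = 100, center = c(8, 8))
  # isotropic expansion at 0.1 um/s over 2 s
  c2 <- circle_contour(r = 5.2, n = 100, center = c(8, 8))
  sp <- local_speed(register_contours(c1, c2), c1, frame_interval_s = 2)
  expect_true(all(sp > 0))
  expect_lt(abs(mean(sp) - 0.1) / 0.1, 0.1)
  expect_lt(sqrt(mean((sp - 0.1)^2)) / 0.1, 0.1)
  # static: all zero
  sp0 <- local_speed(register_contours(c1, c1), c1, 2)
  expect_equal(max(abs(sp0)), 0, tolerance = 1e-9)
  # pure translation: front positive, rear negative, mean near zero
  c3 <- c1
  c3$points <- sweep(c1$points, 2, c(0.3, 0), `+`)
  c3$centroid_um <- c1$centroid_um + c(0.3, 0)
  sp3 <- local_speed(register_contours(c1, c3), c1, 2)
  expect_lt(abs(mean(sp3)), 0.02)
  expect_gt(max(sp3), 0.1)
  expect_lt(min(sp3), -0.1)
})

test_that("speed-intensity pooling flags a motionless movie and kills shuffled signal", {
  c1 <- circle_contour(r = 5, n = 100, center = c(8, 8))
  contours <- list(c1, c1, c1)
  sm <- compute_speed_map(contours, 2)
  profs <- lapply(1:3, function(f)
    list(patch = fake_profile(100 + rnorm(100), cyto_mean = 100)))
  jh <- speed_intensity_analysis(sm, profs, "patch")
  expect_true(jh$undefined)
  # independent speed and intensity: |r| < 0.1 at n >= 1e4
  set.seed(3)
  jh2 <- joint_histogram(rnorm(2e4), rnorm(2e4))
  expect_lt(abs(jh2$pearson_r), 0.1)
})

test_that("membrane kymographs conserve content and undo rotation", {
  n <- 100
  # a pattern rotating by 3 indices per frame
  base <- rep(1, n); base[10:30] <- 3
  nf <- 8
  profs <- lapply(seq_len(nf), function(t) {
    rot <- ((seq_len(n) - 1 - 3 * (t - 1)) %% n) + 1
    list(patch = fake_profile(base[rot] * 100, cyto_mean = 100))
  })
  # without alignment the stripe moves 3 rows per column
  k0 <- build_membrane_kymograph(profs, NULL, "patch")
  pos <- apply(k0$matrix, 2, function(col) which(col == 3)[1])
  expect_equal(unique(diff(pos)), 3)
  # with correspondences carrying the rotation, the stripe is horizontal
  corrs <- lapply(seq_len(nf - 1), function(t) {
    structure(list(offset = 3L), class = "contour_correspondence")
  })
  k1 <- build_membrane_kymograph(profs, corrs, "patch")
  first_rows <- which(k1$matrix[, 1] == 3)
  for (t in seq_len(nf)) {
    expect_equal(which(k1$matrix[, t] == 3), first_rows)
  }
  # alignment only permutes rows: column sums match the profiles
  for (t in seq_len(nf)) {
    expect_equal(sum(k1$matrix[, t]), sum(profs[[t]]$patch$normalized))
  }
})

test_that("edge-line kymographs sample the image along the tracked line", {
  img <- matrix(50, 60, 60)
  stack <- structure(array(img, c(60, 60, 1, 3)),
                     class = c("frame_stack", "array"),
                     pixel_size_um = 0.1, frame_interval_s = 1,
                     channel_names = "patch")
  pts <- matrix(rep(c(3, 3), 3), ncol = 2, byrow = TRUE)
  dirs <- matrix(rep(c(1, 0), 3), ncol = 2, byrow = TRUE)
  k <- build_edge_kymograph(stack, "patch", pts, dirs, line_length_um = 2)
  expect_true(all(k$matrix == 50))
  expect_equal(ncol(k$matrix), 3)
  # a line leaving the image is clamped and flagged
  pts2 <- matrix(rep(c(5.8, 3), 3), ncol = 2, byrow = TRUE)
  expect_warning(k2 <- build_edge_kymograph(stack, "patch", pts2, dirs,
                                            line_length_um = 2),
                 class = "mp_warning_clipped")
  expect_true(k2$clipped)
})

test_that("a persistent patch yields one continuous track", {
  v <- rep(100, 100); v[20:40] <- 200
  calls <- lapply(1:6, function(f)
    call_patches(fake_profile(v), fake_cyto(100, 10)))
  tk <- track_patches(calls, NULL)
  expect_equal(tk$summary$n_tracks, 1)
  expect_equal(tk$tracks[[1]]$origin, "initial")
  expect_equal(tk$tracks[[1]]$frames, 1:6)
  expect_equal(tk$tracks[[1]]$end, "censored")
})

test_that("gap tolerance bridges flicker below the calling threshold", {
  v_on <- rep(100, 100); v_on[20:40] <- 200
  v_off <- rep(100, 100)
  calls <- lapply(1:7, function(f)
    call_patches(fake_profile(if (f %% 2 == 1) v_on else v_off),
                 fake_cyto(100, 10)))
  tk <- track_patches(calls, NULL, gap_tolerance = 1)
  expect_equal(tk$summary$n_tracks, 1)
  expect_equal(tk$tracks[[1]]$frames, c(1, 3, 5, 7))
  # without tolerance the flicker fragments into separate tracks
  tk0 <- track_patches(calls, NULL, gap_tolerance = 0)
  expect_gt(tk0$summary$n_tracks, 1)
})

test_that("a division is classified as a split of the continuing parent", {
  v1 <- rep(100, 100); v1[20:50] <- 200              # one patch
  v2 <- rep(100, 100); v2[20:33] <- 200; v2[38:50] <- 200  # divided
  calls <- lapply(1:6, function(f)
    call_patches(fake_profile(if (f < 4) v1 else v2), fake_cyto(100, 10)))
  tk <- track_patches(calls, NULL)
  expect_equal(tk$summary$n_tracks, 2)
  origins <- sort(vapply(tk$tracks, `[[`, character(1), "origin"))
  expect_equal(origins, c("initial", "split"))
  expect_equal(tk$summary$split_fraction, 1)
})

test_that("recovered split fraction matches the realized truth fraction at scale", {
  cfg <- synth_config(n_frames = 1200, patch_birth_rate = 0.1,
                      split_probability = 0.6,
                      patch_width_deg_mean = 65, patch_width_deg_sd = 10,
                      patch_lifetime_frames_mean = 25,
                      image_size_px = c(128, 128), seed = 14)
  truth <- make_patch_schedule(cfg)
  b <- truth$events[truth$events$event == "birth", ]
  expect_gt(nrow(b), 50)
  tk <- track_patches(truth_to_calls(truth), NULL)
  ci <- stats::binom.test(sum(b$origin == "split"), nrow(b))$conf.int
  expect_gte(tk$summary$split_fraction, ci[1])
  expect_lte(tk$summary$split_fraction, ci[2])
})

test_that("speed estimates from a rendered expanding cell match the growth rate", {
  cfg <- synth_config(n_frames = 8, patch_birth_rate = 0,
                      drift_speed_um_s = 0, protrusion_amp_um = 0,
                      radius_growth_um_s = 0.1,
                      noise_poisson_scale = 0, noise_gauss_sd = 0,
                      image_size_px = c(200, 200), seed = 2)
  mv <- make_cell_movie(cfg)
  px <- attr(mv$stack, "pixel_size_um")
  cts <- lapply(1:8, function(f)
    extract_contour(segment_cell(stack_frame(mv$stack, f, "patch"), px,
                                 min_area_px = 500), 100))
  sm <- compute_speed_map(cts, cfg$frame_interval_s)
  expect_true(all(sm$speed > 0))
  expect_lt(abs(mean(sm$speed) - 0.1) / 0.1, 0.1)
})
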