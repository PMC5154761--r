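# Circular threshold calling, centre/edge quantification, sizes, tests.

test_that("threshold rule calls the hand-evaluated example", {
  prof <- fake_profile(c(rep(100, 9), rep(120, 10), rep(100, 81)))
  call <- call_patches(prof, fake_cyto(100, 10), k_sd = 1)
  expect_equal(call$threshold, 110)
  expect_equal(nrow(call$intervals), 1)
  expect_equal(call$intervals$start_idx, 10)
  expect_equal(call$intervals$end_idx, 20)
  expect_equal(call$intervals$n_points, 10)
  # even-length interval: centre ties to the lower index
  expect_equal(call$intervals$center_idx, 14)
  # strictly above: values exactly at the threshold are excluded
  prof2 <- fake_profile(c(rep(100, 9), rep(110, 10), rep(100, 81)))
  expect_equal(nrow(call_patches(prof2, fake_cyto(100, 10))$intervals), 0)
})

test_that("constant profiles and full-circle profiles are handled", {
  expect_equal(nrow(call_patches(fake_profile(rep(100, 50)),
                                 fake_cyto(100, 10))$intervals), 0)
  full <- call_patches(fake_profile(rep(200, 50)), fake_cyto(100, 10))
  expect_true(full$full_circle)
  expect_equal(full$intervals$n_points, 50)
  expect_error(call_patches(fake_profile(rep(1, 5)), fake_cyto()),
               class = "mp_error_profile_too_coarse")
})

test_that("wrap-around runs merge into a single interval (rotation oracle)", {
  v <- rep(100, 100)
  v[c(96:100, 1:5)] <- 130
  call <- call_patches(fake_profile(v), fake_cyto(100, 10))
  expect_equal(nrow(call$intervals), 1)
  expect_equal(call$intervals$start_idx, 96)
  expect_equal(call$intervals$end_idx, 6)
  expect_equal(call$intervals$n_points, 10)
  # oracle: rotate the profile so the run is interior, call, rotate back
  rot <- 30
  vr <- v[((seq_len(100) - 1 + rot) %% 100) + 1]
  cr <- call_patches(fake_profile(vr), fake_cyto(100, 10))
  back <- ((cr$intervals$start_idx - 1 + rot) %% 100) + 1
  expect_equal(back, call$intervals$start_idx)
  expect_equal(cr$intervals$n_points, call$intervals$n_points)
})

test_that("calling is rotation equivariant and threshold-shift invariant", {
  set.seed(5)
  v <- 100 + 5 * rnorm(100)
  v[20:40] <- 130 + 5 * rnorm(21)
  v[70:78] <- 125 + 5 * rnorm(9)
  cy <- fake_cyto(100, 10)
  base <- call_patches(fake_profile(v), cy)
  for (m in c(7, 31, 63)) {
    vr <- v[((seq_len(100) - 1 + m) %% 100) + 1]
    cr <- call_patches(fake_profile(vr), cy)
    expect_equal(sort(((cr$intervals$start_idx - 1 + m) %% 100) + 1),
                 sort(base$intervals$start_idx))
  }
  # adding a constant to profile and cytosol mean leaves calls unchanged
  shifted <- call_patches(fake_profile(v + 50), fake_cyto(150, 10))
  expect_equal(shifted$intervals$start_idx, base$intervals$start_idx)
  expect_equal(shifted$intervals$end_idx, base$intervals$end_idx)
})

test_that("raising k_sd never increases total called length", {
  set.seed(8)
  v <- 100 + 8 * rnorm(100)
  v[10:30] <- v[10:30] + 30
  v[60:70] <- v[60:70] + 15
  cy <- fake_cyto(100, 10)
  lens <- vapply(c(0.5, 1, 1.5, 2, 3), function(k) {
    sum(call_patches(fake_profile(v), cy, k_sd = k,
                     min_patch_points = 1)$intervals$n_points)
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("min_patch_points suppresses short runs", {
  v <- rep(100, 100)
  v[50:51] <- 150          # 2-point run
  v[10:19] <- 150          # 10-point run
  call <- call_patches(fake_profile(v), fake_cyto(100, 10),
                       min_patch_points = 3)
  expect_equal(nrow(call$intervals), 1)
  expect_equal(call$intervals$start_idx, 10)
})

test_that("centre/edge measurement follows the geometry contract", {
  # call on one channel, measure another with a ring-like elevation just
  # outside the patch boundaries
  v_call <- rep(100, 100); v_call[40:60] <- 200
  v_meas <- rep(100, 100); v_meas[c(36:39, 61:64)] <- 300
  call <- call_patches(fake_profile(v_call), fake_cyto(100, 10))
  ce <- measure_center_edge(call, fake_profile(v_meas), fake_cyto(100, 5))
  expect_equal(nrow(ce), 1)
  expect_equal(ce$I_cytosol, 1)
  expect_equal(ce$I_center, 1)                # centre sees no ring signal
  expect_equal(ce$I_edge, mean(c((1 + 3) / 2, (1 + 3) / 2)))
  # symmetric odd-length patch: centre equidistant from both edges
  vo <- rep(100, 100); vo[40:60] <- 200
  co <- call_patches(fake_profile(vo), fake_cyto(100, 10))
  ctr <- co$intervals$center_idx
  expect_equal(ctr - co$intervals$start_idx,
               (co$intervals$end_idx - 1) - ctr)
  # measuring the calling channel itself: centre above threshold
  ce2 <- measure_center_edge(co, fake_profile(vo), fake_cyto(100, 10))
  expect_gt(ce2$I_center * 100, co$threshold)
  # sub-minimal patches are skipped with a warning
  v3 <- rep(100, 100); v3[10:11] <- 200; v3[50:57] <- 200
  c3 <- call_patches(fake_profile(v3), fake_cyto(100, 10),
                     min_patch_points = 2)
  expect_warning(m3 <- measure_center_edge(c3, fake_profile(v3),
                                           fake_cyto(100, 10)),
                 class = "mp_warning_patch_too_small")
  expect_equal(nrow(m3), 1)
})

test_that("patch size statistics summarize arc lengths", {
  v <- rep(100, 100); v[11:20] <- 200
  call <- call_patches(fake_profile(v, radius_um = 100 / (2 * pi) * 0.2),
                       fake_cyto(100, 10))
  # arc spacing is 0.2 um -> a 10-point patch is 2.0 um
  st <- patch_size_stats(call)
  expect_equal(st$sizes_um, 2.0)
  expect_equal(st$n, 1)
  empty <- call_patches(fake_profile(rep(100, 100)), fake_cyto(100, 10))
  expect_error(patch_size_stats(empty), class = "mp_error_empty_distribution")
})

test_that("measured sizes order with the configured truth widths", {
  sizes <- vapply(c(50, 100), function(w) {
    cfg <- small_config(seed = 19, n_frames = 4, patch_width_deg_mean = w,
                        patch_width_deg_sd = 5)
    mv <- make_cell_movie(cfg)
    calls <- lapply(1:4, function(f) {
      fr <- measure_frame(mv$stack, mv$truth, f)
      call_patches(fr$profile_patch, fr$cyto_patch)
    })
    patch_size_stats(calls)$mean
  }, numeric(1))
  expect_lt(sizes[1], sizes[2])
})

test_that("group comparison handles degenerate, powered and null cases", {
  # identical paired groups: statistic 0, p = 1
  x <- rnorm(10)
  res <- compare_groups(x, x, paired = TRUE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(compare_groups(1, 1:5), class = "mp_error_insufficient_data")
  expect_error(compare_groups(1:4, 1:6, paired = TRUE),
               class = "mp_error_insufficient_data")
  # separated groups: overwhelmingly significant (small in-test replicate
  # count; the acceptance suite runs the full simulation)
  set.seed(12)
  p_sig <- replicate(30, compare_groups(rnorm(30, 1, 0.3),
                                        rnorm(30, 2, 0.3))$p_value)
  expect_true(all(p_sig < 0.01))
  # null calibration at reduced replicate count
  p_null <- replicate(300, compare_groups(rnorm(15, 1, 0.3),
                                          rnorm(15, 1, 0.3))$p_value)
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.01)
})
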