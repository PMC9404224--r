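test_that("clamp_normalize matches a direct percentile + z-score recomputation", {
  vals <- sample(0:999)  # one of each value
  vol <- volume3d(array(as.double(vals), c(10, 10, 10)))
  out <- clamp_normalize(vol)
  q <- quantile(vals, c(0.005, 0.995), names = FALSE)
  clipped <- pmin(pmax(vals, q[1]), q[2])
  expected <- (clipped - mean(clipped)) / sd(clipped)
  expect_equal(as.vector(out$volume$data), expected, tolerance = 1e-12)
  expect_lt(abs(mean(out$volume$data)), 1e-3)
  expect_lt(abs(sd(out$volume$data) - 1), 1e-2)
})

test_that("constant volumes normalize to zeros with a warning", {
  vol <- volume3d(array(7, c(6, 6, 6)))
  expect_warning(out <- clamp_normalize(vol), "constant")
  expect_true(all(out$volume$data == 0))
})

test_that("normalization is idempotent when nothing is clipped twice", {
  set.seed(3)
  vol <- volume3d(array(rnorm(8^3), c(8, 8, 8)))
  once <- clamp_normalize(vol)$volume
  twice <- clamp_normalize(once)$volume
  # z-scores of z-scores: equal up to the second clipping of extremes
  expect_equal(twice$data, clamp_normalize(once)$volume$data, tolerance = 1e-12)
  expect_lt(max(abs(twice$data - once$data)), 0.05)
})

test_that("target spacing is the per-axis arithmetic mean of case spacings", {
  dir <- withr::local_tempdir()
  m1 <- tiny_cohort(file.path(dir, "a"), n = 1, spacing = c(1, 1, 1))
  m2 <- tiny_cohort(file.path(dir, "b"), n = 1, spacing = c(1, 1, 2))
  both <- rbind(m1, m2)
  both$case_id <- c("a", "b")
  expect_equal(compute_target_spacing(both), c(1, 1, 1.5), tolerance = 1e-6)
  expect_equal(compute_target_spacing(m1), c(1, 1, 1), tolerance = 1e-6)
  expect_error(compute_target_spacing(m1[0, ]), "empty")
})

test_that("resampling to the source spacing is the identity for nearest mode", {
  ph <- sphere_phantom()
  out <- resample_volume(ph$mask, c(1, 1, 1), "nearest")
  expect_identical(out$data, ph$mask$data)
})

test_that("nearest resampling keeps masks binary; sphere volume is conserved", {
  ph <- sphere_phantom()
  up <- resample_volume(ph$mask, c(0.5, 0.5, 0.5), "nearest")
  expect_true(all(up$data %in% c(0L, 1L)))
  v1 <- sum(ph$mask$data) * 1
  v2 <- sum(up$data) * 0.5^3
  expect_lt(abs(v2 - v1) / v1, 0.03)
  # both digitizations sit within 3% of the analytic sphere
  expect_lt(abs(v2 - 4188.79) / 4188.79, 0.03)
})

test_that("patch centres follow the foreground probability", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                      spacing_mm = c(1, 1, 1),
                                      semi_axes_mm = c(9, 8, 7), seed = 6))
  cfg <- patch_config(patch_size = c(16, 16, 16), fg_center_prob = 0.5,
                      samples_per_volume = 2000L)
  set.seed(10)
  smp <- sample_patches(ph$volume, ph$mask, cfg)
  frac <- mean(vapply(smp, function(s) s$fg_centered, logical(1)))
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(frac - 0.5), 3 * se)
  # fg-centred draws actually sit on lesion voxels
  on_lesion <- vapply(smp, function(s)
    ph$mask$data[s$center_index[1], s$center_index[2], s$center_index[3]] == 1L,
    logical(1))
  expect_identical(on_lesion, vapply(smp, function(s) s$fg_centered, logical(1)))
})

test_that("fg_center_prob 1 puts every centre on the lesion; 2:1 is configurable", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                      spacing_mm = c(1, 1, 1),
                                      semi_axes_mm = c(9, 8, 7), seed = 6))
  set.seed(2)
  smp <- sample_patches(ph$volume, ph$mask,
                        patch_config(c(16, 16, 16), fg_center_prob = 1,
                                     samples_per_volume = 50L))
  expect_true(all(vapply(smp, function(s) s$fg_centered, logical(1))))
  cfg21 <- patch_config(c(16, 16, 16), fg_center_prob = 2 / 3)
  expect_equal(cfg21$fg_center_prob, 2 / 3)
  # empty foreground falls back to background with a warning
  empty <- mask3d(array(0L, dim(ph$mask$data)), ph$mask$spacing)
  expect_warning(sample_patches(ph$volume, empty, patch_config(c(16, 16, 16))),
                 "empty foreground")
})

test_that("patches fit inside volumes smaller than the patch (zero padding)", {
  vol <- volume3d(array(rnorm(10 * 10 * 6), c(10, 10, 6)))
  mask <- mask3d(array(0L, c(10, 10, 6)))
  mask$data[5, 5, 3] <- 1L
  set.seed(1)
  smp <- sample_patches(vol, mask, patch_config(c(16, 16, 16), fg_center_prob = 1))
  expect_identical(dim(smp[[1]]$image), c(16L, 16L, 16L))
  expect_equal(sum(smp[[1]]$label), 1)
})

test_that("disabling every augmentation yields the identity", {
  ph <- sphere_phantom()
  set.seed(4)
  smp <- sample_patches(ph$volume, ph$mask, patch_config(c(16, 16, 16)))[[1]]
  off <- augment_config(enable_zoom = FALSE, enable_intensity_scale = FALSE,
                        enable_intensity_shift = FALSE, enable_noise = FALSE,
                        enable_rot90 = FALSE, enable_elastic = FALSE)
  out <- augment_patch(smp, off)
  expect_identical(out$image, smp$image)
  expect_identical(out$label, smp$label)
})

test_that("geometric transforms conserve label binarity; rotation conserves count", {
  ph <- sphere_phantom()
  set.seed(5)
  smp <- sample_patches(ph$volume, ph$mask,
                        patch_config(c(16, 16, 16), fg_center_prob = 1))[[1]]
  rot_only <- augment_config(enable_zoom = FALSE, enable_intensity_scale = FALSE,
                             enable_intensity_shift = FALSE, enable_noise = FALSE,
                             enable_elastic = FALSE, prob = 1)
  out <- augment_patch(smp, rot_only)
  expect_equal(sum(out$label), sum(smp$label))
  expect_equal(sum(out$image), sum(smp$image), tolerance = 1e-12)
  all_geo <- augment_config(enable_intensity_scale = FALSE,
                            enable_intensity_shift = FALSE,
                            enable_noise = FALSE, prob = 1)
  for (i in 1:5) {
    out <- augment_patch(smp, all_geo)
    expect_true(all(out$label %in% c(0L, 1L)))
  }
})

test_that("intensity noise touches the image only, at the configured SD", {
  smp <- structure(list(image = array(100, c(16, 16, 16)),
                        label = array(0L, c(16, 16, 16)),
                        center_index = c(8L, 8L, 8L), fg_centered = FALSE,
                        case_id = "x"),
                   class = "patch_sample")
  smp$label[8, 8, 8] <- 1L
  cfg <- augment_config(enable_zoom = FALSE, enable_intensity_scale = FALSE,
                        enable_intensity_shift = FALSE, enable_rot90 = FALSE,
                        enable_elastic = FALSE, noise_sd_range = c(10, 10),
                        prob = 1)
  set.seed(11)
  out <- augment_patch(smp, cfg)
  n <- length(out$image)
  expect_lt(abs(mean(out$image) - 100), 3 * 10 / sqrt(n))
  expect_gt(sd(out$image), 5)
  expect_identical(out$label, smp$label)
})
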