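test_that("largest_component keeps the biggest region, with deterministic ties", {
  arr <- array(0L, c(20, 20, 8))
  arr[2:11, 2:11, 2:6] <- 1L           # 500 voxels
  arr[14:18, 14:17, 2:3] <- 1L         # 40 voxels
  m <- mask3d(arr)
  out <- largest_component(m)
  expect_equal(sum(out$data), 500)
  expect_true(all(out$data[2:11, 2:11, 2:6] == 1L))
  # single component: identity
  one <- mask3d(array(as.integer(arr == 1L & out$data == 1L), dim(arr)))
  expect_identical(largest_component(one)$data, one$data)
  # two equal components: the one with the smallest linear seed index wins
  arr2 <- array(0L, c(10, 10, 4))
  arr2[7:8, 7:8, 2] <- 1L
  arr2[2:3, 2:3, 2] <- 1L
  tie <- largest_component(mask3d(arr2))
  expect_equal(sum(tie$data), 4)
  expect_equal(tie$data[2, 2, 2], 1L)
  expect_equal(tie$data[7, 7, 2], 0L)
  # empty mask warns and passes through
  expect_warning(largest_component(mask3d(array(0L, c(4, 4, 4)))), "empty")
})

test_that("component labelling agrees with an independent flood fill", {
  for (seed in 1:3) {
    m <- random_mask(c(12, 12, 12), 250, seed = seed)
    for (conn in c(26, 6)) {
      lab <- label_components(m, conn)
      ref <- oracle_label(m$data, conn)
      # same partition (label ids may renumber, so compare by matching)
      expect_equal(attr(lab, "n_components"), max(ref))
      expect_true(all((lab > 0) == (ref > 0)))
      map <- table(lab[lab > 0], ref[ref > 0])
      expect_true(all(rowSums(map > 0) == 1))  # each label maps to one oracle label
    }
  }
})

test_that("two-voxel mask gives the 3-4-5 diameter", {
  arr <- array(0L, c(6, 6, 6))
  arr[1, 1, 1] <- 1L
  arr[4, 5, 1] <- 1L
  g <- compute_geometry(mask3d(arr))
  expect_equal(g$max_3d_diameter_mm, 5)
  expect_equal(g$voxel_volume_mm3, 2)
})

test_that("digitized sphere recovers the analytic volume and isotropy", {
  ph <- sphere_phantom()
  g <- compute_geometry(ph$mask)
  expect_lt(abs(g$voxel_volume_mm3 - 4188.79) / 4188.79, 0.02)
  expect_lt(abs(g$mesh_volume_mm3 - 4188.79) / 4188.79, 0.02)
  expect_lt(abs(g$maximal_diameter_mm - g$minimal_diameter_mm) /
              g$maximal_diameter_mm, 0.02)
  expect_lt(abs(g$max_3d_diameter_mm - 20), sqrt(3))  # within one voxel diagonal
  # mesh volume converges on the voxel volume for large lesions
  expect_lt(abs(g$mesh_volume_mm3 / g$voxel_volume_mm3 - 1), 0.02)
})

test_that("geometry matches brute-force and eigen-decomposition oracles", {
  for (seed in c(2, 7)) {
    set.seed(seed)
    # connected-ish random blob with anisotropic spacing
    m <- random_mask(c(10, 12, 8), 300, spacing = c(0.8, 1, 1.3))
    g <- compute_geometry(m)
    idx <- which(m$data == 1L) - 1L
    co <- cbind((idx %% 10) * 0.8,
                ((idx %/% 10) %% 12) * 1,
                (idx %/% 120) * 1.3)
    expect_equal(g$max_3d_diameter_mm, max(dist(co)), tolerance = 1e-12)
    cen <- scale(co, scale = FALSE)
    ev <- sort(svd(cen)$d^2 / (nrow(co) - 1), decreasing = TRUE)
    expect_equal(g$maximal_diameter_mm, 4 * sqrt(ev[1]), tolerance = 1e-9)
    expect_equal(g$minimal_diameter_mm, 4 * sqrt(ev[2]), tolerance = 1e-9)
    expect_equal(g$voxel_volume_mm3, 300 * 0.8 * 1 * 1.3, tolerance = 1e-12)
  }
})

test_that("max 3D diameter is invariant to translation and axis permutation", {
  m <- random_mask(c(8, 8, 8), 60, spacing = c(0.7, 0.7, 1.1), seed = 5)
  g0 <- compute_geometry(m)
  shifted <- array(0L, c(12, 12, 12))
  shifted[3:10, 4:11, 2:9] <- m$data
  g1 <- compute_geometry(mask3d(shifted, c(0.7, 0.7, 1.1)))
  expect_equal(g1$max_3d_diameter_mm, g0$max_3d_diameter_mm, tolerance = 1e-12)
  perm <- aperm(m$data, c(3, 1, 2))
  g2 <- compute_geometry(mask3d(perm, c(1.1, 0.7, 0.7)))
  expect_equal(g2$max_3d_diameter_mm, g0$max_3d_diameter_mm, tolerance = 1e-12)
})

test_that("degenerate masks degrade gracefully", {
  one <- array(0L, c(4, 4, 4))
  one[2, 2, 2] <- 1L
  expect_warning(g <- compute_geometry(mask3d(one, c(0.7, 0.7, 1.1))), "single-voxel")
  expect_equal(g$max_3d_diameter_mm, 0)
  expect_equal(g$voxel_volume_mm3, 0.7 * 0.7 * 1.1, tolerance = 1e-12)
  expect_gte(g$mesh_volume_mm3, 0)
  expect_warning(g0 <- compute_geometry(mask3d(array(0L, c(4, 4, 4)))), "empty")
  expect_equal(g0$voxel_volume_mm3, 0)
})

test_that("Otsu separates a perfectly bimodal sample", {
  x <- c(rep(50, 100), rep(200, 100))
  thr <- otsu_threshold(x)
  expect_true(thr > 50 && thr < 200)
  expect_true(all((x < thr) == (x == 50)))
})

test_that("Otsu equals the exhaustive within-class-variance search", {
  set.seed(42)
  for (i in 1:10) {
    x <- c(rnorm(300, runif(1, 50, 150), runif(1, 5, 30)),
           rnorm(300, runif(1, 200, 400), runif(1, 5, 40)))
    expect_equal(otsu_threshold(x), oracle_otsu(x), tolerance = 1e-12)
  }
  expect_error(otsu_threshold(rep(3, 10)), "degenerate")
})

test_that("Otsu lands between well-separated Gaussian modes", {
  set.seed(9)
  x <- c(rnorm(1000, 100, 10), rnorm(1000, 300, 10))
  thr <- otsu_threshold(x)
  expect_gt(thr, 150)
  expect_lt(thr, 250)
})

test_that("cystic decomposition recovers a noise-free core exactly", {
  ph <- sphere_phantom(core = list(core_semi_axes_mm = c(6, 6, 6),
                                   core_intensity = 100))
  res <- segment_cystic(ph$volume, ph$mask)
  expect_identical(res$cyst_mask$data, ph$core_mask$data)
  expect_lt(abs(res$report$cyst_volume_mm3 - 904.78) / 904.78, 0.05)
  expect_lt(res$report$cyst_mean_intensity, res$report$lesion_mean_intensity)
})

test_that("cystic decomposition tolerates noise at 10% of the rim-core contrast", {
  ph <- sphere_phantom(noise_sd = 20, seed = 12,
                       core = list(core_semi_axes_mm = c(6, 6, 6),
                                   core_intensity = 100))
  res <- segment_cystic(ph$volume, ph$mask)
  expect_lt(abs(res$report$cyst_volume_mm3 - 904.78) / 904.78, 0.05)
  # surviving components all have >= 30 voxels
  lab <- label_components(res$cyst_mask)
  if (attr(lab, "n_components") > 0)
    expect_true(all(tabulate(lab[lab > 0]) >= 30))
})

test_that("coreless lesions report no cystic component after filtering", {
  ph <- sphere_phantom(noise_sd = 10, seed = 3)
  res <- segment_cystic(ph$volume, ph$mask)
  lab <- label_components(res$cyst_mask)
  k <- attr(lab, "n_components")
  if (k > 0) expect_true(all(tabulate(lab[lab > 0], k) >= 30))
  if (res$report$n_cyst_components > 0)
    expect_lt(res$report$cyst_mean_intensity, res$report$lesion_mean_intensity)
})

test_that("T staging applies the AJCC-consistent boundaries", {
  expect_equal(as.character(classify_t_stage(27.41)), "T2")
  expect_equal(as.character(classify_t_stage(20)), "T1")
  expect_equal(as.character(classify_t_stage(50)), "T2")
  expect_equal(as.character(classify_t_stage(60)), "T3")
  expect_equal(as.character(classify_t_stage(c(5, 35, 80))), c("T1", "T2", "T3"))
  expect_error(classify_t_stage(-1), "diameters")
  expect_error(staging_rules(50, 20), "t1_max")
})
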