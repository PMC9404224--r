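# Operator "models": functions mapping a 3D patch to K x dims probabilities.
const_op <- function(p_fg) function(patch) {
  d <- dim(patch)
  out <- array(0, c(2, d))
  out[1, , , ] <- 1 - p_fg
  out[2, , , ] <- p_fg
  out
}

# Voxelwise operator: foreground probability from the (clamped) intensity.
intensity_op <- function(patch) {
  d <- dim(patch)
  p <- pmin(pmax(patch, 0), 1)
  out <- array(0, c(2, d))
  out[2, , , ] <- p
  out[1, , , ] <- 1 - p
  out
}

test_that("stitching a constant-output model reproduces the constant", {
  vol <- volume3d(array(rnorm(20 * 24 * 16), c(20, 24, 16)))
  for (ov in c(0, 0.25, 0.5)) {
    pm <- sliding_window_predict(const_op(0.3), vol,
                                 inference_config(patch_size = c(8, 8, 8),
                                                  overlap = ov))
    expect_equal(dim(pm$probs), c(2L, 20L, 24L, 16L))
    expect_true(all(abs(pm$probs[2, , , ] - 0.3) < 1e-12))
  }
})

test_that("a volume of exactly one patch equals a single forward pass", {
  set.seed(2)
  vol <- volume3d(array(runif(8^3), c(8, 8, 8)))
  pm <- sliding_window_predict(intensity_op, vol,
                               inference_config(patch_size = c(8, 8, 8),
                                                overlap = 0))
  direct <- intensity_op(vol$data)
  expect_equal(pm$probs, direct, tolerance = 1e-12)
})

test_that("probability maps stay normalized through stitching, TTA, ensembling", {
  set.seed(3)
  vol <- volume3d(array(runif(12 * 12 * 8), c(12, 12, 8)))
  cfg <- inference_config(patch_size = c(8, 8, 8), overlap = 0.5, tta = TRUE)
  pm <- tta_predict(intensity_op, vol, cfg)
  sums <- pm$probs[1, , , ] + pm$probs[2, , , ]
  expect_true(all(abs(sums - 1) < 1e-5))
  em <- ensemble_predict(list(intensity_op, const_op(0.2)), vol, cfg)
  sums2 <- em$probs[1, , , ] + em$probs[2, , , ]
  expect_true(all(abs(sums2 - 1) < 1e-5))
})

test_that("TTA disabled is bit-identical to the plain sliding window", {
  set.seed(4)
  vol <- volume3d(array(runif(10 * 10 * 6), c(10, 10, 6)))
  cfg <- inference_config(patch_size = c(8, 8, 8), overlap = 0.5, tta = FALSE)
  expect_identical(tta_predict(intensity_op, vol, cfg),
                   sliding_window_predict(intensity_op, vol, cfg))
})

test_that("TTA with a voxelwise operator equals the identity pass", {
  # rotation and un-rotation cancel exactly for a voxelwise operator,
  # including on a non-square in-plane grid (pad-to-square path)
  set.seed(5)
  for (dims in list(c(8, 8, 8), c(12, 8, 6))) {
    vol <- volume3d(array(runif(prod(dims)), dims))
    cfg <- inference_config(patch_size = c(4, 4, 4), overlap = 0, tta = TRUE)
    ident <- sliding_window_predict(intensity_op, vol, cfg)
    ttap <- tta_predict(intensity_op, vol, cfg)
    expect_equal(ttap$probs, ident$probs, tolerance = 1e-12)
  }
})

test_that("ensembling averages member maps; single member is a no-op", {
  vol <- volume3d(array(rnorm(8^3), c(8, 8, 8)))
  cfg <- inference_config(patch_size = c(8, 8, 8), overlap = 0)
  one <- ensemble_predict(list(const_op(0.4)), vol, cfg)
  expect_equal(one$probs, sliding_window_predict(const_op(0.4), vol, cfg)$probs,
               tolerance = 1e-12)
  two <- ensemble_predict(list(const_op(0.2), const_op(0.6)), vol, cfg)
  expect_true(all(abs(two$probs[2, , , ] - 0.4) < 1e-12))
  expect_error(ensemble_predict(list(), vol, cfg), "non-empty")
})

test_that("binarize_and_filter removes components below 30 voxels only", {
  probs <- array(0, c(2, 24, 24, 12))
  probs[1, , , ] <- 1
  fg <- array(0L, c(24, 24, 12))
  fg[2:6, 2:6, 2:5] <- 1L       # 100 voxels
  fg[10:12, 10:12, 2:4] <- 1L   # 27 voxels < 30: must vanish
  fg[16:20, 16:18, 2:3] <- 1L   # exactly 30 voxels: must survive
  probs[2, , , ][fg == 1L] <- 1
  probs[1, , , ][fg == 1L] <- 0
  pm <- segvol:::prob_map(probs, c(1, 1, 1), c(0, 0, 0))
  out <- binarize_and_filter(pm, inference_config(min_component_voxels = 30))
  expect_equal(sum(out$data[2:6, 2:6, 2:5]), 100)
  expect_equal(sum(out$data[10:12, 10:12, 2:4]), 0)
  expect_equal(sum(out$data[16:20, 16:18, 2:3]), 30)
})

test_that("the small-component filter is idempotent and complete", {
  set.seed(6)
  for (i in 1:5) {
    m <- random_mask(c(16, 16, 16), 700)
    f1 <- filter_small_components(m, 30)
    f2 <- filter_small_components(f1, 30)
    expect_identical(f2$data, f1$data)
    lab <- oracle_label(f1$data)              # independent labelling oracle
    if (max(lab) > 0)
      expect_true(all(tabulate(lab[lab > 0]) >= 30))
    # nothing above threshold was lost
    lab0 <- oracle_label(m$data)
    big <- which(tabulate(lab0[lab0 > 0]) >= 30)
    expect_equal(sum(f1$data), sum(lab0 %in% big))
  }
})

test_that("argmax ties resolve to background; empty masks are legal", {
  probs <- array(0.5, c(2, 6, 6, 6))
  pm <- segvol:::prob_map(probs, c(1, 1, 1), c(0, 0, 0))
  out <- binarize_and_filter(pm, inference_config())
  expect_equal(sum(out$data), 0)
})

test_that("invalid inference configurations are rejected", {
  expect_error(inference_config(overlap = 1), "overlap")
  expect_error(inference_config(tta_angles = c(45)), "tta_angles")
  expect_error(inference_config(min_component_voxels = -1), "min_component")
})
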