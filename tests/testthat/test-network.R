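# softmax on columns, independent of package internals
softmax_probs_test <- function(s) {
  e <- exp(sweep(s, 2, apply(s, 2, max)))
  sweep(e, 2, colSums(e), "/")
}

test_that("output shape equals input shape with num_classes channels", {
  set.seed(1)
  model <- build_network(network_spec(depth = 4, base_channels = 2))
  x <- array(rnorm(16^3), c(16, 16, 16))
  fwd <- forward_network(model, x)
  expect_equal(dim(fwd$scores), c(2L, 16L^3))
  expect_equal(fwd$dims, c(16L, 16L, 16L))
})

test_that("parameter count equals the hand-derived layer arithmetic", {
  set.seed(2)
  model <- build_network(network_spec(depth = 2, base_channels = 4))
  # enc1 (1->4, s1):  4*1*27 + 2*4 + 4*4*27 + 2*4 + proj 4*1 + 2*4 = 568
  # enc2 (4->8, s2):  8*4*27 + 2*8 + 8*8*27 + 2*8 + proj 8*4 + 2*8 = 2672
  # up1  (8->4):      4*8*8 + 4                                    = 260
  # dec1 (8->4, s1):  4*8*27 + 2*4 + 4*4*27 + 2*4 + proj 4*8 + 2*4 = 1352
  # head (4->2):      2*4 + 2                                      = 10
  expect_equal(count_params(model), 568L + 2672L + 260L + 1352L + 10L)
})

test_that("patch size must divide by 2^(depth-1)", {
  expect_error(forward_network(build_network(network_spec(depth = 4, base_channels = 2)),
                               array(0, c(50, 50, 50))),
               "divisible")
  expect_silent(check_patch_divisibility(network_spec(depth = 3), c(48, 48, 48)))
})

test_that("a zeroed residual branch reduces to the identity path", {
  set.seed(3)
  p <- segvol:::init_resunit(4L, 4L, 1L)  # no projection: skip is x itself
  p$g2 <- rep(0, 4)
  p$b2 <- rep(0, 4)
  x <- matrix(rnorm(4 * 4^3), 4, 4^3)
  out <- segvol:::resunit_fwd(x, c(4L, 4L, 4L), p, 1L)
  expect_equal(out$y, pmax(x, 0), tolerance = 1e-6)
})

test_that("the network is translation-covariant up to border effects", {
  set.seed(4)
  model <- build_network(network_spec(depth = 2, base_channels = 4))
  x <- array(0, c(24, 24, 24))
  x[11:14, 11:14, 11:14] <- rnorm(64)  # compact support away from borders
  xs <- array(0, c(24, 24, 24))
  xs[13:16, 11:14, 11:14] <- x[11:14, 11:14, 11:14]  # shift one stride (2 voxels)
  f0 <- array(forward_network(model, x)$scores, c(2, 24, 24, 24))
  f1 <- array(forward_network(model, xs)$scores, c(2, 24, 24, 24))
  d <- abs(f1[, 11:18, 9:16, 9:16] - f0[, 9:16, 9:16, 9:16])
  # instance-norm statistics couple residual border effects into the
  # interior, so covariance holds only to a small relative error
  expect_lt(max(d), 5e-3 * max(abs(f0)))
})

test_that("soft Dice loss hits its closed-form anchor points", {
  y <- array(0L, c(4, 4, 4))
  y[1:2, , ] <- 1L                     # half the voxels
  n <- 64
  # perfect one-hot prediction
  p <- matrix(0, 2, n)
  p[2, as.vector(y) == 1] <- 1
  p[1, as.vector(y) == 0] <- 1
  expect_lte(dice_loss(p, y), 1e-5 / (2 * 32 + 1e-5))
  # disjoint prediction
  pd <- matrix(0, 2, n)
  pd[2, as.vector(y) == 0] <- 1
  pd[1, as.vector(y) == 1] <- 1
  expect_gt(dice_loss(pd, y), 1 - 1e-5)
  # p == 0.5 on a half-foreground target: 1 - 2*0.25n / (0.5n + 0.5n) = 0.5
  ph <- matrix(0.5, 2, n)
  expect_equal(dice_loss(ph, y, loss_config(smooth = 1e-12)), 0.5,
               tolerance = 1e-9)
})

test_that("cross-entropy matches the per-voxel brute-force oracle", {
  # uniform scores: ln 2
  expect_equal(cross_entropy_loss(matrix(0, 2, 10), rep(c(0, 1), 5)), log(2),
               tolerance = 1e-12)
  set.seed(6)
  s <- matrix(rnorm(2 * 64), 2, 64)
  y <- as.integer(runif(64) > 0.5)
  brute <- 0
  for (i in 1:64) {
    pr <- exp(s[, i]) / sum(exp(s[, i]))
    brute <- brute - log(pr[if (y[i] == 1) 2 else 1])
  }
  expect_equal(cross_entropy_loss(s, y), brute / 64, tolerance = 1e-10)
  # certain correct prediction: 0
  s1 <- matrix(c(-50, 50), 2, 8)
  expect_lt(cross_entropy_loss(s1, rep(1, 8)), 1e-12)
})

test_that("combined loss mixes the two terms with the configured weights", {
  y <- rep(c(0, 1), 32)
  s <- matrix(0, 2, 64)
  cl <- combined_loss(s, y)
  expect_equal(as.numeric(cl), 0.5 * 0.5 + 0.5 * log(2), tolerance = 1e-3)
  # weights (1, 0) reduce to the Dice term exactly
  dice_only <- combined_loss(s, y, loss_config(dice_weight = 1, ce_weight = 0))
  expect_equal(as.numeric(dice_only), dice_loss(softmax_probs_test(s), y),
               tolerance = 1e-12)
  set.seed(7)
  sp <- matrix(rnorm(2 * 27), 2, 27)
  yp <- as.integer(runif(27) > 0.6)
  both <- combined_loss(sp, yp)
  expect_equal(as.numeric(both), 0.5 * attr(both, "dice") + 0.5 * attr(both, "ce"),
               tolerance = 1e-12)
})

test_that("hard-label duality: 1 - dice_loss equals the evaluation DSC", {
  set.seed(8)
  for (i in 1:5) {
    pred <- random_mask(c(5, 5, 5), sample(10:60, 1))
    gt <- random_mask(c(5, 5, 5), sample(10:60, 1))
    p <- matrix(0, 2, 125)
    p[2, ] <- as.vector(pred$data)
    p[1, ] <- 1 - p[2, ]
    ld <- dice_loss(p, gt$data, loss_config(smooth = 1e-12))
    expect_equal(1 - ld, dsc(pred, gt), tolerance = 1e-6)
  }
})

test_that("loss gradient matches finite differences through the softmax", {
  set.seed(9)
  s <- matrix(rnorm(2 * 27), 2, 27)
  y <- as.integer(runif(27) > 0.5)
  cfg <- loss_config()
  lg <- segvol:::combined_loss_grad(s, y, cfg)
  eps <- 1e-6
  for (i in sample(length(s), 6)) {
    s1 <- s; s1[i] <- s1[i] + eps
    s0 <- s; s0[i] <- s0[i] - eps
    num <- (as.numeric(combined_loss(s1, y, cfg)) -
            as.numeric(combined_loss(s0, y, cfg))) / (2 * eps)
    expect_equal(lg$dscores[i], num, tolerance = 1e-5)
  }
})
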