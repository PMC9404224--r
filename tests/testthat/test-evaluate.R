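test_that("DSC and IOU follow the set-cardinality formulas", {
  a <- array(0L, c(4, 4, 4)); b <- array(0L, c(4, 4, 4))
  a[1:4, 1, 1] <- 1L              # |X| = 4
  b[3:4, 1, 1] <- 1L; b[1:2, 2, 1] <- 1L  # |Y| = 4, overlap 2
  expect_equal(dsc(a, b), 0.5)
  expect_equal(iou(a, b), 1 / 3)
  expect_equal(2 * iou(a, b) / (1 + iou(a, b)), dsc(a, b))
  expect_equal(dsc(a, a), 1)
  expect_equal(iou(a, a), 1)
})

test_that("empty-mask conventions: one empty 0, both empty 1 with warning", {
  x <- array(0L, c(3, 3, 3))
  y <- array(0L, c(3, 3, 3)); y[1, 1, 1] <- 1L
  expect_equal(dsc(x, y), 0)
  expect_equal(iou(x, y), 0)
  expect_warning(d <- dsc(x, x), "both masks empty")
  expect_equal(d, 1)
  expect_warning(j <- iou(x, x), "both masks empty")
  expect_equal(j, 1)
  expect_error(dsc(x, array(0L, c(2, 2, 2))), "shape mismatch")
})

test_that("DSC = 2 IOU / (1 + IOU) and symmetry on random mask pairs", {
  set.seed(8)
  for (i in 1:100) {
    x <- random_mask(c(6, 6, 6), sample(1:100, 1))
    y <- random_mask(c(6, 6, 6), sample(1:100, 1))
    d <- dsc(x, y); j <- iou(x, y)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_equal(d, dsc(y, x), tolerance = 1e-15)
    expect_equal(j, iou(y, x), tolerance = 1e-15)
  }
})

test_that("classification metrics equal hand-computed one-vs-rest values", {
  # confusion matrix rows = truth: [[47,3,0],[3,130,5],[0,3,9]]
  truth <- rep(c("T1", "T2", "T3"), c(50, 138, 12))
  pred <- c(rep("T1", 47), rep("T2", 3),
            rep("T1", 3), rep("T2", 130), rep("T3", 5),
            rep("T2", 3), rep("T3", 9))
  rep_ <- classification_metrics(truth, pred)
  n <- 200
  expect_equal(rep_$accuracy, (47 + 130 + 9) / n)
  # T1: TP 47, FP 3, FN 3, TN 147
  expect_equal(rep_$per_class$precision[1], 47 / 50)
  expect_equal(rep_$per_class$recall[1], 47 / 50)
  expect_equal(rep_$per_class$specificity[1], 147 / 150)
  # T2: TP 130, FP 6, FN 8, TN 56
  expect_equal(rep_$per_class$precision[2], 130 / 136)
  expect_equal(rep_$per_class$recall[2], 130 / 138)
  expect_equal(rep_$per_class$specificity[2], 56 / 62)
  # T3: TP 9, FP 5, FN 3, TN 183
  expect_equal(rep_$per_class$precision[3], 9 / 14)
  expect_equal(rep_$per_class$recall[3], 9 / 12)
  expect_equal(rep_$per_class$specificity[3], 183 / 188)
  expect_equal(rep_$per_class$support, c(50L, 138L, 12L))
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(rep_$macro_avg[["f1"]],
               mean(c(f1(47/50, 47/50), f1(130/136, 130/138), f1(9/14, 9/12))))
  expect_equal(rep_$weighted_avg[["recall"]], rep_$accuracy)
})

test_that("perfect predictions score 1 everywhere; absent class warns", {
  rep_ <- classification_metrics(c("T1", "T2", "T3"), c("T1", "T2", "T3"))
  expect_equal(rep_$accuracy, 1)
  expect_true(all(rep_$per_class$precision == 1))
  expect_true(all(rep_$per_class$recall == 1))
  expect_warning(r2 <- classification_metrics(c("T1", "T1", "T2"),
                                              c("T1", "T1", "T2")),
                 "absent")
  expect_true(is.na(r2$per_class$recall[3]))
  expect_equal(r2$n_defined_classes, 2)
  expect_error(classification_metrics(character(), character()), "empty")
})

test_that("weighted-average recall equals accuracy on random label sets", {
  set.seed(4)
  for (i in 1:10) {
    truth <- sample(c("T1", "T2", "T3"), 60, replace = TRUE)
    pred <- sample(c("T1", "T2", "T3"), 60, replace = TRUE)
    r <- suppressWarnings(classification_metrics(truth, pred))
    expect_equal(r$weighted_avg[["recall"]], r$accuracy, tolerance = 1e-12)
    expect_equal(sum(r$per_class$support), 60L)
    expect_equal(sum(r$confusion), 60L)
  }
})

test_that("ICC(2,1) matches a two-way ANOVA mean-squares oracle", {
  set.seed(21)
  a <- rnorm(30, 100, 10)
  b <- a + rnorm(30, 2, 3)
  res <- icc_agreement(a, b)
  # independent route: mean squares from aov()
  df <- data.frame(y = c(a, b), case = factor(rep(1:30, 2)),
                   rater = factor(rep(1:2, each = 30)))
  ms <- summary(stats::aov(y ~ case + rater, df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc_oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 30)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-10)
})

test_that("identical raters give ICC 1; offsets are penalized", {
  a <- c(5, 9, 2, 7, 4, 8)
  expect_equal(icc_agreement(a, a)$icc, 1, tolerance = 1e-12)
  set.seed(3)
  base <- rnorm(40, 50, 1)     # between-case SD 1
  res <- icc_agreement(base, base + 10)
  expect_lt(res$icc, 0.5)      # absolute agreement punishes the shift
  expect_error(icc_agreement(rep(1, 10), rep(1, 10)), "degenerate")
  expect_error(icc_agreement(1:2, 1:2), "at least 3")
})

test_that("ICC recovers the true variance-ratio on simulated raters", {
  set.seed(77)
  n <- 200
  case_eff <- rnorm(n, 0, 3)          # case variance 9
  a <- case_eff + rnorm(n, 0, 1)      # error variance 1
  b <- case_eff + rnorm(n, 0, 1)
  res <- icc_agreement(a, b)
  expect_gt(res$icc, 0.85)
  expect_lt(res$icc, 0.95)            # true ICC = 9 / 10
  expect_equal(res$band, "good")
})

test_that("concordance bands follow the configured cut points", {
  set.seed(5)
  x <- rnorm(50, 0, 5)
  hi <- icc_agreement(x, x + rnorm(50, 0, 0.1))
  expect_equal(hi$band, "excellent")
  expect_gt(hi$icc, 0.95)
})

test_that("evaluate_cohort on copied ground truth is a fixed point", {
  dir <- withr::local_tempdir()
  man <- tiny_cohort(file.path(dir, "cohort"), n = 4, seed = 31)
  preds <- file.path(dir, "preds")
  dir.create(preds)
  for (i in seq_len(nrow(man)))
    file.copy(man$mask_path[i], file.path(preds, paste0(man$case_id[i], "_pred.nii.gz")))
  res <- suppressWarnings(evaluate_cohort(man, preds))
  expect_equal(res$seg_summary$dsc_mean, 1)
  expect_equal(res$classification$accuracy, 1)
  expect_equal(res$agreement$volume$icc, 1, tolerance = 1e-12)
  expect_equal(nrow(res$per_case), 4)
  expect_length(res$excluded, 0)
})

test_that("eroded predictions lower DSC but keep high volume agreement", {
  dir <- withr::local_tempdir()
  man <- tiny_cohort(file.path(dir, "cohort"), n = 8, seed = 57)
  preds <- file.path(dir, "preds")
  dir.create(preds)
  erode1 <- function(arr) {
    # 6-neighbourhood erosion by one voxel
    out <- arr
    d <- dim(arr)
    sh <- function(a, k, ax) {
      idx <- rep(list(quote(expr = )), 3)
      n <- d[ax]
      src <- pmin(pmax(seq_len(n) + k, 1), n)
      idx[[ax]] <- src
      do.call(`[`, c(list(a), idx))
    }
    for (ax in 1:3) for (k in c(-1, 1)) out <- out * sh(arr, k, ax)
    out
  }
  for (i in seq_len(nrow(man))) {
    gt <- read_mask(man$mask_path[i])
    er <- mask3d(erode1(gt$data), gt$spacing, gt$origin)
    write_volume(er, file.path(preds, paste0(man$case_id[i], "_pred.nii.gz")))
  }
  res <- suppressWarnings(evaluate_cohort(man, preds))
  expect_lt(res$seg_summary$dsc_mean, 1)
  expect_gt(res$seg_summary$dsc_mean, 0.8)
  expect_gt(res$agreement$volume$icc, 0.9)
})

test_that("missing predictions are flagged and excluded from the tables", {
  dir <- withr::local_tempdir()
  man <- tiny_cohort(file.path(dir, "cohort"), n = 4, seed = 13)
  preds <- file.path(dir, "preds")
  dir.create(preds)
  for (i in 1:3)
    file.copy(man$mask_path[i], file.path(preds, paste0(man$case_id[i], "_pred.nii.gz")))
  res <- suppressWarnings(evaluate_cohort(man, preds))
  expect_equal(res$excluded, man$case_id[4])
  expect_equal(nrow(res$per_case), 3)
  # report files are written when out_dir is given
  rep_dir <- file.path(dir, "report")
  res2 <- suppressWarnings(evaluate_cohort(man, preds, out_dir = rep_dir))
  expect_true(file.exists(file.path(rep_dir, "segmetrics.csv")))
  expect_true(file.exists(file.path(rep_dir, "classification.json")))
  expect_true(file.exists(file.path(rep_dir, "agreement.json")))
})
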