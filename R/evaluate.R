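#' Dice similarity coefficient between two masks
#'
#' `DSC = 2|X intersect Y| / (|X| + |Y|)` on foreground voxel sets. If both
#' masks are empty the DSC is defined as 1 (with a warning); if exactly one
#' is empty it is 0.
#'
#' @param x,y Aligned [mask3d()] objects (or plain binary arrays of equal
#'   shape).
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(x, y) {
  ab <- mask_pair_counts(x, y)
  if (ab$nx == 0 && ab$ny == 0) {
    warning("dsc: both masks empty; returning 1 by convention")
    return(1)
  }
  2 * ab$inter / (ab$nx + ab$ny)
}

#' Intersection over union (Jaccard) between two masks
#'
#' `IOU = |X intersect Y| / |X union Y|`, with the same empty-mask
#' conventions as [dsc()]. The two are linked by
#' `DSC = 2 IOU / (1 + IOU)`.
#'
#' @inheritParams dsc
#' @return Scalar in `[0, 1]`.
#' @export
iou <- function(x, y) {
  ab <- mask_pair_counts(x, y)
  if (ab$nx == 0 && ab$ny == 0) {
    warning("iou: both masks empty; returning 1 by convention")
    return(1)
  }
  ab$inter / (ab$nx + ab$ny - ab$inter)
}

mask_pair_counts <- function(x, y) {
  ax <- if (inherits(x, "mask3d")) x$data else x
  ay <- if (inherits(y, "mask3d")) y$data else y
  if (!identical(dim(ax), dim(ay)))
    stop("mask metrics: shape mismatch (", paste(dim(ax), collapse = "x"),
         " vs ", paste(dim(ay), collapse = "x"), ")")
  list(nx = sum(ax == 1), ny = sum(ay == 1), inter = sum(ax == 1 & ay == 1))
}

#' One-vs-rest classification metrics for T stages
#'
#' Builds the confusion matrix (rows = truth, columns = prediction) and the
#' per-class precision, recall (sensitivity), specificity, F1 and support,
#' plus macro (unweighted over classes with defined values) and weighted
#' (support-weighted) averages and the overall accuracy. A class absent
#' from the truth has undefined recall, reported as `NA` with a warning and
#' excluded from the macro average (the count of defined classes is
#' disclosed in the report).
#'
#' @param true_stages,predicted_stages Equal-length vectors/factors with
#'   values in `levels`.
#' @param levels Class labels (default `T1`, `T2`, `T3`).
#' @return An object of class `classification_report`.
#' @export
classification_metrics <- function(true_stages, predicted_stages,
                                   levels = c("T1", "T2", "T3")) {
  if (length(true_stages) == 0)
    stop("classification_metrics: empty input")
  if (length(true_stages) != length(predicted_stages))
    stop("classification_metrics: length mismatch")
  tr <- factor(as.character(true_stages), levels = levels)
  pr <- factor(as.character(predicted_stages), levels = levels)
  if (anyNA(tr) || anyNA(pr))
    stop("classification_metrics: labels outside ", paste(levels, collapse = "/"))
  cm <- table(truth = tr, prediction = pr)
  n <- sum(cm)
  per <- lapply(seq_along(levels), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- n - tp - fp - fn
    support <- tp + fn
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (support > 0) tp / support else NA_real_
    specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    list(class = levels[i], precision = precision, recall = recall,
         specificity = specificity, f1 = f1, support = as.integer(support))
  })
  per_df <- do.call(rbind, lapply(per, function(p) as.data.frame(p, stringsAsFactors = FALSE)))
  if (any(per_df$support == 0))
    warning("classification_metrics: class(es) absent from truth: ",
            paste(per_df$class[per_df$support == 0], collapse = ", "),
            "; their recall is undefined (NA)")
  macro <- function(v) mean(v, na.rm = TRUE)
  wavg <- function(v) {
    ok <- !is.na(v)
    sum(v[ok] * per_df$support[ok]) / sum(per_df$support[ok])
  }
  structure(list(
    confusion = cm,
    per_class = per_df,
    macro_avg = c(precision = macro(per_df$precision), recall = macro(per_df$recall),
                  specificity = macro(per_df$specificity), f1 = macro(per_df$f1)),
    weighted_avg = c(precision = wavg(per_df$precision), recall = wavg(per_df$recall),
                     specificity = wavg(per_df$specificity), f1 = wavg(per_df$f1)),
    accuracy = sum(diag(cm)) / n,
    n = as.integer(n),
    n_defined_classes = sum(per_df$support > 0)),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> accuracy", sprintf("%.4f", x$accuracy),
      "on", x$n, "cases\n")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Two-way random-effects absolute-agreement ICC (single measure)
#'
#' ICC(2,1) from the two-way ANOVA mean squares of an `n x 2` (case by
#' rater) layout:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, `k = 2`.
#' Absolute agreement penalizes systematic offsets between the two
#' measurement methods. The concordance band is `"excellent"` for
#' ICC > 0.95 and `"good"` for 0.80 < ICC <= 0.95.
#'
#' @param values_a,values_b Paired measurements (length `n >= 3`).
#' @return An object of class `icc_result` with fields `icc`, `band`, the
#'   mean squares, and per-rater mean/SD.
#' @export
icc_agreement <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("icc_agreement: length mismatch")
  n <- length(values_a)
  if (n < 3) stop("icc_agreement: need at least 3 paired cases")
  x <- cbind(values_a, values_b)
  if (any(!is.finite(x))) stop("icc_agreement: non-finite values")
  k <- 2
  grand <- mean(x)
  if (sum((x - grand)^2) < 1e-12 * max(1, grand^2))
    stop("icc_agreement: degenerate (zero total variance)")
  si <- rowMeans(x)
  rj <- colMeans(x)
  msr <- k * sum((si - grand)^2) / (n - 1)
  msc <- n * sum((rj - grand)^2) / (k - 1)
  resid <- x - outer(si, rep(1, k)) - outer(rep(1, n), rj) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  band <- if (icc > 0.95) "excellent" else if (icc > 0.80) "good" else "poor-to-moderate"
  structure(list(icc = icc, band = band, model = "ICC(2,1) absolute agreement",
                 msr = msr, msc = msc, mse = mse, n = n,
                 mean_a = mean(values_a), sd_a = stats::sd(values_a),
                 mean_b = mean(values_b), sd_b = stats::sd(values_b)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %.4f (%s), n = %d\n", x$icc, x$band, x$n))
  invisible(x)
}

#' Evaluate a cohort of predicted masks against ground truth
#'
#' For every manifest case with a prediction mask (named
#' `<case_id>_pred.nii.gz` in `pred_dir`): per-case DSC and IOU; geometry
#' and T stage of both predicted and ground-truth masks (largest component
#' each); classification metrics of predicted vs ground-truth stage; and
#' ICC(2,1) agreement of voxel volume and maximal/minimal diameter between
#' prediction and ground truth. Cases without a prediction are flagged,
#' excluded and counted.
#'
#' @param manifest A `cohort_manifest` (see [read_manifest()]).
#' @param pred_dir Directory with prediction masks.
#' @param out_dir Optional output directory; if given, writes
#'   `segmetrics.csv`, `classification.json` and `agreement.json`.
#' @param rules,stage_by Staging configuration (see [quantify_case()]).
#' @return List with `per_case` (data.frame), `seg_summary` (mean/SD of
#'   DSC and IOU), `classification` (a `classification_report`),
#'   `agreement` (named list of `icc_result`), and `excluded` (case ids).
#' @export
evaluate_cohort <- function(manifest, pred_dir, out_dir = NULL,
                            rules = staging_rules(),
                            stage_by = c("maximal", "max3d")) {
  stage_by <- match.arg(stage_by)
  pred_paths <- file.path(pred_dir, paste0(manifest$case_id, "_pred.nii.gz"))
  have <- file.exists(pred_paths)
  excluded <- manifest$case_id[!have]
  if (all(!have)) stop("evaluate_cohort: no prediction masks found in ", pred_dir)
  rows <- vector("list", sum(have))
  ri <- 0
  for (i in which(have)) {
    gt <- read_mask(manifest$mask_path[i])
    pred <- read_mask(pred_paths[i])
    d <- dsc(pred, gt)
    j <- iou(pred, gt)
    qp <- suppressWarnings(quantify_case(NULL_volume(gt), pred, rules = rules, stage_by = stage_by))
    qg <- suppressWarnings(quantify_case(NULL_volume(gt), gt, rules = rules, stage_by = stage_by))
    ri <- ri + 1
    rows[[ri]] <- data.frame(
      case_id = manifest$case_id[i], dsc = d, iou = j,
      pred_stage = as.character(qp$t_stage), gt_stage = as.character(qg$t_stage),
      pred_volume_mm3 = qp$geometry$voxel_volume_mm3,
      gt_volume_mm3 = qg$geometry$voxel_volume_mm3,
      pred_mesh_volume_mm3 = qp$geometry$mesh_volume_mm3,
      gt_mesh_volume_mm3 = qg$geometry$mesh_volume_mm3,
      pred_maximal_mm = qp$geometry$maximal_diameter_mm,
      gt_maximal_mm = qg$geometry$maximal_diameter_mm,
      pred_minimal_mm = qp$geometry$minimal_diameter_mm,
      gt_minimal_mm = qg$geometry$minimal_diameter_mm,
      pred_max3d_mm = qp$geometry$max_3d_diameter_mm,
      gt_max3d_mm = qg$geometry$max_3d_diameter_mm,
      stringsAsFactors = FALSE)
  }
  per_case <- do.call(rbind, rows)
  seg_summary <- list(dsc_mean = mean(per_case$dsc), dsc_sd = stats::sd(per_case$dsc),
                      iou_mean = mean(per_case$iou), iou_sd = stats::sd(per_case$iou))
  classification <- classification_metrics(per_case$gt_stage, per_case$pred_stage)
  icc_or_na <- function(a, b) {
    tryCatch(icc_agreement(a, b), error = function(e) {
      warning("evaluate_cohort: ICC not estimable (", conditionMessage(e), ")")
      structure(list(icc = NA_real_, band = "not estimable",
                     model = "ICC(2,1) absolute agreement",
                     msr = NA_real_, msc = NA_real_, mse = NA_real_,
                     n = length(a),
                     mean_a = mean(a), sd_a = stats::sd(a),
                     mean_b = mean(b), sd_b = stats::sd(b)),
                class = "icc_result")
    })
  }
  agreement <- list(
    volume = icc_or_na(per_case$pred_volume_mm3, per_case$gt_volume_mm3),
    maximal_diameter = icc_or_na(per_case$pred_maximal_mm, per_case$gt_maximal_mm),
    minimal_diameter = icc_or_na(per_case$pred_minimal_mm, per_case$gt_minimal_mm))
  out <- list(per_case = per_case, seg_summary = seg_summary,
              classification = classification, agreement = agreement,
              excluded = excluded)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_case, file.path(out_dir, "segmetrics.csv"), row.names = FALSE)
    cls <- list(confusion = as.data.frame.matrix(unclass(classification$confusion)),
                per_class = classification$per_class,
                macro_avg = as.list(classification$macro_avg),
                weighted_avg = as.list(classification$weighted_avg),
                accuracy = classification$accuracy,
                n = classification$n,
                excluded = excluded)
    jsonlite::write_json(cls, file.path(out_dir, "classification.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    agr <- lapply(agreement, function(a)
      list(icc = a$icc, band = a$band, model = a$model,
           mean_sd_prediction = c(a$mean_a, a$sd_a),
           mean_sd_ground_truth = c(a$mean_b, a$sd_b)))
    jsonlite::write_json(agr, file.path(out_dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# Placeholder intensity volume for geometry-only quantification.
NULL_volume <- function(mask) {
  volume3d(array(0, dim(mask$data)), mask$spacing, mask$origin)
}
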