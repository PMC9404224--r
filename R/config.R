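#' Default pipeline configuration
#'
#' Nested list with one section per stage (`simulate`, `preprocess`,
#' `augment`, `network`, `train`, `infer`, `quantify`, `evaluate`) plus a
#' global `seed` and `output_root`. All values are the package defaults
#' documented on the stage constructors.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    seed = 42L,
    output_root = "segvol_run",
    simulate = list(n_cases = 10L, stage_mix = c(0.23, 0.72, 0.05),
                    core_fraction = 0.15, spacing = c(0.7, 0.7, 1.1),
                    lobulation_amplitude = 0, noise_sd = 20,
                    test_fraction = 0.2),
    preprocess = list(lower_pct = 0.5, upper_pct = 99.5,
                      patch_size = c(96L, 96L, 96L), fg_center_prob = 0.5,
                      samples_per_volume = 1L),
    augment = list(enabled = TRUE, prob = 0.5,
                   zoom_range = c(0.9, 1.1), scale_range = c(0.9, 1.1),
                   shift_range = c(-0.1, 0.1), noise_sd_range = c(0, 0.1),
                   elastic_grid = 4L, elastic_sd = 2),
    network = list(depth = 4L, base_channels = 16L, num_classes = 2L),
    train = list(learning_rate = 1e-3, batch_size = 2L,
                 max_iterations = 300L, checkpoint_every = 100L),
    infer = list(overlap = 0.5, tta = FALSE, tta_angles = c(90L, 180L, 270L),
                 min_component_voxels = 30L, connectivity = 26L,
                 ensemble = TRUE),
    quantify = list(cystic = FALSE, stage_by = "maximal", n_bins = 128L),
    evaluate = list()
  )
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop("load_config: unknown key `", full, "`")
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        stop("load_config: key `", full, "` must be a mapping")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], c(path, key))
    } else if (!is.null(user[[key]])) {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads YAML, fills in every documented default, rejects unknown keys
#' (naming the offending key), and enforces cross-field constraints
#' (patch size divisible by `2^(depth-1)`). An empty file yields exactly
#' [default_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated config list of class `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  check_patch_divisibility(network_spec(depth = cfg$network$depth),
                           as.integer(cfg$preprocess$patch_size))
  if (!cfg$quantify$stage_by %in% c("maximal", "max3d"))
    stop("load_config: quantify.stage_by must be `maximal` or `max3d`")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Serialize a configuration to canonical YAML
#' @param cfg A `pipeline_config` (or plain list).
#' @return A YAML string.
#' @export
dump_config <- function(cfg) yaml::as.yaml(unclass(cfg))

write_run_metadata <- function(dir, cfg, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- c(dump_config(cfg),
            sprintf("package_version: %s", as.character(utils::packageVersion("segvol"))),
            sprintf("run_seed: %d", seed),
            sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  writeLines(meta, file.path(dir, "run_info.yaml"))
}

stage_configs <- function(cfg) {
  list(
    patch = patch_config(cfg$preprocess$patch_size, cfg$preprocess$fg_center_prob,
                         cfg$preprocess$samples_per_volume),
    augment = if (isTRUE(cfg$augment$enabled))
      augment_config(prob = cfg$augment$prob,
                     zoom_range = cfg$augment$zoom_range,
                     scale_range = cfg$augment$scale_range,
                     shift_range = cfg$augment$shift_range,
                     noise_sd_range = cfg$augment$noise_sd_range,
                     elastic_grid = cfg$augment$elastic_grid,
                     elastic_sd = cfg$augment$elastic_sd),
    net = network_spec(depth = cfg$network$depth,
                       base_channels = cfg$network$base_channels,
                       num_classes = cfg$network$num_classes),
    infer = inference_config(patch_size = cfg$preprocess$patch_size,
                             overlap = cfg$infer$overlap, tta = cfg$infer$tta,
                             tta_angles = cfg$infer$tta_angles,
                             min_component_voxels = cfg$infer$min_component_voxels,
                             connectivity = cfg$infer$connectivity)
  )
}

#' Run one pipeline stage (or the whole pipeline)
#'
#' Commands: `simulate` writes train/test phantom cohorts under
#' `<output_root>/cohort_{train,test}`; `train` fits the network and
#' saves checkpoints + a training log under `<output_root>/run`;
#' `predict` writes `<case>_pred.nii.gz` masks under
#' `<output_root>/preds`; `quantify` writes per-case geometry to
#' `<output_root>/quantify/geometry.csv`; `evaluate` writes the metric
#' reports under `<output_root>/report`; `end-to-end` chains all five.
#' Every stage directory receives a `run_info.yaml` with the resolved
#' configuration, package version and seed.
#'
#' @param command One of `simulate`, `train`, `predict`, `quantify`,
#'   `evaluate`, `end-to-end`.
#' @param cfg A `pipeline_config` from [load_config()].
#' @param verbose Log progress.
#' @return Invisibly, a list of produced artifact paths.
#' @export
run_pipeline <- function(command = c("end-to-end", "simulate", "train", "predict",
                                     "quantify", "evaluate"),
                         cfg = load_config(), verbose = TRUE) {
  command <- match.arg(command)
  root <- cfg$output_root
  seeds <- derive_seeds(cfg$seed, 4L)
  say <- function(...) if (verbose) message(sprintf(...))
  sc <- stage_configs(cfg)
  paths <- list(train_dir = file.path(root, "cohort_train"),
                test_dir = file.path(root, "cohort_test"),
                run_dir = file.path(root, "run"),
                pred_dir = file.path(root, "preds"),
                quant_dir = file.path(root, "quantify"),
                report_dir = file.path(root, "report"))

  do_simulate <- function() {
    n_test <- max(1L, round(cfg$simulate$n_cases * cfg$simulate$test_fraction))
    n_train <- max(1L, cfg$simulate$n_cases - n_test)
    say("simulate: %d training + %d test phantoms", n_train, n_test)
    generate_cohort(paths$train_dir, n_train,
                    stage_mix = cfg$simulate$stage_mix,
                    core_fraction = cfg$simulate$core_fraction,
                    seed = seeds[1], spacing_mm = cfg$simulate$spacing,
                    lobulation_amplitude = cfg$simulate$lobulation_amplitude,
                    noise_sd = cfg$simulate$noise_sd,
                    stage_by = cfg$quantify$stage_by)
    generate_cohort(paths$test_dir, n_test,
                    stage_mix = cfg$simulate$stage_mix,
                    core_fraction = cfg$simulate$core_fraction,
                    seed = seeds[2], spacing_mm = cfg$simulate$spacing,
                    lobulation_amplitude = cfg$simulate$lobulation_amplitude,
                    noise_sd = cfg$simulate$noise_sd,
                    stage_by = cfg$quantify$stage_by)
    write_run_metadata(paths$train_dir, cfg, seeds[1])
    write_run_metadata(paths$test_dir, cfg, seeds[2])
  }

  do_train <- function() {
    manifest <- read_manifest(file.path(paths$train_dir, "manifest.csv"))
    say("train: %d cases, %d iterations", nrow(manifest), cfg$train$max_iterations)
    tc <- train_config(learning_rate = cfg$train$learning_rate,
                       batch_size = cfg$train$batch_size,
                       max_iterations = cfg$train$max_iterations,
                       checkpoint_every = cfg$train$checkpoint_every,
                       seed = seeds[3])
    res <- train_model(manifest, sc$net, tc, sc$patch, sc$augment)
    dir.create(paths$run_dir, recursive = TRUE, showWarnings = FALSE)
    for (ck in res$checkpoints)
      save_checkpoint(ck, file.path(paths$run_dir,
                                    sprintf("checkpoint_%05d.rds", ck$iteration)))
    utils::write.csv(res$history, file.path(paths$run_dir, "training_log.csv"),
                     row.names = FALSE)
    write_run_metadata(paths$run_dir, cfg, seeds[3])
    res
  }

  do_predict <- function() {
    manifest <- read_manifest(file.path(paths$test_dir, "manifest.csv"))
    cks <- sort(list.files(paths$run_dir, "^checkpoint_.*\\.rds$", full.names = TRUE))
    if (length(cks) == 0) stop("run_pipeline: no checkpoints in ", paths$run_dir,
                               "; run the train stage first")
    models <- if (isTRUE(cfg$infer$ensemble)) as.list(cks) else
      list(cks[length(cks)])
    say("predict: %d cases, %d checkpoint(s), tta = %s",
        nrow(manifest), length(models), cfg$infer$tta)
    dir.create(paths$pred_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      vol <- read_volume(manifest$image_path[i])
      pred <- predict_mask(models, vol, sc$infer)
      write_volume(pred$mask, file.path(paths$pred_dir,
                                        paste0(manifest$case_id[i], "_pred.nii.gz")))
    }
    write_run_metadata(paths$pred_dir, cfg, seeds[4])
  }

  do_quantify <- function() {
    manifest <- read_manifest(file.path(paths$test_dir, "manifest.csv"))
    dir.create(paths$quant_dir, recursive = TRUE, showWarnings = FALSE)
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
      pred_path <- file.path(paths$pred_dir, paste0(manifest$case_id[i], "_pred.nii.gz"))
      mask <- if (file.exists(pred_path)) read_mask(pred_path) else
        read_mask(manifest$mask_path[i])
      vol <- read_volume(manifest$image_path[i])
      q <- suppressWarnings(quantify_case(vol, mask, cystic = cfg$quantify$cystic,
                                          stage_by = cfg$quantify$stage_by))
      data.frame(case_id = manifest$case_id[i],
                 max_3d_diameter_mm = q$geometry$max_3d_diameter_mm,
                 mesh_volume_mm3 = q$geometry$mesh_volume_mm3,
                 maximal_diameter_mm = q$geometry$maximal_diameter_mm,
                 minimal_diameter_mm = q$geometry$minimal_diameter_mm,
                 voxel_volume_mm3 = q$geometry$voxel_volume_mm3,
                 t_stage = as.character(q$t_stage),
                 cyst_volume_mm3 = if (!is.null(q$cystic)) q$cystic$cyst_volume_mm3 else NA,
                 stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows),
                     file.path(paths$quant_dir, "geometry.csv"), row.names = FALSE)
    write_run_metadata(paths$quant_dir, cfg, cfg$seed)
  }

  do_evaluate <- function() {
    manifest <- read_manifest(file.path(paths$test_dir, "manifest.csv"))
    say("evaluate: %d cases", nrow(manifest))
    res <- evaluate_cohort(manifest, paths$pred_dir, out_dir = paths$report_dir,
                           stage_by = cfg$quantify$stage_by)
    write_run_metadata(paths$report_dir, cfg, cfg$seed)
    res
  }

  switch(command,
         "simulate" = do_simulate(),
         "train" = do_train(),
         "predict" = do_predict(),
         "quantify" = do_quantify(),
         "evaluate" = do_evaluate(),
         "end-to-end" = {
           do_simulate(); do_train(); do_predict(); do_quantify(); do_evaluate()
         })
  invisible(paths)
}
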