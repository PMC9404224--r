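#' Training configuration
#'
#' The optimizer is Adam. Training is patch-based: an "iteration" is one
#' optimizer step on `batch_size` freshly sampled (and augmented) patches;
#' there is no dataset-pass epoch. Defaults (learning rate 1e-3, batch 2)
#' are pragmatic CPU-scale choices and fully configurable.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Patches per optimizer step (>= 1).
#' @param max_iterations Total optimizer steps.
#' @param checkpoint_every Snapshot interval in iterations (the final state
#'   is always snapshot).
#' @param seed Seed controlling initialization, sampling and augmentation.
#' @param beta1,beta2,adam_eps Adam moment decays and stabilizer.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 2L,
                         max_iterations = 300L, checkpoint_every = 100L,
                         seed = 42L, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8) {
  if (learning_rate <= 0) stop("train_config: learning_rate must be > 0")
  if (batch_size < 1) stop("train_config: batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations),
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed), beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps),
            class = "train_config")
}

# ---- nested-list parameter trees -------------------------------------------

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

adam_state <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) cfg$beta1 * m + (1 - cfg$beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) cfg$beta2 * v + (1 - cfg$beta2) * g * g,
                       state$v, grads)
  c1 <- 1 - cfg$beta1^state$t
  c2 <- 1 - cfg$beta2^state$t
  upd <- tree_map2(function(m, v) cfg$learning_rate * (m / c1) / (sqrt(v / c2) + cfg$adam_eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

# ---- training loop ---------------------------------------------------------

load_training_case <- function(image_path, mask_path, target_spacing = NULL,
                               lower_pct = 0.5, upper_pct = 99.5) {
  vol <- read_volume(image_path)
  mask <- read_mask(mask_path)
  validate_pair(vol, mask)
  if (!is.null(target_spacing) &&
      any(abs(vol$spacing - target_spacing) / target_spacing > 1e-4)) {
    vol <- resample_volume(vol, target_spacing, "continuous")
    mask <- resample_volume(mask, target_spacing, "nearest")
    # resampling both to one grid keeps shapes aligned by construction
  }
  norm <- clamp_normalize(vol, lower_pct, upper_pct)
  list(vol = norm$volume, mask = mask, norm_params = norm$params)
}

#' Train a Res-UNet on a cohort
#'
#' Full training loop: cases are respaced to the cohort mean spacing
#' (unless `target_spacing` overrides it), normalized per case
#' (percentile-clamped z-score), and patches with balanced
#' foreground/background centres are sampled, augmented and fed through
#' the network; the combined Dice/cross-entropy loss is minimized with
#' Adam. Deterministic for a fixed `train_cfg$seed`.
#'
#' @param manifest A `cohort_manifest` (see [read_manifest()]).
#' @param net_spec A [network_spec()].
#' @param train_cfg A [train_config()].
#' @param patch_cfg A [patch_config()].
#' @param augment_cfg An [augment_config()] (or `NULL` to disable
#'   augmentation).
#' @param loss_cfg A [loss_config()].
#' @param target_spacing Spacing to resample all cases to; `NULL` uses
#'   [compute_target_spacing()] on the manifest.
#' @param verbose Print a progress line every 50 iterations.
#' @return List with `model` (final `segvol_model`), `checkpoints` (list
#'   of `segvol_checkpoint`), `history` (data.frame: iteration, loss,
#'   dice_loss, ce_loss), and `target_spacing`.
#' @export
train_model <- function(manifest, net_spec = network_spec(),
                        train_cfg = train_config(),
                        patch_cfg = patch_config(),
                        augment_cfg = augment_config(),
                        loss_cfg = loss_config(),
                        target_spacing = NULL,
                        verbose = FALSE) {
  if (!is.data.frame(manifest) || nrow(manifest) < 1)
    stop("train_model: empty manifest")
  check_patch_divisibility(net_spec, patch_cfg$patch_size)
  if (is.null(target_spacing)) target_spacing <- compute_target_spacing(manifest)
  cases <- lapply(seq_len(nrow(manifest)), function(i)
    load_training_case(manifest$image_path[i], manifest$mask_path[i], target_spacing))
  set.seed(train_cfg$seed)
  model <- build_network(net_spec)
  state <- adam_state(model$params)
  hist <- matrix(NA_real_, nrow = train_cfg$max_iterations, ncol = 3,
                 dimnames = list(NULL, c("loss", "dice_loss", "ce_loss")))
  checkpoints <- list()
  snapshot <- function(iter) {
    structure(list(params = model$params, spec = net_spec, iteration = iter,
                   train_config = train_cfg, patch_config = patch_cfg,
                   target_spacing = target_spacing,
                   normalization = "clamp_z(0.5,99.5)"),
              class = "segvol_checkpoint")
  }
  for (iter in seq_len(train_cfg$max_iterations)) {
    gsum <- NULL
    lsum <- c(0, 0, 0)
    for (b in seq_len(train_cfg$batch_size)) {
      ci <- sample.int(length(cases), 1L)
      smp <- sample_patches(cases[[ci]]$vol, cases[[ci]]$mask, patch_cfg,
                            case_id = manifest$case_id[ci])[[1]]
      if (!is.null(augment_cfg)) smp <- augment_patch(smp, augment_cfg)
      fwd <- forward_network(model, smp$image)
      lg <- combined_loss_grad(fwd$scores, smp$label, loss_cfg)
      if (!is.finite(lg$loss))
        stop("train_model: non-finite loss at iteration ", iter,
             " (case ", manifest$case_id[ci], "); try a lower learning rate")
      g <- backward_network(model, fwd, lg$dscores)
      gsum <- if (is.null(gsum)) g else tree_map2(`+`, gsum, g)
      lsum <- lsum + c(lg$loss, lg$dice, lg$ce)
    }
    gmean <- tree_map(function(x) x / train_cfg$batch_size, gsum)
    st <- adam_step(model$params, gmean, state, train_cfg)
    model$params <- st$params
    state <- st$state
    hist[iter, ] <- lsum / train_cfg$batch_size
    if (train_cfg$checkpoint_every > 0 && iter %% train_cfg$checkpoint_every == 0L)
      checkpoints[[length(checkpoints) + 1L]] <- snapshot(iter)
    if (verbose && iter %% 50L == 0L)
      message(sprintf("iter %d: loss %.4f (dice %.4f, ce %.4f)",
                      iter, hist[iter, 1], hist[iter, 2], hist[iter, 3]))
  }
  if (length(checkpoints) == 0L ||
      checkpoints[[length(checkpoints)]]$iteration != train_cfg$max_iterations)
    checkpoints[[length(checkpoints) + 1L]] <- snapshot(train_cfg$max_iterations)
  history <- data.frame(iteration = seq_len(train_cfg$max_iterations), hist)
  list(model = model, checkpoints = checkpoints, history = history,
       target_spacing = target_spacing)
}

#' Save / load a training checkpoint
#'
#' Checkpoints are self-describing: parameters plus the network spec,
#' iteration tag, training configuration and preprocessing target spacing.
#'
#' @param ck A `segvol_checkpoint`.
#' @param path File path (`.rds`).
#' @return `path` (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(ck, path) {
  stopifnot(inherits(ck, "segvol_checkpoint"))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "segvol_checkpoint"))
    stop("load_checkpoint: not a segvol checkpoint: ", path)
  ck
}

# Accept a model, a checkpoint, or a path to one.
as_segvol_model <- function(x) {
  if (inherits(x, "segvol_model")) return(x)
  if (is.character(x)) x <- load_checkpoint(x)
  if (inherits(x, "segvol_checkpoint"))
    return(structure(list(spec = x$spec, params = x$params), class = "segvol_model"))
  stop("expected a segvol_model, segvol_checkpoint, or checkpoint path")
}
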