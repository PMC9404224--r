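#' Res-UNet architecture specification
#'
#' Encoder-decoder with residual units in the encoder and skip connections
#' to the decoder. Each residual unit is two convolution -> instance-norm
#' -> ReLU stages whose input joins the output through an addition (with a
#' projected identity path on channel or stride mismatch). Downsampling is
#' by stride-2 convolution, upsampling by stride-2 transposed convolution;
#' the head is a 1x1x1 convolution to `num_classes` score maps at input
#' resolution.
#'
#' @param input_channels Number of image channels (1 for subtraction MRI).
#' @param num_classes Output classes (2: background/lesion).
#' @param depth Number of resolution levels (>= 2).
#' @param base_channels Channels at the finest level, doubled per level.
#' @param residual_blocks_per_level Residual units per level (currently 1).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(input_channels = 1L, num_classes = 2L, depth = 4L,
                         base_channels = 16L, residual_blocks_per_level = 1L) {
  depth <- as.integer(depth)
  if (depth < 2L) stop("network_spec: depth must be >= 2")
  if (base_channels < 1L) stop("network_spec: base_channels must be >= 1")
  if (residual_blocks_per_level != 1L)
    stop("network_spec: only 1 residual block per level is supported")
  structure(list(input_channels = as.integer(input_channels),
                 num_classes = as.integer(num_classes),
                 depth = depth, base_channels = as.integer(base_channels),
                 residual_blocks_per_level = 1L),
            class = "network_spec")
}

#' Check that a patch size is compatible with a network depth
#'
#' Each spatial dimension must be divisible by `2^(depth-1)` so the
#' down/up-sampling path reproduces the input shape.
#'
#' @param spec A [network_spec()].
#' @param patch_size Integer length 3.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
check_patch_divisibility <- function(spec, patch_size) {
  f <- 2L^(spec$depth - 1L)
  if (any(patch_size %% f != 0L))
    stop("patch size (", paste(patch_size, collapse = "x"),
         ") must be divisible by 2^(depth-1) = ", f)
  invisible(TRUE)
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

init_resunit <- function(cin, cout, stride) {
  p <- list(W1 = he_init(cout, cin * 27, cin * 27),
            g1 = rep(1, cout), b1 = rep(0, cout),
            W2 = he_init(cout, cout * 27, cout * 27),
            g2 = rep(1, cout), b2 = rep(0, cout))
  if (cin != cout || stride != 1)
    p <- c(p, list(Wp = he_init(cout, cin, cin),
                   gp = rep(1, cout), bp = rep(0, cout)))
  p
}

#' Build a Res-UNet model
#'
#' Initializes all parameters (He-normal weights, unit-gain instance
#' norms). Channel counts are `base_channels * 2^(level-1)`.
#'
#' @param spec A [network_spec()].
#' @return An object of class `segvol_model` holding `spec` and `params`.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  ch <- spec$base_channels * 2L^(seq_len(spec$depth) - 1L)
  enc <- vector("list", spec$depth)
  enc[[1]] <- init_resunit(spec$input_channels, ch[1], 1L)
  for (l in seq(2, spec$depth))
    enc[[l]] <- init_resunit(ch[l - 1], ch[l], 2L)
  up <- dec <- vector("list", spec$depth - 1L)
  for (l in seq(spec$depth - 1L, 1L)) {
    up[[l]] <- list(W = he_init(ch[l], ch[l + 1] * 8, ch[l + 1] * 8),
                    b = rep(0, ch[l]))
    dec[[l]] <- init_resunit(2L * ch[l], ch[l], 1L)
  }
  head <- list(W = he_init(spec$num_classes, ch[1], ch[1]),
               b = rep(0, spec$num_classes))
  structure(list(spec = spec,
                 params = list(enc = enc, up = up, dec = dec, head = head)),
            class = "segvol_model")
}

#' Number of trainable parameters of a model
#' @param model A `segvol_model`.
#' @return Integer count.
#' @export
count_params <- function(model) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(model$params)
  n
}

# ---- layer forward/backward (feature maps are C x N matrices) --------------

# Stride-1 convolutions use the padded shift-and-GEMM kernel (no im2col
# buffer); strided convolutions keep the im2col path, whose buffer scales
# with the (8x smaller) output grid.
conv3_fwd <- function(x, dims, W, b, stride) {
  if (stride == 1L) conv3s1_fwd_cpp(x, dims, W, b)
  else conv3_fwd_cpp(x, dims, W, b, stride)
}

conv3_bwd <- function(x, dims, W, stride, dY) {
  if (stride == 1L) conv3s1_bwd_cpp(x, dims, W, dY)
  else conv3_bwd_cpp(x, dims, W, stride, dY)
}

IN_EPS <- 1e-5

in_fwd <- function(x, g, b, relu = FALSE) in_fwd_cpp(x, g, b, IN_EPS, relu)

in_bwd <- function(dy, cache, g) in_bwd_cpp(dy, cache$xhat, cache$istd, g)

subsample_cols <- function(dims, stride) {
  if (stride == 1) return(NULL)
  ix <- seq(0, dims[1] - 1, by = stride)
  iy <- seq(0, dims[2] - 1, by = stride)
  iz <- seq(0, dims[3] - 1, by = stride)
  idx <- outer(outer(ix, iy * dims[1], "+"), iz * dims[1] * dims[2], "+")
  as.integer(idx) + 1L
}

resunit_fwd <- function(x, dims, p, stride) {
  zero1 <- rep(0, nrow(p$W1))
  c1 <- conv3_fwd(x, dims, p$W1, zero1, stride)
  n1 <- in_fwd(c1$Y, p$g1, p$b1, relu = TRUE)
  r1 <- n1$y
  c2 <- conv3_fwd(r1, c1$odim, p$W2, zero1, 1L)
  n2 <- in_fwd(c2$Y, p$g2, p$b2)
  if (!is.null(p$Wp)) {
    idx <- subsample_cols(dims, stride)
    sx <- if (is.null(idx)) x else x[, idx, drop = FALSE]
    ns <- in_fwd(p$Wp %*% sx, p$gp, p$bp)
    sk <- ns$y
  } else {
    idx <- NULL; sx <- NULL; ns <- NULL
    sk <- x
  }
  pre <- n2$y + sk
  y <- pre * (pre > 0)
  list(y = y, odim = c1$odim,
       cache = list(x = x, dims = dims, odim = c1$odim, n1 = n1, r1 = r1,
                    n2 = n2, ns = ns, sx = sx, idx = idx, act = pre > 0))
}

resunit_bwd <- function(dy, p, cache, stride) {
  dy <- dy * cache$act
  b2 <- in_bwd(dy, cache$n2, p$g2)
  cv2 <- conv3_bwd(cache$r1, cache$odim, p$W2, 1L, b2$dx)
  dr1 <- cv2$dX * (cache$r1 > 0)
  b1 <- in_bwd(dr1, cache$n1, p$g1)
  cv1 <- conv3_bwd(cache$x, cache$dims, p$W1, stride, b1$dx)
  dx <- cv1$dX
  g <- list(W1 = cv1$dW, g1 = b1$dg, b1 = b1$db,
            W2 = cv2$dW, g2 = b2$dg, b2 = b2$db)
  if (!is.null(p$Wp)) {
    bs <- in_bwd(dy, cache$ns, p$gp)
    g$Wp <- bs$dx %*% t(cache$sx)
    g$gp <- bs$dg
    g$bp <- bs$db
    dsx <- crossprod(p$Wp, bs$dx)
    if (is.null(cache$idx)) {
      dx <- dx + dsx
    } else {
      dx[, cache$idx] <- dx[, cache$idx] + dsx
    }
  } else {
    dx <- dx + dy
  }
  list(dx = dx, grads = g)
}

#' Forward pass of a Res-UNet on one patch
#'
#' @param model A `segvol_model`.
#' @param x 3D array (or `1 x N` matrix) of input intensities.
#' @param dims Spatial dimensions when `x` is a matrix.
#' @return `list(scores, dims, cache)`: `scores` is a
#'   `num_classes x nvoxels` matrix of raw class scores at input
#'   resolution; `cache` feeds [backward_network()].
#' @export
forward_network <- function(model, x, dims = NULL) {
  stopifnot(inherits(model, "segvol_model"))
  if (is.array(x) && length(dim(x)) == 3L) {
    dims <- dim(x)
    x <- matrix(as.double(x), nrow = 1)
  }
  check_patch_divisibility(model$spec, dims)
  p <- model$params
  depth <- model$spec$depth
  encs <- vector("list", depth)
  cur <- x; curd <- dims
  for (l in seq_len(depth)) {
    r <- resunit_fwd(cur, curd, p$enc[[l]], if (l == 1L) 1L else 2L)
    encs[[l]] <- r
    cur <- r$y; curd <- r$odim
  }
  decs <- vector("list", depth - 1L)
  ups <- vector("list", depth - 1L)
  for (l in seq(depth - 1L, 1L)) {
    u <- upconv2_fwd_cpp(cur, curd, p$up[[l]]$W, p$up[[l]]$b)
    ups[[l]] <- list(xin = cur, dims_in = curd)
    skip <- encs[[l]]$y
    cat_x <- rbind(u$Y, skip)
    r <- resunit_fwd(cat_x, u$odim, p$dec[[l]], 1L)
    decs[[l]] <- r
    cur <- r$y; curd <- r$odim
  }
  scores <- p$head$W %*% cur + p$head$b
  list(scores = scores, dims = curd,
       cache = list(encs = encs, ups = ups, decs = decs, top = cur, x = x))
}

#' Backward pass of a Res-UNet
#'
#' @param model A `segvol_model`.
#' @param fwd The result of [forward_network()].
#' @param dscores Gradient of the loss w.r.t. the raw scores
#'   (`num_classes x nvoxels`).
#' @return Nested gradient list mirroring `model$params`.
#' @export
backward_network <- function(model, fwd, dscores) {
  p <- model$params
  depth <- model$spec$depth
  cache <- fwd$cache
  grads <- list(enc = vector("list", depth),
                up = vector("list", depth - 1L),
                dec = vector("list", depth - 1L),
                head = list(W = dscores %*% t(cache$top),
                            b = rowSums(dscores)))
  dcur <- crossprod(p$head$W, dscores)
  denc_extra <- vector("list", depth)  # gradient arriving at encoder outputs via skips
  for (l in seq_len(depth - 1L)) {
    r <- cache$decs[[l]]
    bw <- resunit_bwd(dcur, p$dec[[l]], r$cache, 1L)
    grads$dec[[l]] <- bw$grads
    cup <- nrow(p$up[[l]]$W)
    dcat <- bw$dx
    dup <- dcat[seq_len(cup), , drop = FALSE]
    dskip <- dcat[-seq_len(cup), , drop = FALSE]
    denc_extra[[l]] <- dskip
    ub <- upconv2_bwd_cpp(cache$ups[[l]]$xin, cache$ups[[l]]$dims_in,
                          p$up[[l]]$W, dup)
    grads$up[[l]] <- list(W = ub$dW, b = ub$db)
    dcur <- ub$dX
  }
  # dcur is now the gradient at the bottleneck encoder output
  for (l in seq(depth, 1L)) {
    if (l < depth && !is.null(denc_extra[[l]]))
      dcur <- dcur + denc_extra[[l]]
    r <- cache$encs[[l]]
    bw <- resunit_bwd(dcur, p$enc[[l]], r$cache, if (l == 1L) 1L else 2L)
    grads$enc[[l]] <- bw$grads
    dcur <- bw$dx
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- losses ----------------------------------------------------------------

#' Loss configuration
#'
#' Weights of the combined objective
#' `loss = dice_weight * DSC_loss + ce_weight * cross_entropy_loss`
#' (defaults 0.5/0.5) and the smoothing term of the soft Dice ratio that
#' guards empty-target patches against division by zero.
#'
#' @param dice_weight,ce_weight Non-negative weights.
#' @param smooth Smoothing term of the Dice ratio.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(dice_weight = 0.5, ce_weight = 0.5, smooth = 1e-5) {
  if (dice_weight < 0 || ce_weight < 0)
    stop("loss_config: weights must be >= 0")
  structure(list(dice_weight = dice_weight, ce_weight = ce_weight,
                 smooth = smooth), class = "loss_config")
}

as_class_matrix <- function(x, what) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (!is.null(d) && length(d) == 4L) return(matrix(x, nrow = d[1]))
  stop(what, ": expected a K x N matrix or K x nx x ny x nz array")
}

as_target_vector <- function(target) {
  y <- as.double(target)
  if (!all(y %in% c(0, 1))) stop("target must be binary")
  y
}

col_max <- function(scores) {
  m <- scores[1, ]
  for (i in seq_len(nrow(scores))[-1]) m <- pmax(m, scores[i, ])
  m
}

softmax_probs <- function(scores) {
  e <- exp(sweep(scores, 2, col_max(scores)))
  sweep(e, 2, colSums(e), "/")
}

log_softmax <- function(scores) {
  s <- sweep(scores, 2, col_max(scores))
  sweep(s, 2, log(colSums(exp(s))))
}

#' Soft Dice loss on the foreground channel
#'
#' `1 - (2 sum(p y) + s) / (sum(p) + sum(y) + s)` where `p` is the
#' softmax foreground probability (last class row) and `y` the binary
#' target; batch-pooled over all supplied voxels. For hard 0/1
#' predictions this is `1 - DSC` (as `s -> 0`).
#'
#' @param probs Softmax-normalized class probabilities, `K x N` matrix or
#'   `K x nx x ny x nz` array.
#' @param target Binary target mask (array or vector of length N).
#' @param cfg A [loss_config()] (only `smooth` is used).
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(probs, target, cfg = loss_config()) {
  p <- as_class_matrix(probs, "dice_loss")
  y <- as_target_vector(target)
  if (ncol(p) != length(y)) stop("dice_loss: shape mismatch")
  p1 <- p[nrow(p), ]
  s <- cfg$smooth
  1 - (2 * sum(p1 * y) + s) / (sum(p1) + sum(y) + s)
}

#' Cross-entropy loss from raw class scores
#'
#' Mean over voxels of the negative log softmax probability of the true
#' class (standard per-voxel multiclass cross-entropy; the foreground is
#' the last class row).
#'
#' @param scores Raw class scores, `K x N` matrix or `K x nx x ny x nz`
#'   array.
#' @param target Binary target mask.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(scores, target) {
  s <- as_class_matrix(scores, "cross_entropy_loss")
  y <- as_target_vector(target)
  if (ncol(s) != length(y)) stop("cross_entropy_loss: shape mismatch")
  lp <- log_softmax(s)
  k <- nrow(s)
  -mean(ifelse(y == 1, lp[k, ], lp[1, ]))
}

#' Combined Dice + cross-entropy loss
#'
#' `dice_weight * DSC_loss + ce_weight * cross_entropy_loss` evaluated
#' from raw scores (softmax applied internally).
#'
#' @inheritParams cross_entropy_loss
#' @param cfg A [loss_config()].
#' @return Scalar; attributes `dice` and `ce` carry the components.
#' @export
combined_loss <- function(scores, target, cfg = loss_config()) {
  s <- as_class_matrix(scores, "combined_loss")
  y <- as_target_vector(target)
  p <- softmax_probs(s)
  ld <- dice_loss(p, y, cfg)
  lc <- cross_entropy_loss(s, y)
  structure(cfg$dice_weight * ld + cfg$ce_weight * lc, dice = ld, ce = lc)
}

# Loss value + gradient w.r.t. raw scores (two-class case used in training).
combined_loss_grad <- function(scores, target, cfg) {
  y <- as_target_vector(target)
  n <- length(y)
  p <- softmax_probs(scores)
  k <- nrow(scores)
  lp <- log_softmax(scores)
  lc <- -mean(ifelse(y == 1, lp[k, ], lp[1, ]))
  p1 <- p[k, ]
  s <- cfg$smooth
  A <- 2 * sum(p1 * y) + s
  B <- sum(p1) + sum(y) + s
  ld <- 1 - A / B
  # d(dice)/dp1, then through softmax; CE gradient is (p - onehot)/n
  gd_p1 <- (A - 2 * y * B) / B^2
  gmat <- matrix(0, nrow = k, ncol = n)
  gmat[k, ] <- gd_p1
  inner <- colSums(gmat * p)
  d_dice <- p * sweep(gmat, 2, inner)
  onehot <- matrix(0, nrow = k, ncol = n)
  onehot[k, y == 1] <- 1
  onehot[1, y == 0] <- 1
  d_ce <- (p - onehot) / n
  list(loss = cfg$dice_weight * ld + cfg$ce_weight * lc,
       dice = ld, ce = lc,
       dscores = cfg$dice_weight * d_dice + cfg$ce_weight * d_ce)
}
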