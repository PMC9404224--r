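# Shared fixtures: small phantoms and independent mini-oracles used across
# test files. Everything is generated in code; nothing is stored on disk.

# A clean digitized sphere: radius 10 mm, 1 mm spacing, no noise.
sphere_phantom <- function(noise_sd = 0, seed = 1, core = NULL) {
  generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
                                spacing_mm = c(1, 1, 1),
                                semi_axes_mm = c(10, 10, 10),
                                noise_sd = noise_sd, core = core,
                                seed = seed))
}

# Random small binary mask with n_fg foreground voxels on a dims grid.
random_mask <- function(dims, n_fg, spacing = c(1, 1, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arr <- array(0L, dims)
  arr[sample(prod(dims), n_fg)] <- 1L
  mask3d(arr, spacing)
}

# Independent flood-fill component labelling (pure R, queue-based); the
# oracle for the compiled union of BFS labelling.
oracle_label <- function(arr, connectivity = 26) {
  dims <- dim(arr)
  nb <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nb <- nb[!(nb$dx == 0 & nb$dy == 0 & nb$dz == 0), ]
  if (connectivity == 6) nb <- nb[abs(nb$dx) + abs(nb$dy) + abs(nb$dz) == 1, ]
  lab <- array(0L, dims)
  nxt <- 0L
  for (s in which(arr == 1L)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      v0 <- v - 1L
      x <- v0 %% dims[1]; y <- (v0 %/% dims[1]) %% dims[2]; z <- v0 %/% (dims[1] * dims[2])
      for (r in seq_len(nrow(nb))) {
        xx <- x + nb$dx[r]; yy <- y + nb$dy[r]; zz <- z + nb$dz[r]
        if (xx < 0 || xx >= dims[1] || yy < 0 || yy >= dims[2] || zz < 0 || zz >= dims[3]) next
        w <- xx + dims[1] * (yy + dims[2] * zz) + 1L
        if (arr[w] == 1L && lab[w] == 0L) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# Brute-force Otsu oracle: minimize the within-class variance of the
# histogram (same bins/midpoints, opposite criterion route; ties resolve
# to the plateau midpoint, matching the documented convention).
oracle_otsu <- function(x, n_bins = 128) {
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  wcv <- rep(Inf, n_bins - 1)
  for (k in 1:(n_bins - 1)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts[(k + 1):n_bins])
    if (n0 == 0 || n1 == 0) next
    w <- counts[1:k] / n0
    v0 <- sum(w * mids[1:k]^2) - sum(w * mids[1:k])^2
    w <- counts[(k + 1):n_bins] / n1
    v1 <- sum(w * mids[(k + 1):n_bins]^2) - sum(w * mids[(k + 1):n_bins])^2
    wcv[k] <- (n0 * v0 + n1 * v1) / (n0 + n1)
  }
  best <- min(wcv)
  ties <- which(wcv <= best + 1e-9 * max(1, abs(best)))
  edges[ties[ceiling(length(ties) / 2)] + 1]
}

# Write a volume/mask pair plus manifest row(s) for quick cohort tests.
tiny_cohort <- function(dir, n = 3, seed = 9, spacing = c(1, 1, 1), ...) {
  generate_cohort(dir, n, seed = seed, spacing_mm = spacing, ...)
}
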