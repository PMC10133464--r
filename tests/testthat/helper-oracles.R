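# Independent scalar-loop oracles used to cross-check the vectorized loss
# and metric implementations. Deliberately written in the most naive style
# possible (explicit loops over voxels/classes) so they share no code path
# with the implementation.

oracle_dice <- function(probs, onehot, smooth = 1e-5) {
  M <- dim(probs)[length(dim(probs))]
  pm <- matrix(probs, ncol = M)
  ym <- matrix(onehot, ncol = M)
  acc <- 0
  for (cl in seq_len(M)) {
    num <- 0; dp <- 0; dy <- 0
    for (v in seq_len(nrow(pm))) {
      num <- num + 2 * pm[v, cl] * ym[v, cl]
      dp <- dp + pm[v, cl]; dy <- dy + ym[v, cl]
    }
    acc <- acc + (num + smooth) / (dp + dy + smooth)
  }
  1 - acc / M
}

oracle_ce <- function(probs, onehot, clip = 1e-7) {
  M <- dim(probs)[length(dim(probs))]
  pm <- matrix(probs, ncol = M)
  ym <- matrix(onehot, ncol = M)
  tot <- 0
  for (v in seq_len(nrow(pm)))
    for (cl in seq_len(M)) {
      p <- min(max(pm[v, cl], clip), 1 - clip)
      tot <- tot - ym[v, cl] * log(p)
    }
  tot / (M * nrow(pm))
}

oracle_mse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  s / length(a)
}

oracle_bce <- function(scores, target) {
  s <- 0
  for (i in seq_along(scores)) {
    p <- 1 / (1 + exp(-scores[i]))
    s <- s - (target * log(p) + (1 - target) * log(1 - p))
  }
  s / length(scores)
}

# coordinate-tracking oracle for a single 90-degree CCW rotation of (H, W):
# pixel (i, j) of the input lands at (W + 1 - j, i) in the output.
oracle_rot90_map <- function(mat) {
  H <- nrow(mat); W <- ncol(mat)
  out <- matrix(NA_real_, W, H)
  for (i in seq_len(H))
    for (j in seq_len(W))
      out[W + 1 - j, i] <- mat[i, j]
  out
}

# brute-force symmetric Hausdorff over explicit point matrices
oracle_hausdorff <- function(A, B, variant = "max") {
  mins_ab <- numeric(nrow(A)); mins_ba <- numeric(nrow(B))
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    mins_ab[i] <- best
  }
  for (j in seq_len(nrow(B))) {
    best <- Inf
    for (i in seq_len(nrow(A)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    mins_ba[j] <- best
  }
  if (variant == "max") max(max(mins_ab), max(mins_ba))
  else (sum(mins_ab) + sum(mins_ba)) / (length(mins_ab) + length(mins_ba))
}

# random soft prediction on an h x w grid with M classes
random_pred <- function(h, w, M, seed) {
  set.seed(seed)
  soft_prediction(array(rnorm(h * w * M, sd = 2), c(h, w, M)))
}

# one-hot map with a centered rectangle of class `fg`
rect_onehot <- function(h, w, M, fg = 2L) {
  lab <- array(0L, c(h, w))
  lab[max(1, h %/% 4):(3 * h %/% 4), max(1, w %/% 4):(3 * w %/% 4)] <- fg - 1L
  one_hot(lab, M)
}

# tiny dataset + config helpers for training tests (16x16 keeps steps fast)
tiny_spec <- function(size = 16L) {
  phantom_spec(size = size, radius_range = c(2.5, 4),
               intensity_shift = list(c(-0.7, 0.85), c(1.35, -0.15)),
               contrast_inversion = TRUE)
}

tiny_config <- function(mode, seed = 1L, max_iter = 5L, ...) {
  args <- list(mode = mode, seed = seed, max_iter = max_iter,
               base_lr = 0.02, eval_every = 1000L,
               segnet = segnet_config(in_channels = 2L, num_classes = 4L,
                                      depth = 2L, base_width = 4L,
                                      dropout = 0.1),
               disc = disc_config(in_channels = 4L, base_width = 4L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(train_config, args)
}
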