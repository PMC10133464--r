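# Low-level neural-network primitives with hand-written gradients.
# Layout convention everywhere: activations are (H, W, C, N) arrays,
# conv weights are (kh, kw, inC, outC) arrays flattened to (kh*kw*inC) x outC
# matrices for the C++ kernels.

#' @useDynLib dsseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd
NULL

## ---- deterministic seed derivation -----------------------------------------

#' Derive a reproducible sub-seed from a base seed and a stream label
#'
#' All randomness in the package (weight init, dropout, batch sampling,
#' transform sampling, phantom generation) flows through dedicated sub-seeds
#' derived from one user-facing seed, so that adding or removing one stochastic
#' consumer never perturbs the others. Keeps values in [1, 2^31 - 2].
#'
#' @param ... integers and/or short strings identifying the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(...) {
  parts <- list(...)
  h <- 17
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    for (v in as.numeric(p)) {
      h <- (h * 1000003 + (abs(v) %% 2147483647)) %% 2147483647
    }
  }
  as.integer(h %% 2147483645 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

## ---- parameter initialization ----------------------------------------------

# fan_in/fan_out follow the usual convention for conv kernels.
init_conv <- function(kh, kw, inC, outC, scheme = c("xavier", "kaiming")) {
  scheme <- match.arg(scheme)
  fan_in <- kh * kw * inC
  fan_out <- kh * kw * outC
  n <- kh * kw * inC * outC
  w <- if (scheme == "xavier") {
    a <- sqrt(6 / (fan_in + fan_out))
    runif(n, -a, a)
  } else {
    rnorm(n, 0, sqrt(2 / fan_in))
  }
  list(W = array(w, c(kh, kw, inC, outC)), b = numeric(outC))
}

wmat <- function(W) {
  d <- dim(W)
  matrix(W, nrow = d[1] * d[2] * d[3], ncol = d[4])
}

## ---- conv / pool / upsample wrappers ---------------------------------------

conv2d <- function(x, W, b, stride = 1L, pad = 1L) {
  d <- dim(W)
  .conv2d_fwd(x, wmat(W), b, d[1], d[2], as.integer(stride), as.integer(pad))
}

conv2d_grad <- function(x, W, gy, stride = 1L, pad = 1L) {
  d <- dim(W)
  g <- .conv2d_bwd(x, wmat(W), gy, d[1], d[2], as.integer(stride), as.integer(pad))
  g$gw <- array(g$gw, d)
  g
}

maxpool2 <- function(x) .maxpool2_fwd(x)

maxpool2_grad <- function(gy, idx, xdim) .maxpool2_bwd(gy, idx, as.integer(xdim))

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

upsample2_grad <- function(gy) {
  d <- dim(gy)
  oh <- d[1] / 2L; ow <- d[2] / 2L
  # sum each 2x2 block
  g <- array(gy, c(2L, oh, 2L, ow, d[3], d[4]))
  r <- colSums(g)                        # (oh, 2, ow, C, N)
  r <- aperm(r, c(2L, 1L, 3L, 4L, 5L))   # (2, oh, ow, C, N)
  array(colSums(r), c(oh, ow, d[3], d[4]))
}

## ---- activations ------------------------------------------------------------

relu <- function(x) .relu_fwd(x)
relu_grad <- function(y, gy) .relu_bwd(y, gy)

leaky_relu <- function(x, slope = 0.2) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}
# needs the pre-activation sign; cache the mask
leaky_relu_grad <- function(mask_neg, gy, slope = 0.2) {
  gy[mask_neg] <- gy[mask_neg] * slope
  gy
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically safe softmax over the class dimension (3rd) of (H,W,M,N).
softmax4 <- function(logits) {
  d <- dim(logits)
  M <- d[3]
  mx <- logits[, , 1L, , drop = FALSE]
  if (M > 1L) for (m in 2:M) mx <- pmax(mx, logits[, , m, , drop = FALSE])
  e <- exp(sweep_class(logits, mx, `-`))
  s <- e[, , 1L, , drop = FALSE]
  if (M > 1L) for (m in 2:M) s <- s + e[, , m, , drop = FALSE]
  sweep_class(e, s, `/`)
}

# apply op between (H,W,M,N) tensor and (H,W,1,N) tensor, broadcasting classes
sweep_class <- function(x, v, op) {
  d <- dim(x)
  vv <- array(v, c(d[1], d[2], 1L, d[4]))[, , rep(1L, d[3]), , drop = FALSE]
  op(x, vv)
}

# Backprop through softmax: given g = dL/dprobs, return dL/dlogits.
softmax_backward <- function(probs, gprobs) {
  d <- dim(probs)
  dot <- (probs * gprobs)[, , 1L, , drop = FALSE]
  if (d[3] > 1L) for (m in 2:d[3]) dot <- dot + (probs * gprobs)[, , m, , drop = FALSE]
  probs * sweep_class(gprobs, dot, `-`)
}

## ---- batch norm -------------------------------------------------------------

BN_EPS <- 1e-5

bn_forward <- function(x, gamma, beta, run_mean, run_var, train, momentum = 0.1) {
  r <- .bn_fwd(x, gamma, beta, run_mean, run_var, train, momentum, BN_EPS)
  list(y = r$y,
       cache = list(xhat = r$xhat, ivstd = r$ivstd, train = train),
       run_mean = r$run_mean, run_var = r$run_var)
}

bn_backward <- function(cache, gamma, gy) {
  .bn_bwd(gy, cache$xhat, cache$ivstd, gamma, cache$train)
}

## ---- dropout ----------------------------------------------------------------

# Channel-wise (spatial) dropout; mask drawn from a dedicated sub-seed.
dropout_forward <- function(x, rate, train, seed) {
  if (!train || rate <= 0) return(list(y = x, mask = NULL))
  d <- dim(x)
  keep <- with_seed(seed, runif(d[3] * d[4]) >= rate)
  mask <- array(rep(keep / (1 - rate), each = d[1] * d[2]), d)
  list(y = x * mask, mask = mask)
}

dropout_backward <- function(mask, gy) {
  if (is.null(mask)) gy else gy * mask
}

## ---- optimizers -------------------------------------------------------------

# SGD with classical momentum and L2 weight decay (decay added to the
# gradient, as in the usual segmentation training recipes).
sgd_step <- function(params, grads, state, lr, momentum = 0.9, weight_decay = 1e-4,
                     decay_filter = NULL) {
  if (is.null(state)) state <- lapply(params, function(p) array(0, dim_or_len(p)))
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    wd <- if (!is.null(decay_filter) && !decay_filter(nm)) 0 else weight_decay
    g <- g + wd * params[[nm]]
    state[[nm]] <- momentum * state[[nm]] + g
    params[[nm]] <- params[[nm]] - lr * state[[nm]]
  }
  list(params = params, state = state)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.45, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(state)) {
    state <- list(m = lapply(params, function(p) array(0, dim_or_len(p))),
                  v = lapply(params, function(p) array(0, dim_or_len(p))),
                  t = 0L)
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

dim_or_len <- function(p) if (is.null(dim(p))) length(p) else dim(p)

# elementwise-accumulate grads lists: a + w*b (b entries may be missing)
acc_grads <- function(a, b, w = 1) {
  if (w == 0 || is.null(b)) return(a)
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) w * b[[nm]] else a[[nm]] + w * b[[nm]]
  }
  a
}
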