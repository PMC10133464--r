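# Network definitions: a compact U-Net segmentor and a 5-layer stride-2 fully
# convolutional discriminator, both with hand-written forward/backward passes
# (no autodiff dependency). 2D only: the adaptation mechanism is rank-agnostic
# and the desk-scale experiments run on 2D phantoms; see the methods vignette.

#' Segmentation network configuration
#'
#' @param spatial_rank 2 (3D networks are not provided in this CPU build;
#'   see the methods vignette).
#' @param in_channels number of image channels C.
#' @param num_classes number of segmentation classes M (>= 2).
#' @param depth number of encoder levels / poolings; input dims must be
#'   divisible by `2^depth`.
#' @param base_width feature channels at the first level; doubles per level.
#' @param dropout spatial dropout rate applied at the bottleneck.
#' @param batchnorm use batch normalization (always TRUE in this build).
#' @return A `segnet_config` list.
#' @export
segnet_config <- function(spatial_rank = 2L, in_channels = 2L, num_classes = 4L,
                          depth = 4L, base_width = 16L, dropout = 0.1,
                          batchnorm = TRUE) {
  if (spatial_rank != 2L)
    stop("only spatial_rank = 2 networks are implemented in this build")
  stopifnot(in_channels >= 1L, num_classes >= 2L, depth >= 1L, base_width >= 1L,
            dropout >= 0, dropout < 1)
  structure(list(spatial_rank = 2L, in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes), depth = as.integer(depth),
                 base_width = as.integer(base_width), dropout = dropout,
                 batchnorm = isTRUE(batchnorm)), class = "segnet_config")
}

unet_widths <- function(cfg) {
  w <- cfg$base_width * 2L^(seq_len(cfg$depth) - 1L)
  list(enc = w, bottleneck = cfg$base_width * 2L^cfg$depth)
}

#' Build a U-Net segmentor
#'
#' Encoder of `depth` two-conv blocks (3x3, batch norm, ReLU) with 2x2 max
#' pooling, a bottleneck block with spatial dropout, and a mirrored decoder
#' using nearest-neighbor upsampling, skip concatenation, and a final 1x1
#' projection to class logits. Initialization is deterministic given
#' `(config, init_scheme, seed)`; the two students of the dual-student
#' framework are built with different schemes and seeds so their parameter
#' sets genuinely differ.
#'
#' @param config a [segnet_config()].
#' @param init_scheme `"xavier"` (uniform Glorot) or `"kaiming"` (He normal).
#' @param seed integer seed for the weight draw.
#' @return A network object (list with `params`, `bn`, `cfg`, `kind`).
#' @export
build_segmentor <- function(config = segnet_config(), init_scheme = "xavier",
                            seed = 1L) {
  cfg <- config
  w <- unet_widths(cfg)
  params <- list()
  bn <- list()
  add_conv <- function(name, kh, kw, ic, oc) {
    p <- init_conv(kh, kw, ic, oc, init_scheme)
    params[[paste0(name, "_W")]] <<- p$W
    params[[paste0(name, "_b")]] <<- p$b
  }
  add_bn <- function(name, c) {
    params[[paste0(name, "_g")]] <<- rep(1, c)
    params[[paste0(name, "_be")]] <<- rep(0, c)
    bn[[name]] <<- list(mean = rep(0, c), var = rep(1, c))
  }
  with_seed(derive_seed(seed, "unet", init_scheme), {
    ic <- cfg$in_channels
    for (l in seq_len(cfg$depth)) {
      add_conv(sprintf("enc%d_conv1", l), 3, 3, ic, w$enc[l])
      add_bn(sprintf("enc%d_bn1", l), w$enc[l])
      add_conv(sprintf("enc%d_conv2", l), 3, 3, w$enc[l], w$enc[l])
      add_bn(sprintf("enc%d_bn2", l), w$enc[l])
      ic <- w$enc[l]
    }
    add_conv("bot_conv1", 3, 3, ic, w$bottleneck)
    add_bn("bot_bn1", w$bottleneck)
    add_conv("bot_conv2", 3, 3, w$bottleneck, w$bottleneck)
    add_bn("bot_bn2", w$bottleneck)
    up_in <- w$bottleneck
    for (l in rev(seq_len(cfg$depth))) {
      add_conv(sprintf("dec%d_up", l), 3, 3, up_in, w$enc[l])
      add_bn(sprintf("dec%d_bnu", l), w$enc[l])
      add_conv(sprintf("dec%d_conv", l), 3, 3, 2L * w$enc[l], w$enc[l])
      add_bn(sprintf("dec%d_bnc", l), w$enc[l])
      up_in <- w$enc[l]
    }
    add_conv("final", 1, 1, w$enc[1], cfg$num_classes)
  })
  structure(list(params = params, bn = bn, cfg = cfg, kind = "unet"),
            class = "dsseg_net")
}

# one conv+bn+relu unit; returns output plus cache and updated bn stats
cbr_fwd <- function(net, name_conv, name_bn, x, train, pad = 1L) {
  W <- net$params[[paste0(name_conv, "_W")]]
  b <- net$params[[paste0(name_conv, "_b")]]
  z <- conv2d(x, W, b, stride = 1L, pad = pad)
  st <- net$bn[[name_bn]]
  bnr <- bn_forward(z, net$params[[paste0(name_bn, "_g")]],
                    net$params[[paste0(name_bn, "_be")]],
                    st$mean, st$var, train)
  a <- relu(bnr$y)
  list(y = a,
       cache = list(x = x, z = z, bn = bnr$cache, act = a,
                    conv = name_conv, bnn = name_bn, pad = pad),
       stats = list(mean = bnr$run_mean, var = bnr$run_var))
}

cbr_bwd <- function(net, cache, gy, grads) {
  g <- relu_grad(cache$act, gy)
  bb <- bn_backward(cache$bn, net$params[[paste0(cache$bnn, "_g")]], g)
  grads[[paste0(cache$bnn, "_g")]] <- bb$ggamma
  grads[[paste0(cache$bnn, "_be")]] <- bb$gbeta
  cg <- conv2d_grad(cache$x, net$params[[paste0(cache$conv, "_W")]], bb$gx,
                    stride = 1L, pad = cache$pad)
  grads[[paste0(cache$conv, "_W")]] <- cg$gw
  grads[[paste0(cache$conv, "_b")]] <- cg$gb
  list(gx = cg$gx, grads = grads)
}

#' Forward pass of a segmentor
#'
#' @param net a network from [build_segmentor()].
#' @param x input batch, array (H, W, C, N); H and W divisible by `2^depth`.
#' @param train training mode (batch statistics, dropout active).
#' @param seed sub-seed for the dropout mask when in training mode.
#' @return List with `logits` (H, W, M, N), `probs`, `cache` (for
#'   [segmentor_backward()]), and `bn` (updated running statistics; commit
#'   to `net$bn` when training).
#' @export
segmentor_forward <- function(net, x, train = FALSE, seed = 1L) {
  cfg <- net$cfg
  d <- dim(x)
  if (length(d) != 4L || d[3] != cfg$in_channels)
    stop("input must be (H, W, C, N) with C = ", cfg$in_channels)
  if (d[1] %% 2L^cfg$depth || d[2] %% 2L^cfg$depth)
    stop("spatial dims must be divisible by 2^depth = ", 2L^cfg$depth)
  caches <- list()
  stats <- net$bn
  h <- x
  skips <- list()
  for (l in seq_len(cfg$depth)) {
    r <- cbr_fwd(net, sprintf("enc%d_conv1", l), sprintf("enc%d_bn1", l), h, train)
    stats[[r$cache$bnn]] <- r$stats; caches[[paste0("e", l, "a")]] <- r$cache
    r <- cbr_fwd(net, sprintf("enc%d_conv2", l), sprintf("enc%d_bn2", l), r$y, train)
    stats[[r$cache$bnn]] <- r$stats; caches[[paste0("e", l, "b")]] <- r$cache
    skips[[l]] <- r$y
    mp <- maxpool2(r$y)
    caches[[paste0("p", l)]] <- list(idx = mp$idx, xdim = dim(r$y))
    h <- mp$y
  }
  r <- cbr_fwd(net, "bot_conv1", "bot_bn1", h, train)
  stats[[r$cache$bnn]] <- r$stats; caches[["ba"]] <- r$cache
  r <- cbr_fwd(net, "bot_conv2", "bot_bn2", r$y, train)
  stats[[r$cache$bnn]] <- r$stats; caches[["bb"]] <- r$cache
  dr <- dropout_forward(r$y, cfg$dropout, train, derive_seed(seed, "drop"))
  caches[["drop"]] <- dr$mask
  h <- dr$y
  for (l in rev(seq_len(cfg$depth))) {
    up <- upsample2(h)
    r <- cbr_fwd(net, sprintf("dec%d_up", l), sprintf("dec%d_bnu", l), up, train)
    stats[[r$cache$bnn]] <- r$stats; caches[[paste0("d", l, "u")]] <- r$cache
    wl <- dim(r$y)[3]
    cat_in <- array(0, c(dim(r$y)[1], dim(r$y)[2], 2L * wl, dim(r$y)[4]))
    cat_in[, , seq_len(wl), ] <- r$y
    cat_in[, , wl + seq_len(wl), ] <- skips[[l]]
    r2 <- cbr_fwd(net, sprintf("dec%d_conv", l), sprintf("dec%d_bnc", l), cat_in, train)
    stats[[r2$cache$bnn]] <- r2$stats; caches[[paste0("d", l, "c")]] <- r2$cache
    caches[[paste0("d", l, "w")]] <- wl
    h <- r2$y
  }
  logits <- conv2d(h, net$params$final_W, net$params$final_b, stride = 1L, pad = 0L)
  caches[["head_in"]] <- h
  list(logits = logits, probs = softmax4(logits), cache = caches, bn = stats)
}

#' Backward pass of a segmentor
#'
#' @param net the network used in the forward pass.
#' @param cache the cache returned by [segmentor_forward()].
#' @param glogits gradient of the scalar loss w.r.t. the logits.
#' @return Named list of parameter gradients.
#' @export
segmentor_backward <- function(net, cache, glogits) {
  cfg <- net$cfg
  grads <- list()
  cg <- conv2d_grad(cache$head_in, net$params$final_W, glogits,
                    stride = 1L, pad = 0L)
  grads$final_W <- cg$gw; grads$final_b <- cg$gb
  gh <- cg$gx
  gskips <- list()
  for (l in seq_len(cfg$depth)) {
    r2 <- cbr_bwd(net, cache[[paste0("d", l, "c")]], gh, grads)
    grads <- r2$grads
    wl <- cache[[paste0("d", l, "w")]]
    gup_out <- r2$gx[, , seq_len(wl), , drop = FALSE]
    gskips[[l]] <- r2$gx[, , wl + seq_len(wl), , drop = FALSE]
    r <- cbr_bwd(net, cache[[paste0("d", l, "u")]], gup_out, grads)
    grads <- r$grads
    gh <- upsample2_grad(r$gx)
  }
  gh <- dropout_backward(cache$drop, gh)
  r <- cbr_bwd(net, cache$bb, gh, grads); grads <- r$grads
  r <- cbr_bwd(net, cache$ba, r$gx, grads); grads <- r$grads
  gh <- r$gx
  for (l in rev(seq_len(cfg$depth))) {
    pc <- cache[[paste0("p", l)]]
    g <- maxpool2_grad(gh, pc$idx, pc$xdim)
    g <- g + gskips[[l]]
    r <- cbr_bwd(net, cache[[paste0("e", l, "b")]], g, grads); grads <- r$grads
    r <- cbr_bwd(net, cache[[paste0("e", l, "a")]], r$gx, grads); grads <- r$grads
    gh <- r$gx
  }
  grads
}

## ---- discriminator ----------------------------------------------------------

#' Discriminator configuration
#'
#' Five stride-2 convolutions with 4x4 kernels; all but the last are followed
#' by leaky ReLU (slope 0.2) and dropout (0.5); the last emits a 1-channel
#' domain score map (logits, no final activation).
#'
#' @param in_channels channels of the input map (usually M, the class count).
#' @param base_width features of the first conv; doubles per layer.
#' @return A `disc_config` list.
#' @export
disc_config <- function(in_channels = 4L, base_width = 16L) {
  structure(list(in_channels = as.integer(in_channels),
                 base_width = as.integer(base_width),
                 layers = 5L, kernel = 4L, stride = 2L,
                 leaky_slope = 0.2, dropout = 0.5), class = "disc_config")
}

#' Build a discriminator
#'
#' @param config a [disc_config()].
#' @param seed integer seed for the weight draw (Kaiming normal).
#' @return A network object.
#' @export
build_discriminator <- function(config = disc_config(), seed = 1L) {
  cfg <- config
  widths <- c(cfg$base_width * 2L^(0:3), 1L)
  params <- list()
  with_seed(derive_seed(seed, "disc"), {
    ic <- cfg$in_channels
    for (l in seq_len(cfg$layers)) {
      p <- init_conv(cfg$kernel, cfg$kernel, ic, widths[l], "kaiming")
      params[[sprintf("d%d_W", l)]] <- p$W
      params[[sprintf("d%d_b", l)]] <- p$b
      ic <- widths[l]
    }
  })
  structure(list(params = params, cfg = cfg, kind = "disc", widths = widths),
            class = "dsseg_net")
}

#' Discriminator forward pass
#'
#' @param net network from [build_discriminator()].
#' @param x input map, array (H, W, in_channels, N); H, W >= 32 for the full
#'   five halvings.
#' @param train training mode (dropout active).
#' @param seed sub-seed for dropout masks.
#' @return List with `score` (h', w', 1, N) logits and `cache`.
#' @export
disc_forward <- function(net, x, train = FALSE, seed = 1L) {
  cfg <- net$cfg
  caches <- list()
  h <- x
  for (l in seq_len(cfg$layers)) {
    if (dim(h)[1] < 2L || dim(h)[2] < 2L)
      stop("input too small for 5 stride-2 layers")
    W <- net$params[[sprintf("d%d_W", l)]]
    z <- conv2d(h, W, net$params[[sprintf("d%d_b", l)]],
                stride = cfg$stride, pad = 1L)
    if (l < cfg$layers) {
      neg <- z < 0
      a <- leaky_relu(z, cfg$leaky_slope)
      dr <- dropout_forward(a, cfg$dropout, train, derive_seed(seed, "ddrop", l))
      caches[[l]] <- list(x = h, neg = neg, mask = dr$mask)
      h <- dr$y
    } else {
      caches[[l]] <- list(x = h)
      h <- z
    }
  }
  list(score = h, cache = caches)
}

#' Discriminator backward pass
#'
#' @param net the discriminator.
#' @param cache cache from [disc_forward()].
#' @param gscore gradient w.r.t. the score map.
#' @return List with parameter `grads` and `gx`, the gradient w.r.t. the
#'   input map (used to push adversarial gradient into the segmentor).
#' @export
disc_backward <- function(net, cache, gscore) {
  cfg <- net$cfg
  grads <- list()
  g <- gscore
  for (l in rev(seq_len(cfg$layers))) {
    cc <- cache[[l]]
    if (l < cfg$layers) {
      g <- dropout_backward(cc$mask, g)
      g <- leaky_relu_grad(cc$neg, g, cfg$leaky_slope)
    }
    cg <- conv2d_grad(cc$x, net$params[[sprintf("d%d_W", l)]], g,
                      stride = cfg$stride, pad = 1L)
    grads[[sprintf("d%d_W", l)]] <- cg$gw
    grads[[sprintf("d%d_b", l)]] <- cg$gb
    g <- cg$gx
  }
  list(grads = grads, gx = g)
}

#' Extract one sample's soft prediction from a batch forward
#'
#' @param fwd result of [segmentor_forward()].
#' @param n sample index within the batch.
#' @return A `soft_prediction` with class dimension last.
#' @export
batch_prediction <- function(fwd, n) {
  soft_prediction(logits = fwd$logits[, , , n],
                  probs = fwd$probs[, , , n], validate = FALSE)
}
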