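# Stochastic input perturbations used by the consistency machinery.
#
# A transform_spec is split into a spatial part (exact lattice symmetries:
# 90-degree rotations and axis flips, replayable on both images and
# probability maps) and an intensity part (contrast gain and Gaussian noise,
# images only). Everything is deterministic once sampled: the noise carries
# its own recorded sub-seed so replay is bit-exact.

#' Default transform configuration
#'
#' @param rot90 logical, enable in-plane 90-degree rotations.
#' @param k_range integers in 0..3 the rotation count is drawn from.
#' @param flip logical, enable axis flips (mirror/reflection).
#' @param flip_axes spatial axes eligible for flipping.
#' @param contrast logical, enable multiplicative contrast gain.
#' @param gamma_range range of the gain, must be positive.
#' @param noise logical, enable additive Gaussian noise.
#' @param sigma_range range of the noise standard deviation, nonnegative.
#' @return A list understood by [sample_transform()].
#' @export
transform_config <- function(rot90 = TRUE, k_range = 0:3,
                             flip = TRUE, flip_axes = c(1L, 2L),
                             contrast = TRUE, gamma_range = c(0.8, 1.2),
                             noise = TRUE, sigma_range = c(0, 0.1)) {
  stopifnot(all(k_range %in% 0:3), all(gamma_range > 0), all(sigma_range >= 0))
  list(rot90 = rot90, k_range = as.integer(k_range),
       flip = flip, flip_axes = as.integer(flip_axes),
       contrast = contrast, gamma_range = gamma_range,
       noise = noise, sigma_range = sigma_range)
}

#' Sample a stochastic perturbation
#'
#' Draws one perturbation from the configured families. The spatial part
#' (rotation/flip) and the intensity part (contrast/noise) are recorded
#' separately so the spatial part alone can be replayed onto predictions.
#'
#' @param seed integer seed for the draw; equal seeds give equal specs.
#' @param config a [transform_config()] list.
#' @return An object of class `transform_spec`.
#' @export
sample_transform <- function(seed, config = transform_config()) {
  if (!any(c(config$rot90, config$flip, config$contrast, config$noise)))
    stop("no transforms enabled")
  with_seed(seed, {
    spatial <- list()
    intensity <- list()
    if (config$rot90) {
      k <- if (length(config$k_range) == 1L) config$k_range else
        sample(config$k_range, 1L)
      spatial[[length(spatial) + 1L]] <- list(op = "rot90", k = as.integer(k),
                                              axes = c(1L, 2L))
    }
    if (config$flip) {
      ax <- if (length(config$flip_axes) == 1L) config$flip_axes else
        sample(config$flip_axes, 1L)
      if (runif(1) < 0.5)
        spatial[[length(spatial) + 1L]] <- list(op = "flip", axis = as.integer(ax))
    }
    if (config$contrast) {
      g <- runif(1, config$gamma_range[1], config$gamma_range[2])
      intensity[[length(intensity) + 1L]] <- list(op = "contrast", gain = g)
    }
    if (config$noise) {
      s <- runif(1, config$sigma_range[1], config$sigma_range[2])
      intensity[[length(intensity) + 1L]] <-
        list(op = "noise", sigma = s,
             seed = as.integer(floor(runif(1, 1, 2^31 - 2))))
    }
    structure(list(spatial = spatial, intensity = intensity),
              class = "transform_spec")
  })
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("<transform_spec>\n spatial :",
      if (length(x$spatial)) paste(vapply(x$spatial, function(o)
        paste0(o$op, "(", if (o$op == "rot90") o$k else o$axis, ")"),
        character(1)), collapse = " -> ") else "identity", "\n",
      "intensity:",
      if (length(x$intensity)) paste(vapply(x$intensity, function(o)
        paste0(o$op, "(", signif(if (o$op == "contrast") o$gain else o$sigma, 3), ")"),
        character(1)), collapse = " -> ") else "identity", "\n")
  invisible(x)
}

## ---- primitive lattice symmetries ------------------------------------------

# 90-degree CCW rotation in the plane of two spatial axes, any-rank array.
arr_rot90 <- function(a, k = 1L, axes = c(1L, 2L)) {
  k <- ((k %% 4L) + 4L) %% 4L
  if (k == 0L) return(a)
  nd <- length(dim(a))
  for (i in seq_len(k)) {
    perm <- seq_len(nd)
    perm[axes] <- axes[c(2L, 1L)]
    a <- aperm(a, perm)
    a <- arr_flip(a, axes[1L])
  }
  a
}

arr_flip <- function(a, axis) {
  idx <- rep(list(quote(expr = )), length(dim(a)))
  idx[[axis]] <- rev(seq_len(dim(a)[axis]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Apply the spatial part to an array whose first `n_spatial` dims are spatial.
apply_spatial_ops <- function(a, ops, n_spatial = 2L) {
  for (op in ops) {
    if (op$op == "rot90") {
      ax <- op$axes
      if (op$k %% 2L == 1L && dim(a)[ax[1]] != dim(a)[ax[2]])
        stop("rot90 by an odd k needs a square plane; got dims ",
             dim(a)[ax[1]], "x", dim(a)[ax[2]])
      a <- arr_rot90(a, op$k, ax)
    } else if (op$op == "flip") {
      if (op$axis > n_spatial) stop("flip axis beyond spatial rank")
      a <- arr_flip(a, op$axis)
    } else stop("unknown spatial op: ", op$op)
  }
  a
}

#' Apply a sampled perturbation to an image
#'
#' Spatial operations are applied first, in recorded order, followed by the
#' intensity operations. The channel dimension (last) is never permuted by
#' spatial operations and never touched by them. A label map, when supplied,
#' receives the spatial operations only.
#'
#' @param image numeric array, spatial dims first, channel dim last.
#' @param spec a `transform_spec`.
#' @param labels optional integer label map over the spatial dims.
#' @param n_spatial number of leading spatial dimensions (2 or 3).
#' @return The transformed image, or `list(image, labels)` when labels given.
#' @export
apply_to_image <- function(image, spec, labels = NULL, n_spatial = 2L) {
  stopifnot(inherits(spec, "transform_spec"))
  out <- apply_spatial_ops(image, spec$spatial, n_spatial)
  for (op in spec$intensity) {
    if (op$op == "contrast") {
      out <- out * op$gain
    } else if (op$op == "noise") {
      if (op$sigma > 0)
        out <- out + array(with_seed(op$seed, rnorm(length(out), 0, op$sigma)),
                           dim(out))
    } else stop("unknown intensity op: ", op$op)
  }
  if (is.null(labels)) return(out)
  list(image = out, labels = apply_spatial_ops(labels, spec$spatial, n_spatial))
}

#' Replay the spatial part of a perturbation onto a soft prediction
#'
#' Only the exact lattice symmetries are replayed; intensity operations have
#' no meaning on probability maps and are deliberately dropped. Per-voxel
#' probability vectors are moved, never altered.
#'
#' @param pred a `soft_prediction` (see [soft_prediction()]).
#' @param spec a `transform_spec`.
#' @param n_spatial number of leading spatial dimensions.
#' @return The transformed `soft_prediction`.
#' @export
apply_spatial_to_prediction <- function(pred, spec, n_spatial = 2L) {
  stopifnot(inherits(pred, "soft_prediction"), inherits(spec, "transform_spec"))
  soft_prediction(
    logits = apply_spatial_ops(pred$logits, spec$spatial, n_spatial),
    probs = apply_spatial_ops(pred$probs, spec$spatial, n_spatial),
    validate = FALSE)
}

#' Invert the spatial part of a perturbation
#'
#' @param spec a `transform_spec`.
#' @return A `transform_spec` with reversed, inverted spatial ops and no
#'   intensity ops; applying it after `spec`'s spatial part is the identity,
#'   bit-exactly.
#' @export
invert_spatial <- function(spec) {
  stopifnot(inherits(spec, "transform_spec"))
  inv <- lapply(rev(spec$spatial), function(op) {
    if (op$op == "rot90") list(op = "rot90", k = (4L - op$k) %% 4L, axes = op$axes)
    else op  # flips are involutions
  })
  structure(list(spatial = inv, intensity = list()), class = "transform_spec")
}
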