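# Synthetic nested-lesion phantoms: paired source/target segmentation domains
# with the statistical structure of multi-channel brain-lesion data — a small
# number of nested foreground classes (whole > core > enhancing analogue),
# severe class imbalance, and a controllable source-to-target domain shift
# (per-channel intensity remap, lesion-morphology rescaling, contrast
# inversion of one class). Geometry is deliberately stylized (rotated
# ellipses + Gaussian texture): the mechanism under test is the adaptation
# machinery, not anatomy.

#' Phantom specification
#'
#' @param spatial_rank 2 or 3.
#' @param size spatial extent per dimension (square/cubic images).
#' @param channels number of image channels C.
#' @param classes number of classes M including background (default 4:
#'   background + three nested lesion classes).
#' @param n_lesions integer range for the lesion count per image.
#' @param radius_range range of the outer lesion radius, in voxels.
#' @param nesting fractions `(core/whole, enhancing/core)` of nested radii.
#' @param intensity per-class x per-channel mean matrix (classes in rows,
#'   channels in columns); `NULL` uses a built-in contrast table.
#' @param class_sd per-class intensity standard deviation.
#' @param texture_sd global additive Gaussian texture noise.
#' @param intensity_shift list of per-channel `(a, b)` affine coefficients
#'   applied to TARGET images only (`x -> a*x + b`).
#' @param morphology_shift multiplier on target lesion radii.
#' @param contrast_inversion swap the intensity rows of the core and
#'   enhancing classes in the target domain.
#' @param max_foreground rejection bound on the foreground voxel fraction.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(spatial_rank = 2L, size = 32L, channels = 2L,
                         classes = 4L, n_lesions = c(1L, 2L),
                         radius_range = c(4, 7), nesting = c(0.65, 0.55),
                         intensity = NULL, class_sd = 0.03, texture_sd = 0.05,
                         intensity_shift = NULL, morphology_shift = 1.0,
                         contrast_inversion = FALSE, max_foreground = 0.25) {
  stopifnot(spatial_rank %in% c(2L, 3L), size >= 8L, channels >= 1L,
            classes >= 2L, morphology_shift > 0)
  if (max(radius_range) * max(morphology_shift, 1) >= size / 2)
    stop("lesion larger than image")
  if (is.null(intensity)) {
    # rows: classes 0..3; columns: channels. Distinct contrast per channel,
    # echoing complementary MRI sequences.
    base <- rbind(bg = c(0.15, 0.20), whole = c(0.55, 0.35),
                  core = c(0.75, 0.60), enh = c(0.45, 0.90))
    intensity <- base[seq_len(classes), seq_len(max(channels, 1)), drop = FALSE]
    if (channels > 2L)
      intensity <- cbind(intensity,
                         matrix(rep(intensity[, 2L], channels - 2L),
                                ncol = channels - 2L))
    intensity <- intensity[, seq_len(channels), drop = FALSE]
  }
  if (is.null(intensity_shift))
    intensity_shift <- rep(list(c(1, 0)), channels)
  structure(list(spatial_rank = as.integer(spatial_rank), size = as.integer(size),
                 channels = as.integer(channels), classes = as.integer(classes),
                 n_lesions = as.integer(range(n_lesions)),
                 radius_range = radius_range, nesting = nesting,
                 intensity = intensity, class_sd = class_sd,
                 texture_sd = texture_sd, intensity_shift = intensity_shift,
                 morphology_shift = morphology_shift,
                 contrast_inversion = isTRUE(contrast_inversion),
                 max_foreground = max_foreground), class = "phantom_spec")
}

#' Stylized preset tasks
#'
#' `cross_grade` mimics adaptation across lesion severity: target lesions are
#' stochastically smaller (radius multiplier 0.6) with a mild intensity
#' shift. `cross_modality` mimics adaptation across imaging sequences: a
#' strong per-channel affine intensity remap with partial inversion of the
#' first channel plus contrast inversion of the enhancing class; lesion
#' morphology is unchanged, so the label distribution is identical across
#' domains.
#'
#' @param name `"cross_grade"` or `"cross_modality"`.
#' @param size spatial extent (default 32).
#' @return A `phantom_spec`.
#' @export
preset_task <- function(name = c("cross_grade", "cross_modality"), size = 32L) {
  name <- match.arg(name)
  if (name == "cross_grade") {
    phantom_spec(size = size, morphology_shift = 0.6,
                 intensity_shift = list(c(1.05, 0.03), c(1.05, 0.03)))
  } else {
    phantom_spec(size = size, morphology_shift = 1.0,
                 intensity_shift = list(c(-0.7, 0.85), c(1.35, -0.15)),
                 contrast_inversion = TRUE)
  }
}

#' Generate one phantom sample
#'
#' Draws lesion centers/radii, rasterizes the nested class regions (ellipses
#' with random axis ratios and orientation), paints per-class per-channel
#' intensities plus texture noise, and applies the domain-shift block iff
#' `domain = "target"`. Samples violating the foreground-fraction bound are
#' rejected and redrawn (deterministically, from the same stream).
#'
#' @param spec a [phantom_spec()].
#' @param domain `"source"` or `"target"`.
#' @param seed integer seed; generation is bit-reproducible from
#'   `(spec, domain-morphology, seed)`.
#' @return List with `image` (size^rank, C array) and `labels` (integer
#'   array, values 0..M-1).
#' @export
generate_sample <- function(spec, domain = c("source", "target"), seed = 1L) {
  domain <- match.arg(domain)
  with_seed(derive_seed(seed, "phantom"), {
    for (attempt in 1:25) {
      lab <- draw_labelmap(spec, domain)
      if (mean(lab > 0) < spec$max_foreground) break
    }
    img <- paint_image(spec, lab, domain)
    list(image = img, labels = lab)
  })
}

draw_labelmap <- function(spec, domain) {
  s <- spec$size
  rank <- spec$spatial_rank
  lab <- array(0L, rep(s, rank))
  n <- if (spec$n_lesions[1] == spec$n_lesions[2]) spec$n_lesions[1] else
    sample(spec$n_lesions[1]:spec$n_lesions[2], 1L)
  mult <- if (domain == "target") spec$morphology_shift else 1.0
  coords <- which(lab == 0L, arr.ind = TRUE)  # all voxel coordinates
  for (i in seq_len(n)) {
    r0 <- runif(1, spec$radius_range[1], spec$radius_range[2]) * mult
    ctr <- runif(rank, r0 + 1, s - r0)
    ax <- runif(rank, 0.75, 1.3)
    th <- runif(1, 0, pi)
    dx <- sweep(coords[, 1:rank, drop = FALSE], 2, ctr)
    if (rank == 2L) {
      u <- cos(th) * dx[, 1] + sin(th) * dx[, 2]
      v <- -sin(th) * dx[, 1] + cos(th) * dx[, 2]
      rho <- sqrt((u / ax[1])^2 + (v / ax[2])^2)
    } else {
      rho <- sqrt((dx[, 1] / ax[1])^2 + (dx[, 2] / ax[2])^2 +
                    (dx[, 3] / ax[3])^2)
    }
    les <- integer(nrow(coords))
    r_core <- r0 * spec$nesting[1]
    r_enh <- r_core * spec$nesting[2]
    les[rho <= r0] <- 1L
    if (spec$classes >= 3L) les[rho <= r_core] <- 2L
    if (spec$classes >= 4L) les[rho <= r_enh] <- 3L
    lab[] <- pmax(as.integer(lab), les)
  }
  lab
}

paint_image <- function(spec, lab, domain) {
  s <- spec$size
  rank <- spec$spatial_rank
  C <- spec$channels
  intens <- spec$intensity
  if (domain == "target" && spec$contrast_inversion && spec$classes >= 4L) {
    tmp <- intens[3L, ]
    intens[3L, ] <- intens[4L, ]
    intens[4L, ] <- tmp
  }
  img <- array(0, c(rep(s, rank), C))
  nvox <- s^rank
  for (ch in seq_len(C)) {
    mu <- intens[as.integer(lab) + 1L, ch]
    v <- mu + rnorm(nvox, 0, spec$class_sd) + rnorm(nvox, 0, spec$texture_sd)
    if (domain == "target") {
      ab <- spec$intensity_shift[[ch]]
      v <- ab[1] * v + ab[2]
    }
    if (rank == 2L) img[, , ch] <- v else img[, , , ch] <- v
  }
  img
}

#' Generate a full adaptation dataset
#'
#' Splits mirror the usual adaptation protocol: labeled source training
#' images, unlabeled target training images, and held-out target validation
#' and test sets (labels retained for evaluation). Target TRAINING labels
#' exist by construction but are hidden: adaptation code cannot read them
#' (the accessor raises), only the fully supervised `super_all` arm may
#' unhide them explicitly.
#'
#' @param spec a [phantom_spec()].
#' @param n_source,n_target,n_val,n_test split sizes (all positive).
#' @param seed integer seed.
#' @return A `phantom_dataset` list with fields `source` (labeled),
#'   `target_train` (labels hidden), `val`, `test` (labeled target), `spec`,
#'   `seed`.
#' @export
generate_dataset <- function(spec, n_source, n_target, n_val, n_test, seed = 1L) {
  stopifnot(n_source > 0, n_target > 0, n_val > 0, n_test > 0)
  gen <- function(n, domain, tag) {
    lapply(seq_len(n), function(i)
      c(generate_sample(spec, domain, derive_seed(seed, tag, i)),
        list(id = paste0(tag, "_", i))))
  }
  tgt <- gen(n_target, "target", "ttrain")
  hidden <- lapply(tgt, `[[`, "labels")
  tgt <- lapply(tgt, function(s) { s$labels <- NULL; s })
  structure(list(
    source = gen(n_source, "source", "src"),
    target_train = tgt,
    val = gen(n_val, "target", "val"),
    test = gen(n_test, "target", "test"),
    .hidden_target_labels = hidden,
    labels_unhidden = FALSE,
    spec = spec, seed = as.integer(seed)), class = "phantom_dataset")
}

#' Access hidden target-training labels
#'
#' Raises unless the dataset was explicitly unhidden with
#' [unhide_target_labels()]; adaptation training must never call that.
#'
#' @param ds a `phantom_dataset`.
#' @return List of label maps.
#' @export
target_train_labels <- function(ds) {
  if (!isTRUE(ds$labels_unhidden))
    stop("target training labels are hidden in adaptation mode")
  ds$.hidden_target_labels
}

#' Unhide target-training labels (supervised-upper-bound arm only)
#'
#' @param ds a `phantom_dataset`.
#' @return The dataset with labels accessible.
#' @export
unhide_target_labels <- function(ds) {
  ds$labels_unhidden <- TRUE
  ds
}

#' Generate labeled samples from one domain (for held-out source testing)
#'
#' @param spec a [phantom_spec()].
#' @param n number of samples.
#' @param domain `"source"` or `"target"`.
#' @param seed integer seed.
#' @return List of `list(image, labels, id)` samples.
#' @export
generate_domain_samples <- function(spec, n, domain = "source", seed = 1L) {
  lapply(seq_len(n), function(i)
    c(generate_sample(spec, domain, derive_seed(seed, "dom", domain, i)),
      list(id = paste0(domain, "_extra_", i))))
}
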