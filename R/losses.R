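# Scalar objectives: supervised dice + cross-entropy, transform-consistency
# MSE, reliability gating, the cross-coordination constraint between the two
# students, and the adversarial/discriminator binary cross-entropies.
#
# All per-sample predictions are (spatial..., M) arrays with the class
# dimension LAST; gradients returned by the *_grad helpers are with respect
# to the probability maps and are chained through softmax by the caller.

PROB_CLIP <- 1e-7

#' Construct a soft prediction
#'
#' A soft prediction couples a network's pre-normalization logits with the
#' per-voxel class probabilities obtained by softmax over the class dimension
#' (the last array dimension).
#'
#' @param logits numeric array (spatial..., M).
#' @param probs optional matching probability array; computed by softmax when
#'   missing.
#' @param validate check normalization (sum to 1 within 1e-5) and M >= 2.
#' @return Object of class `soft_prediction` with fields `logits`, `probs`.
#' @export
soft_prediction <- function(logits, probs = NULL, validate = TRUE) {
  d <- dim(logits)
  if (is.null(d) || length(d) < 2L) stop("logits must be an array")
  if (is.null(probs)) probs <- softmax_lastdim(logits)
  if (validate) {
    M <- d[length(d)]
    if (M < 2L) stop("need at least 2 classes (background + foreground)")
    s <- rowSums(matrix(probs, ncol = M))
    if (any(abs(s - 1) > 1e-5)) stop("per-voxel probabilities do not sum to 1")
    if (any(probs < -1e-12 | probs > 1 + 1e-12)) stop("probabilities outside [0,1]")
  }
  structure(list(logits = logits, probs = probs), class = "soft_prediction")
}

softmax_lastdim <- function(logits) {
  d <- dim(logits)
  M <- d[length(d)]
  m <- matrix(logits, ncol = M)
  mx <- m[, 1L]
  if (M > 1L) for (j in 2:M) mx <- pmax(mx, m[, j])
  e <- exp(m - mx)
  array(e / rowSums(e), d)
}

as_probs <- function(x) {
  if (inherits(x, "soft_prediction")) x$probs else x
}

check_onehot <- function(target, d) {
  if (!identical(dim(target), d)) stop("shape mismatch between pred and target")
  M <- d[length(d)]
  tm <- matrix(target, ncol = M)
  if (!all(target %in% c(0, 1)) || any(rowSums(tm) != 1))
    stop("target is not one-hot")
  invisible(TRUE)
}

#' One-hot encode an integer label map
#'
#' @param labels integer array with values in 0..(n_classes-1).
#' @param n_classes number of classes M.
#' @return Numeric array (dim(labels), M).
#' @export
one_hot <- function(labels, n_classes) {
  d <- if (is.null(dim(labels))) length(labels) else dim(labels)
  out <- array(0, c(d, n_classes))
  m <- matrix(out, ncol = n_classes)
  m[cbind(seq_along(labels), as.integer(labels) + 1L)] <- 1
  array(m, c(d, n_classes))
}

## ---- supervised losses ------------------------------------------------------

#' Soft dice loss
#'
#' Class-averaged soft dice: `1 - (1/M) * sum_c 2*sum(p*y)/(sum(p)+sum(y))`,
#' with a small smoothing constant added to numerator and denominator so that
#' classes absent from both prediction and target contribute a perfect score
#' rather than 0/0.
#'
#' @param pred `soft_prediction` or probability array (spatial..., M).
#' @param target one-hot array of the same shape.
#' @param smooth smoothing constant, default 1e-5.
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, smooth = 1e-5) {
  p <- as_probs(pred)
  check_onehot(target, dim(p))
  M <- dim(p)[length(dim(p))]
  pm <- matrix(p, ncol = M); ym <- matrix(target, ncol = M)
  num <- 2 * colSums(pm * ym) + smooth
  den <- colSums(pm) + colSums(ym) + smooth
  1 - mean(num / den)
}

dice_loss_grad <- function(pred, target, smooth = 1e-5) {
  p <- as_probs(pred)
  d <- dim(p)
  M <- d[length(d)]
  pm <- matrix(p, ncol = M); ym <- matrix(target, ncol = M)
  num <- 2 * colSums(pm * ym) + smooth
  den <- colSums(pm) + colSums(ym) + smooth
  # d/dp of -(1/M) * num_c/den_c
  g <- -(2 * ym * rep(den, each = nrow(ym)) - rep(num, each = nrow(ym))) /
    rep(den^2, each = nrow(ym)) / M
  array(g, d)
}

#' Class-normalized cross-entropy loss
#'
#' Mean over voxels of `-(1/M) * sum_c y_c log p_c`; probabilities are
#' clipped away from zero before the log.
#'
#' @inheritParams dice_loss
#' @return Nonnegative scalar.
#' @export
cross_entropy_loss <- function(pred, target) {
  p <- as_probs(pred)
  check_onehot(target, dim(p))
  M <- dim(p)[length(dim(p))]
  pc <- pmin(pmax(p, PROB_CLIP), 1 - PROB_CLIP)
  nvox <- length(p) / M
  -sum(target * log(pc)) / (M * nvox)
}

cross_entropy_grad <- function(pred, target) {
  p <- as_probs(pred)
  M <- dim(p)[length(dim(p))]
  pc <- pmin(pmax(p, PROB_CLIP), 1 - PROB_CLIP)
  nvox <- length(p) / M
  -target / pc / (M * nvox)
}

#' Compound supervised segmentation loss
#'
#' `0.5 * dice_loss + cross_entropy_loss`, the standard compound objective
#' for imbalanced lesion segmentation.
#'
#' @inheritParams dice_loss
#' @return Nonnegative scalar.
#' @export
supervised_loss <- function(pred, target) {
  0.5 * dice_loss(pred, target) + cross_entropy_loss(pred, target)
}

supervised_grad <- function(pred, target) {
  0.5 * dice_loss_grad(pred, target) + cross_entropy_grad(pred, target)
}

## ---- consistency and reliability -------------------------------------------

#' Transform-consistency loss
#'
#' Mean squared error between two probability maps living in the same
#' (transformed) frame: the prediction on the perturbed input versus the
#' replayed prediction on the clean input. `n` is the total element count.
#'
#' @param a,b `soft_prediction`s or probability arrays of equal shape.
#' @return Nonnegative scalar.
#' @export
consistency_loss <- function(a, b) {
  pa <- as_probs(a); pb <- as_probs(b)
  if (!identical(dim(pa), dim(pb))) stop("shape mismatch")
  mean((pa - pb)^2)
}

consistency_grad <- function(a, b) {
  pa <- as_probs(a); pb <- as_probs(b)
  2 * (pa - pb) / length(pa)
}

#' Reliability of a prediction under perturbation
#'
#' Compares a student's prediction on a clean sample with its prediction on a
#' noisy augmentation of the same sample (mapped back to the clean frame).
#' A voxel is reliable when the predicted labels agree AND at least one of
#' the two max-probabilities exceeds the confidence threshold `xi`. The
#' stability distance `epsilon` is the Euclidean norm of the difference of
#' the two full probability maps — one scalar per sample, used to rank the
#' two students' stability.
#'
#' @param pred_clean,pred_noisy `soft_prediction`s for the same sample.
#' @param xi confidence threshold in `[0, 1]`.
#' @return Object of class `reliability_bundle` with fields `labels`,
#'   `labels_noisy` (1-based argmax maps), `maxprob`, `maxprob_noisy`,
#'   `reliable` (logical map), `epsilon` (scalar).
#' @export
compute_reliability <- function(pred_clean, pred_noisy, xi) {
  if (xi < 0 || xi > 1) stop("xi outside [0,1]")
  pc <- as_probs(pred_clean); pn <- as_probs(pred_noisy)
  if (!identical(dim(pc), dim(pn))) stop("shape mismatch")
  d <- dim(pc)
  M <- d[length(d)]
  sp <- d[-length(d)]
  pcm <- matrix(pc, ncol = M); pnm <- matrix(pn, ncol = M)
  lab_c <- max.col(pcm, ties.method = "first")
  lab_n <- max.col(pnm, ties.method = "first")
  mp_c <- pcm[cbind(seq_len(nrow(pcm)), lab_c)]
  mp_n <- pnm[cbind(seq_len(nrow(pnm)), lab_n)]
  rel <- (lab_c == lab_n) & (mp_c > xi | mp_n > xi)
  structure(list(
    labels = array(lab_c, sp), labels_noisy = array(lab_n, sp),
    maxprob = array(mp_c, sp), maxprob_noisy = array(mp_n, sp),
    reliable = array(rel, sp),
    epsilon = sqrt(sum((pc - pn)^2))), class = "reliability_bundle")
}

#' Reduce a voxel-wise reliability map to a per-sample bit
#'
#' The cross-coordination rule needs one reliability bit per student per
#' sample; the voxel map is reduced by quorum: the sample is reliable when
#' the fraction of reliable voxels exceeds `quorum`.
#'
#' @param bundle a `reliability_bundle`.
#' @param quorum fraction in `[0, 1]`, default 0.5.
#' @return 0 or 1.
#' @export
reliability_bit <- function(bundle, quorum = 0.5) {
  stopifnot(inherits(bundle, "reliability_bundle"))
  as.integer(mean(bundle$reliable) > quorum)
}

#' Cross-coordination constraint between the two students
#'
#' The reliability-gated knowledge-exchange rule on one unlabeled target
#' sample. With sample-level reliability bits `R_i`, `R_j` and stability
#' distances `eps_i`, `eps_j`:
#' when both students are reliable, only the LESS stable student (strictly
#' larger epsilon) incurs the MSE to the other's prediction; otherwise a
#' student incurs the MSE only if the OTHER student is reliable. The MSE
#' target carries no gradient: knowledge flows from the more trustworthy
#' student, predictions are never pulled symmetrically.
#'
#' @param bundle_i,bundle_j `reliability_bundle`s of students i and j.
#' @param pred_i,pred_j the students' clean-frame `soft_prediction`s.
#' @param quorum quorum for [reliability_bit()].
#' @return List with `loss_i`, `loss_j`, the gate coefficients `gate_i`,
#'   `gate_j` (0/1), the shared `mse`, and the bits `R_i`, `R_j`.
#' @export
cross_coordination_loss <- function(bundle_i, bundle_j, pred_i, pred_j,
                                    quorum = 0.5) {
  pi_ <- as_probs(pred_i); pj_ <- as_probs(pred_j)
  if (!identical(dim(pi_), dim(pj_))) stop("mismatched sample shapes")
  R_i <- reliability_bit(bundle_i, quorum)
  R_j <- reliability_bit(bundle_j, quorum)
  e_i <- bundle_i$epsilon; e_j <- bundle_j$epsilon
  mse <- mean((pi_ - pj_)^2)
  gate_i <- if (R_i == 1L && R_j == 1L) as.integer(e_i > e_j) else R_j
  gate_j <- if (R_i == 1L && R_j == 1L) as.integer(e_j > e_i) else R_i
  list(loss_i = gate_i * mse, loss_j = gate_j * mse,
       gate_i = gate_i, gate_j = gate_j, mse = mse, R_i = R_i, R_j = R_j)
}

## ---- adversarial losses -----------------------------------------------------

bce_with_logits <- function(scores, target) {
  mean(pmax(scores, 0) - scores * target + log1p(exp(-abs(scores))))
}

bce_with_logits_grad <- function(scores, target) {
  (sigmoid(scores) - target) / length(scores)
}

#' Adversarial (generator-side) loss
#'
#' Binary cross-entropy of the discriminator's scores on target-derived
#' segmentation maps against the SOURCE label (1): the segmenter is rewarded
#' for making target predictions indistinguishable from source ones.
#'
#' @param disc_out_on_target real-valued discriminator score map (logits).
#' @return Nonnegative scalar.
#' @export
adversarial_generator_loss <- function(disc_out_on_target) {
  bce_with_logits(disc_out_on_target, 1)
}

#' Discriminator loss
#'
#' Binary cross-entropy with source maps labeled 1 and target maps labeled 0,
#' averaged over the two halves.
#'
#' @param disc_out_source,disc_out_target discriminator score maps (logits).
#' @return Nonnegative scalar.
#' @export
discriminator_loss <- function(disc_out_source, disc_out_target) {
  0.5 * (bce_with_logits(disc_out_source, 1) +
           bce_with_logits(disc_out_target, 0))
}

#' Mean Shannon entropy of a soft prediction
#'
#' The entropy-minimization objective used by the `da_entropy_mini` baseline
#' arm: mean over voxels of `-sum_c p_c log p_c`.
#'
#' @param pred `soft_prediction` or probability array.
#' @return Nonnegative scalar.
#' @export
entropy_loss <- function(pred) {
  p <- as_probs(pred)
  M <- dim(p)[length(dim(p))]
  pc <- pmin(pmax(p, PROB_CLIP), 1 - PROB_CLIP)
  -sum(p * log(pc)) / (length(p) / M)
}

entropy_grad <- function(pred) {
  p <- as_probs(pred)
  M <- dim(p)[length(dim(p))]
  pc <- pmin(pmax(p, PROB_CLIP), 1 - PROB_CLIP)
  -(log(pc) + 1) / (length(p) / M)
}

## ---- composite objective ----------------------------------------------------

#' Assemble the per-student composite objective
#'
#' `total = l_seg + xi_weight * l_con + l_cross + lambda_adv * l_adv`.
#' Components are recorded unweighted in the returned bundle.
#'
#' @param l_seg,l_con,l_cross,l_adv nonnegative component values.
#' @param xi_weight weight on the consistency term.
#' @param lambda_adv weight on the adversarial term.
#' @param l_disc optional discriminator loss (recorded, not part of total).
#' @return Object of class `loss_bundle`.
#' @export
total_student_loss <- function(l_seg, l_con, l_cross, l_adv,
                               xi_weight = 1.0, lambda_adv = 0.1,
                               l_disc = NA_real_) {
  if (xi_weight < 0 || lambda_adv < 0) stop("negative weights")
  structure(list(
    l_seg = l_seg, l_con = l_con, l_cross = l_cross, l_adv = l_adv,
    l_disc = l_disc,
    total = l_seg + xi_weight * l_con + l_cross + lambda_adv * l_adv),
    class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf(
    "<loss_bundle> total %.5f | seg %.5f con %.5f cross %.5f adv %.5f disc %s\n",
    x$total, x$l_seg, x$l_con, x$l_cross, x$l_adv,
    if (is.na(x$l_disc)) "-" else sprintf("%.5f", x$l_disc)))
  invisible(x)
}
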