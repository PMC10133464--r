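# Segmentation metrics: dice similarity coefficient and Hausdorff distance
# over boundary point sets, computed per nested class (whole / core /
# enhancing analogue) and aggregated as means over test samples.

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`. Two empty masks score 1: a class that is absent
#' and not predicted is a success (prevents absent-class cases from zeroing
#' averages).
#'
#' @param pred_mask,true_mask logical/0-1 arrays of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_score <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask), dim(true_mask))) stop("shape mismatch")
  if (!all(pred_mask %in% c(0, 1)) || !all(true_mask %in% c(0, 1)))
    stop("non-binary input")
  a <- sum(pred_mask); b <- sum(true_mask)
  if (a + b == 0) return(1)
  2 * sum(pred_mask * true_mask) / (a + b)
}

# boundary voxels: foreground with at least one face-neighbor background
# (voxels on the image edge count as boundary: outside is background).
boundary_coords <- function(mask) {
  d <- dim(mask)
  rank <- length(d)
  m <- mask > 0
  if (!any(m)) return(matrix(numeric(0), ncol = rank))
  interior <- array(TRUE, d)
  for (ax in seq_len(rank)) {
    lo <- shift_slice(m, ax, 1L)
    hi <- shift_slice(m, ax, -1L)
    interior <- interior & lo & hi
  }
  which(m & !interior, arr.ind = TRUE)
}

# shift array along axis by +-1, padding with FALSE
shift_slice <- function(m, ax, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (by > 0) {
    idx_src[[ax]] <- seq_len(d[ax] - 1L)
    idx_dst[[ax]] <- 2:d[ax]
  } else {
    idx_src[[ax]] <- 2:d[ax]
    idx_dst[[ax]] <- seq_len(d[ax] - 1L)
  }
  out <- do.call(`[<-`, c(list(out), idx_dst,
                          list(do.call(`[`, c(list(m), idx_src, list(drop = FALSE))))))
  out
}

#' Hausdorff distance between two binary masks
#'
#' Computed over boundary point sets (face-neighbor boundary definition).
#' `variant = "max"` is the classical symmetric Hausdorff distance
#' `max(sup_a inf_b d, sup_b inf_a d)`; `variant = "avg"` is the averaged
#' form, the sum of all minimum distances from each set to the other divided
#' by the total number of boundary points.
#'
#' @param mask_a,mask_b logical/0-1 arrays of equal shape.
#' @param variant `"max"` or `"avg"`.
#' @param spacing voxel spacing per axis (scales to physical units).
#' @param empty_value sentinel returned (with a warning) when exactly one
#'   mask is empty; two empty masks give 0 (equal boundary sets).
#' @return Nonnegative scalar.
#' @export
hausdorff_distance <- function(mask_a, mask_b, variant = c("max", "avg"),
                               spacing = NULL, empty_value = NULL) {
  variant <- match.arg(variant)
  if (!identical(dim(mask_a), dim(mask_b))) stop("shape mismatch")
  d <- dim(mask_a)
  if (is.null(spacing)) spacing <- rep(1, length(d))
  if (is.null(empty_value)) empty_value <- sqrt(sum((d * spacing)^2))
  ea <- sum(mask_a) == 0; eb <- sum(mask_b) == 0
  if (ea && eb) return(0)
  if (ea || eb) {
    warning("empty mask in hausdorff_distance; returning sentinel")
    return(empty_value)
  }
  A <- sweep(boundary_coords(mask_a), 2, spacing, `*`)
  B <- sweep(boundary_coords(mask_b), 2, spacing, `*`)
  # pairwise squared distances, |A| x |B|
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  dm <- sqrt(d2)
  min_ab <- apply(dm, 1, min)   # from each a to B
  min_ba <- apply(dm, 2, min)
  if (variant == "max") max(max(min_ab), max(min_ba))
  else (sum(min_ab) + sum(min_ba)) / (length(min_ab) + length(min_ba))
}

#' Default nested class mapping
#'
#' For M = 4 raw labels (0 background, 1..3 nested lesion classes) builds the
#' standard nested evaluation masks: whole = all lesion labels, core = labels
#' 2-3, enhancing = label 3 — so whole contains core contains enhancing by
#' construction.
#'
#' @param n_classes raw class count M.
#' @return Named list of raw-label vectors per evaluation class.
#' @export
nested_class_map <- function(n_classes = 4L) {
  if (n_classes >= 4L)
    list(whole = 1:3, core = 2:3, enhancing = 3L)
  else if (n_classes == 3L)
    list(whole = 1:2, core = 2L)
  else
    list(whole = 1L)
}

#' Evaluate a segmentation model on a labeled split
#'
#' Runs the segmentor in evaluation mode on each sample, takes per-voxel
#' argmax labels, builds the nested class masks, and reports per-class DSC
#' (in percent) and Hausdorff distance, averaged over samples (no pooling
#' across samples before the ratio).
#'
#' @param net a segmentor.
#' @param samples list of `list(image, labels)` samples.
#' @param class_map nested class mapping, see [nested_class_map()].
#' @param spacing voxel spacing, default 1.
#' @param hd_variant `"max"` (default) or `"avg"`.
#' @return A `metric_report`: list with `dsc` and `hd` (named per-class mean
#'   vectors), `per_sample` data frame, `foreground_dsc` (mean over classes).
#' @export
evaluate_model <- function(net, samples, class_map = NULL, spacing = NULL,
                           hd_variant = "max") {
  if (length(samples) == 0L) stop("empty split")
  M <- net$cfg$num_classes
  if (is.null(class_map)) class_map <- nested_class_map(M)
  rows <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    pred <- predict_labels(net, s$image)
    for (cl in names(class_map)) {
      pm <- array(as.numeric(pred %in% class_map[[cl]]), dim(pred))
      tm <- array(as.numeric(s$labels %in% class_map[[cl]]), dim(s$labels))
      hd <- suppressWarnings(
        hausdorff_distance(pm, tm, variant = hd_variant, spacing = spacing))
      rows[[length(rows) + 1L]] <-
        data.frame(sample = i, class = cl,
                   dsc = dice_score(pm, tm), hd = hd)
    }
  }
  ps <- do.call(rbind, rows)
  dsc <- tapply(ps$dsc, ps$class, mean)[names(class_map)] * 100
  hd <- tapply(ps$hd, ps$class, mean)[names(class_map)]
  structure(list(dsc = dsc, hd = hd, per_sample = ps,
                 foreground_dsc = mean(dsc), hd_variant = hd_variant),
            class = "metric_report")
}

#' Predict integer labels for one image
#'
#' @param net a segmentor.
#' @param image array (H, W, C).
#' @return Integer label array (H, W), values 0..M-1.
#' @export
predict_labels <- function(net, image) {
  d <- dim(image)
  x <- array(image, c(d, 1L))
  fwd <- segmentor_forward(net, x, train = FALSE)
  pm <- matrix(fwd$probs[, , , 1L], ncol = net$cfg$num_classes)
  array(max.col(pm, ties.method = "first") - 1L, d[1:2])
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>  (DSC %, HD in", x$hd_variant, "variant)\n")
  for (cl in names(x$dsc))
    cat(sprintf("  %-10s DSC %6.2f%%   HD %6.2f\n", cl, x$dsc[cl], x$hd[cl]))
  cat(sprintf("  mean foreground DSC %.2f%%\n", x$foreground_dsc))
  invisible(x)
}

#' Format an ablation table
#'
#' @param reports named list of `metric_report`s (one per training arm).
#' @return Data frame: rows = methods, columns = per-class DSC and HD.
#' @export
ablation_table <- function(reports) {
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    out <- data.frame(method = nm)
    for (cl in names(r$dsc)) {
      out[[paste0("dsc_", cl)]] <- unname(r$dsc[cl])
      out[[paste0("hd_", cl)]] <- unname(r$hd[cl])
    }
    out
  })
  do.call(rbind, rows)
}
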