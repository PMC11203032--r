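# Evaluation metrics: voxel confusion counts, Dice, sensitivity,
# specificity, the 95th-percentile Hausdorff boundary distance, the soft
# Dice training loss, and per-case reports over the WT/TC/ET regions.
#
# Empty-mask conventions (leaderboard conventions vary, so they are fixed
# here): Dice of two empty masks is 1; sensitivity is NA when the truth is
# empty; specificity is NA when the truth covers everything; HD95 is NA
# whenever either boundary set is empty (never silently zero).

#' Voxel-wise confusion counts
#' @param pred,truth binary (logical or 0/1) arrays of identical shape.
#' @return list with `TP`, `FP`, `FN`, `TN`; the four counts sum to the
#'   voxel total.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop_validation("pred and truth must share a shape")
  p <- as.logical(pred); t_ <- as.logical(truth)
  list(TP = sum(p & t_), FP = sum(p & !t_), FN = sum(!p & t_), TN = sum(!p & !t_))
}

#' Dice similarity coefficient
#'
#' `2TP / (2TP + FP + FN)`; when both masks are empty (denominator zero) the
#' score is 1 by convention.
#' @param c confusion counts from [confusion()].
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(c) {
  den <- 2 * c$TP + c$FP + c$FN
  if (den == 0) return(1)
  2 * c$TP / den
}

#' Sensitivity (true positive rate)
#' @param c confusion counts; `TP / (TP + FN)`, `NA` for an empty truth.
#' @export
sensitivity <- function(c) {
  if (c$TP + c$FN == 0) return(NA_real_)
  c$TP / (c$TP + c$FN)
}

#' Specificity (true negative rate)
#' @param c confusion counts; `TN / (TN + FP)`, `NA` when there are no true
#'   negatives or false positives.
#' @export
specificity <- function(c) {
  if (c$TN + c$FP == 0) return(NA_real_)
  c$TN / (c$TN + c$FP)
}

# boundary voxels: mask voxels with at least one face-neighbor (6-connectivity)
# outside the mask; the array border counts as background
boundary_voxels <- function(mask) {
  m <- mask != 0
  dm <- dim(m)
  interior <- array(TRUE, dm)
  shift_and <- function(acc, ax, off) {
    idx <- seq_len(dm[ax]) + off
    pad <- idx < 1 | idx > dm[ax]
    idx <- pmin(pmax(idx, 1L), dm[ax])
    nb <- switch(ax, m[idx, , , drop = FALSE], m[, idx, , drop = FALSE], m[, , idx, drop = FALSE])
    if (any(pad)) switch(ax, nb[pad, , ] <- FALSE, nb[, pad, ] <- FALSE, nb[, , pad] <- FALSE)
    acc & nb
  }
  for (ax in 1:3) for (off in c(-1L, 1L)) interior <- shift_and(interior, ax, off)
  m & !interior
}

directed_percentile <- function(A, B, q) {
  # A, B: coordinate matrices (n x 3), already scaled to mm
  d <- numeric(nrow(A))
  chunk <- max(1L, floor(2e6 / nrow(B)))
  i <- 1L
  while (i <= nrow(A)) {
    j <- min(i + chunk - 1L, nrow(A))
    blk <- A[i:j, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(B^2), "+") - 2 * blk %*% t(B)
    d[i:j] <- sqrt(pmax(apply(d2, 1L, min), 0))
    i <- j + 1L
  }
  stats::quantile(d, q, names = FALSE, type = 7)
}

#' 95th-percentile Hausdorff distance
#'
#' Extracts the boundary voxels of both masks, computes the directed
#' distances from each boundary set to the other, and returns the maximum of
#' the two directed 95th percentiles (linear-interpolation percentiles),
#' scaled by the voxel spacing. Symmetric by construction.
#'
#' @param pred,truth binary arrays of identical shape.
#' @param spacing per-axis voxel size in mm (default 1 mm isotropic).
#' @param q percentile (default 0.95; `q = 1` gives the classical Hausdorff
#'   distance).
#' @return distance in mm, or `NA` with attribute `empty = TRUE` when either
#'   mask has no boundary voxels.
#' @export
hd95 <- function(pred, truth, spacing = c(1, 1, 1), q = 0.95) {
  if (!identical(dim(pred), dim(truth)))
    stop_validation("pred and truth must share a shape")
  bp <- which(boundary_voxels(pred), arr.ind = TRUE)
  bt <- which(boundary_voxels(truth), arr.ind = TRUE)
  if (nrow(bp) == 0 || nrow(bt) == 0)
    return(structure(NA_real_, empty = TRUE))
  P <- sweep(bp, 2L, spacing, "*")
  T_ <- sweep(bt, 2L, spacing, "*")
  max(directed_percentile(P, T_, q), directed_percentile(T_, P, q))
}

#' Soft Dice loss
#'
#' `1 - mean_r (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)` over the three
#' region channels; the differentiable training objective.
#'
#' @param probs numeric array `(3, D, H, W)` of region probabilities in
#'   `[0, 1]`.
#' @param targets binary array `(3, D, H, W)` of region labels (WT, TC, ET).
#' @param eps smoothing constant (default 1e-5).
#' @return scalar loss.
#' @export
soft_dice_loss <- function(probs, targets, eps = 1e-5) {
  if (!identical(dim(probs), dim(targets)))
    stop_validation("probs and targets must share a shape")
  R <- dim(probs)[1]
  d <- numeric(R)
  for (r in seq_len(R)) {
    p <- probs[r, , , ]; t_ <- targets[r, , , ]
    d[r] <- (2 * sum(p * t_) + eps) / (sum(p) + sum(t_) + eps)
  }
  1 - mean(d)
}

# soft dice loss as a tape node; logits (3,D,H,W) node, targets plain array
bld_soft_dice_loss <- function(tape, logits, targets, eps = 1e-5) {
  probs <- ag_sigmoid(tape, logits)
  R <- dim(targets)[1]
  acc <- NULL
  for (r in seq_len(R)) {
    pr <- ag_index_c(tape, probs, r)
    tr <- ag_const(tape, targets[r, , , , drop = FALSE] * 1)
    inter <- ag_sum(tape, ag_mul(tape, pr, tr))
    tot <- ag_shift(tape, ag_sum(tape, pr), sum(targets[r, , , ]) + eps)
    dr <- ag_div(tape, ag_shift(tape, ag_scale(tape, inter, 2), eps), tot)
    acc <- if (is.null(acc)) dr else ag_add(tape, acc, dr)
  }
  ag_shift(tape, ag_scale(tape, acc, -1 / R), 1)
}

#' Evaluate one case over the WT/TC/ET regions
#'
#' Converts predicted and reference label volumes to the three nested
#' regions and computes Dice, HD95, sensitivity and specificity for each.
#'
#' @param pred_labels,truth integer arrays `(D, H, W)` over \{0, 1, 2, 4\}.
#' @param spacing voxel size in mm.
#' @return data.frame with one row per region (`region`, `dice`, `hd95`,
#'   `sensitivity`, `specificity`, `hd95_defined`).
#' @export
evaluate_case <- function(pred_labels, truth, spacing = c(1, 1, 1)) {
  if (!identical(dim(pred_labels), dim(truth)))
    stop_validation("prediction and truth must share a grid")
  rp <- labels_to_regions(pred_labels)
  rt <- labels_to_regions(truth)
  regions <- c("WT", "TC", "ET")
  out <- lapply(seq_along(regions), function(r) {
    p <- rp[r, , , ]; t_ <- rt[r, , , ]
    cc <- confusion(p, t_)
    h <- hd95(p, t_, spacing)
    data.frame(region = regions[r], dice = dice(cc), hd95 = as.numeric(h),
               sensitivity = sensitivity(cc), specificity = specificity(cc),
               hd95_defined = is.null(attr(h, "empty")))
  })
  do.call(rbind, out)
}
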