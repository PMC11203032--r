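# Group-Normalization Shuffle (GNS) block: a two-branch split/transform/
# concat/shuffle unit in the ShuffleNetV2 style, with the normalization/
# activation layout chosen by ablation: Unit 1 GN+GeLU after the first 1x1x1
# convolution, Unit 2 GN after the 3x3x3 depth-wise convolution, Unit 3
# GN+GeLU after the second 1x1x1 convolution (layout "E"). Placed after the
# windowed-attention encoder blocks, before each downsampling step.

GNS_LAYOUTS <- list(
  A = list(norm = c("bn", "bn", "bn"), act = c(TRUE, FALSE, TRUE)),
  B = list(norm = c("gn", "gn", "gn"), act = c(TRUE, TRUE, TRUE)),
  C = list(norm = c("gn", "gn", "gn"), act = c(FALSE, FALSE, FALSE)),
  D = list(norm = c("gn", "gn", "gn"), act = c(FALSE, TRUE, FALSE)),
  E = list(norm = c("gn", "gn", "gn"), act = c(TRUE, FALSE, TRUE)))

#' Split a feature map into two equal channel halves
#' @param x array `(C, D, H, W)` with even `C`.
#' @return list of two arrays `(C/2, D, H, W)`, original order preserved.
#' @export
channel_split <- function(x) {
  C <- dim(x)[1]
  if (C %% 2 != 0) stop_validation("channel_split requires an even channel count, got %d", C)
  list(x[seq_len(C %/% 2), , , , drop = FALSE],
       x[C %/% 2 + seq_len(C %/% 2), , , , drop = FALSE])
}

shuffle_perm <- function(C, groups) {
  if (C %% groups != 0) stop_validation("groups (%d) must divide channels (%d)", groups, C)
  n <- C %/% groups
  k <- seq_len(C) # view channels as (groups, n), transpose, flatten
  ((k - 1) %% groups) * n + (k - 1) %/% groups + 1
}

#' Channel shuffle
#'
#' Reshapes the channel axis to `(groups, C/groups)`, transposes and
#' flattens: a fixed bijective permutation of channel indices (for `C = 4`,
#' `groups = 2` the new order is 1,3,2,4 in 1-based indexing). Spatial
#' content is untouched.
#'
#' @param x array `(C, D, H, W)`.
#' @param groups number of groups; must divide `C`.
#' @return shuffled array, same shape.
#' @export
channel_shuffle <- function(x, groups) {
  x[shuffle_perm(dim(x)[1], groups), , , , drop = FALSE]
}

#' Group normalization
#'
#' Splits channels into `groups` contiguous groups and normalizes each group
#' to zero mean and unit variance over (channels-in-group x all voxels),
#' followed by a per-channel affine transform. Statistics are computed per
#' sample, so the result is independent of any batching.
#'
#' @param x array `(C, D, H, W)`.
#' @param groups number of groups; must divide `C`.
#' @param gamma,beta per-channel affine parameters (default identity).
#' @param eps variance floor.
#' @return normalized array, same shape.
#' @export
group_normalize <- function(x, groups, gamma = rep(1, dim(x)[1]),
                            beta = numeric(dim(x)[1]), eps = 1e-5) {
  if (dim(x)[1] %% groups != 0)
    stop_validation("groups (%d) must divide channels (%d)", groups, dim(x)[1])
  tape <- ag_tape()
  ag_groupnorm(tape, ag_const(tape, x), groups,
               ag_const(tape, gamma), ag_const(tape, beta), eps = eps)$v
}

# largest divisor of n that is <= cap; used to pick a GN group count that
# always divides the (possibly tiny) branch width
divisor_upto <- function(n, cap) {
  for (g in seq(min(cap, n), 1L)) if (n %% g == 0L) return(as.integer(g))
  1L
}

#' Create GNS weights
#'
#' @param C channel count of the block input (even); each branch uses `C/2`.
#' @param gn_groups group count for GN; defaults to the largest divisor of
#'   `C/2` not exceeding 8.
#' @param seed RNG seed.
#' @param sd init scale override (default: fan-scaled).
#' @return named list of arrays.
#' @export
new_gns_weights <- function(C, gn_groups = NULL, seed = 1L, sd = NULL) {
  if (C %% 2 != 0) stop_validation("GNS requires an even channel count, got %d", C)
  cb <- C %/% 2L
  if (is.null(gn_groups)) gn_groups <- divisor_upto(cb, 8L)
  if (cb %% gn_groups != 0) stop_validation("gn_groups (%d) must divide C/2 (%d)", gn_groups, cb)
  sdl <- sd %||% (1 / sqrt(cb)) # variance-preserving scale
  sdd <- sd %||% sqrt(2 / 27)
  with_seed(seed, list(
    conv1.W = matrix(stats::rnorm(cb * cb, sd = sdl), cb, cb), conv1.b = numeric(cb),
    dwc.w = array(stats::rnorm(cb * 27, sd = sdd), c(cb, 3, 3, 3)), dwc.b = numeric(cb),
    conv2.W = matrix(stats::rnorm(cb * cb, sd = sdl), cb, cb), conv2.b = numeric(cb),
    n1.g = rep(1, cb), n1.b = numeric(cb),
    n2.g = rep(1, cb), n2.b = numeric(cb),
    n3.g = rep(1, cb), n3.b = numeric(cb),
    gn_groups = gn_groups))
}

bld_gns_unit <- function(tape, x, norm, act, gamma, beta, gn_groups) {
  C <- dim(x$v)[1]
  groups <- if (norm == "bn") C else gn_groups # per-channel stats stand in for batch norm at batch size 1
  y <- ag_groupnorm(tape, x, groups, gamma, beta)
  if (act == "relu") y <- ag_relu(tape, y)
  else if (act == "gelu") y <- ag_gelu(tape, y)
  y
}

bld_gns <- function(tape, x, wn, layout = "E", gn_groups = NULL) {
  lay <- GNS_LAYOUTS[[layout]]
  if (is.null(lay)) stop_validation("unknown GNS layout '%s'", layout)
  C <- dim(x$v)[1]
  if (C %% 2 != 0) stop_validation("GNS requires an even channel count, got %d", C)
  cb <- C %/% 2L
  gn_groups <- gn_groups %||% wn$gn_groups %||% divisor_upto(cb, 8L)
  act_of <- function(i) if (!lay$act[i]) "none" else if (lay$norm[i] == "bn") "relu" else "gelu"
  left <- ag_index_c(tape, x, seq_len(cb))
  right <- ag_index_c(tape, x, cb + seq_len(cb))
  r <- bld_channel_linear(tape, right, wn$conv1.W, wn$conv1.b)
  r <- bld_gns_unit(tape, r, lay$norm[1], act_of(1), wn$n1.g, wn$n1.b, gn_groups)
  r <- ag_conv_dw(tape, r, wn$dwc.w, wn$dwc.b)
  r <- bld_gns_unit(tape, r, lay$norm[2], act_of(2), wn$n2.g, wn$n2.b, gn_groups)
  r <- bld_channel_linear(tape, r, wn$conv2.W, wn$conv2.b)
  r <- bld_gns_unit(tape, r, lay$norm[3], act_of(3), wn$n3.g, wn$n3.b, gn_groups)
  cat_ <- ag_concat_c(tape, left, r)
  ag_index_c(tape, cat_, shuffle_perm(C, 2L))
}

#' Group-Normalization Shuffle block
#'
#' Splits the input into two channel halves; the left half passes through
#' unchanged, the right half goes through 1x1x1 conv -> Unit 1 -> 3x3x3
#' depth-wise conv -> Unit 2 -> 1x1x1 conv -> Unit 3; the halves are
#' concatenated and channel-shuffled with two groups. Layout "E"
#' (GN+GeLU / GN / GN+GeLU) is the default; layout "A" reproduces the
#' original shuffle-block unit placement (BN+ReLU / BN / BN+ReLU, with
#' per-channel statistics at batch size one).
#'
#' @param x feature map `(C, D, H, W)`, `C` even.
#' @param weights list from [new_gns_weights()].
#' @param layout one of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @param gn_groups optional GN group-count override.
#' @return feature map of the same shape.
#' @export
gns_block <- function(x, weights, layout = "E", gn_groups = NULL) {
  tape <- ag_tape()
  wn <- lapply(weights[setdiff(names(weights), "gn_groups")], function(a) ag_node(tape, a))
  wn$gn_groups <- weights$gn_groups
  bld_gns(tape, ag_const(tape, x), wn, layout = layout, gn_groups = gn_groups)$v
}
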