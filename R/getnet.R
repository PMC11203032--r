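# Full U-shaped network assembly: patch partition + linear embedding,
# windowed-attention encoder stages with GNS blocks and (depth-halving)
# patch merging, a two-layer ECSA bottleneck, a decoder whose stages fuse
# cross-attention (against bridged encoder K/V) with self-attention, patch
# expanding, and the region classifier. Plus an analytic multiply-accumulate
# counter over the same structure.

#' Network configuration
#'
#' The base hyper-parameters (embedding width, stage count, heads, window)
#' are configuration values with small defaults sized for CPU-scale use;
#' the structural choices fixed by ablation are the defaults `lambda = 0.5`,
#' `fpe_freq = 10000`, `gns_layout = "E"` and `depth_halving = TRUE`.
#'
#' @param input_size spatial input size, scalar or triple; must be divisible
#'   by `patch_size * window * 2^n_stages` along the halved axes.
#' @param in_channels input modalities (4: T1, T2, T1ce, FLAIR).
#' @param out_channels region channels (3: WT, TC, ET).
#' @param patch_size edge of the cubic embedding patch.
#' @param embed_dim token width C0 after linear embedding.
#' @param n_stages number of encoder stages (each ends in patch merging).
#' @param heads attention heads per stage (recycled if scalar); each must
#'   divide the stage width `embed_dim * 2^(s-1)`.
#' @param window attention window edge at token resolution.
#' @param shift shifted-window offset (default half the window).
#' @param mlp_ratio MLP hidden-width multiplier.
#' @param lambda convex weight of the self-attention branch in the decoder
#'   fusion.
#' @param fpe_freq Fourier positional-encoding frequency coefficient.
#' @param gns_layout GNS normalization layout, `"A"`..`"E"`.
#' @param gn_groups optional GN group-count override for GNS.
#' @param bottleneck_depth number of stacked ECSA transformer layers.
#' @param dwc_kernel ECSA depth-wise kernel size.
#' @param depth_halving if `TRUE`, patch merging halves depth, height and
#'   width; if `FALSE` the depth axis is kept (the baseline behaviour) at
#'   the cost of more computation.
#' @param relative_bias include the learned 3D relative-position bias in
#'   window attention.
#' @return object of class `getnet_config`.
#' @export
getnet_config <- function(input_size = 32L, in_channels = 4L, out_channels = 3L,
                          patch_size = 4L, embed_dim = 8L, n_stages = 2L,
                          heads = c(2L, 4L), window = 2L, shift = NULL,
                          mlp_ratio = 4L, lambda = 0.5, fpe_freq = 10000,
                          gns_layout = "E", gn_groups = NULL,
                          bottleneck_depth = 2L, dwc_kernel = 7L,
                          depth_halving = TRUE, relative_bias = TRUE) {
  input_size <- as_triple(input_size)
  window <- as_triple(window)
  shift <- if (is.null(shift)) window %/% 2L else as_triple(shift)
  heads <- rep(as.integer(heads), length.out = n_stages)
  if (any(shift >= window & window > 1L))
    stop_validation("shift must be strictly less than the window size")
  if (lambda < 0 || lambda > 1) stop_validation("lambda must be in [0, 1]")
  if (fpe_freq <= 0) stop_validation("fpe_freq must be positive")
  cfg <- structure(list(
    input_size = input_size, in_channels = as.integer(in_channels),
    out_channels = as.integer(out_channels), patch_size = as.integer(patch_size),
    embed_dim = as.integer(embed_dim), n_stages = as.integer(n_stages),
    heads = heads, window = window, shift = shift,
    mlp_ratio = as.integer(mlp_ratio), lambda = lambda, fpe_freq = fpe_freq,
    gns_layout = gns_layout, gn_groups = gn_groups,
    bottleneck_depth = as.integer(bottleneck_depth),
    dwc_kernel = as.integer(dwc_kernel),
    depth_halving = isTRUE(depth_halving), relative_bias = isTRUE(relative_bias)),
    class = "getnet_config")
  sd_ <- stage_dims(cfg) # validates divisibility
  for (s in seq_len(cfg$n_stages)) {
    C <- sd_$C[s]
    if (C %% heads[s] != 0)
      stop_validation("heads (%d) must divide the stage-%d width (%d)", heads[s], s, C)
    if (any(sd_$dims[[s]] %% window != 0))
      stop_validation("window (%s) must divide the stage-%d token grid (%s)",
                      paste(window, collapse = ","), s,
                      paste(sd_$dims[[s]], collapse = ","))
  }
  cfg
}

# token-grid dimensions and widths per stage; entry n_stages+1 is the bottleneck
stage_dims <- function(cfg) {
  p <- cfg$patch_size
  if (any(cfg$input_size %% p != 0))
    stop_validation("input size must be divisible by the patch size")
  g0 <- cfg$input_size %/% p
  dims <- list(); C <- integer(0)
  g <- g0
  for (s in seq_len(cfg$n_stages + 1L)) {
    dims[[s]] <- g
    C[s] <- cfg$embed_dim * 2L^(s - 1L)
    div <- if (cfg$depth_halving) c(2L, 2L, 2L) else c(1L, 2L, 2L)
    if (any(g %% div != 0))
      stop_validation("stage-%d grid (%s) not divisible for merging", s,
                      paste(g, collapse = ","))
    g <- g %/% div
  }
  list(dims = dims, C = C)
}

## ---- weight initialization ----

flat_set <- function(env, prefix, lst) {
  for (nm in names(lst)) {
    v <- lst[[nm]]
    key <- paste0(prefix, nm)
    if (is.list(v)) flat_set(env, paste0(key, "."), v) else env$w[[key]] <- v
  }
}

#' Initialize network weights
#'
#' Linear and convolution weights use variance-preserving (Glorot) Gaussian
#' init, which keeps activations of order one even at the small widths of
#' the toy profile; normalization gains are 1, biases and the
#' relative-position bias tables 0.
#'
#' @param cfg a [getnet_config()].
#' @param seed integer RNG seed.
#' @return flat named list of parameter arrays.
#' @export
init_getnet_weights <- function(cfg, seed = 1L) {
  sd_ <- stage_dims(cfg)
  env <- new.env(); env$w <- list()
  ctr <- 0L
  sub <- function() { ctr <<- ctr + 1L; as.integer(seed) + ctr }
  rl <- function(a, b) # Glorot fan-scaled init
    with_seed(sub(), matrix(stats::rnorm(a * b, sd = sqrt(2 / (a + b))), a, b))
  attn_w <- function(C, heads) {
    w <- new_attention_weights(C, heads, win = if (cfg$relative_bias) cfg$window else NULL,
                               seed = sub())
    if (!is.null(w$bias_table)) w$bias_table[] <- 0
    w
  }
  block_w <- function(C, heads, decoder = FALSE) {
    hid <- cfg$mlp_ratio * C
    b <- list(ln1.g = rep(1, C), ln1.b = numeric(C))
    if (decoder) {
      b$sa <- attn_w(C, heads)
      b$ca <- list(Wq = rl(C, C), bq = numeric(C), Wo = rl(C, C), bo = numeric(C))
      if (cfg$relative_bias) b$ca$bias_table <- matrix(0, prod(2L * cfg$window - 1L), heads)
    } else {
      b$attn <- attn_w(C, heads)
    }
    b$ln2.g <- rep(1, C); b$ln2.b <- numeric(C)
    b$mlp.W1 <- rl(C, hid); b$mlp.b1 <- numeric(hid)
    b$mlp.W2 <- rl(hid, C); b$mlp.b2 <- numeric(C)
    b
  }
  p3 <- prod(rep(cfg$patch_size, 3L))
  flat_set(env, "embed.", list(W = rl(cfg$in_channels * p3, cfg$embed_dim),
                               b = numeric(cfg$embed_dim)))
  mfac <- if (cfg$depth_halving) 8L else 4L
  for (s in seq_len(cfg$n_stages)) {
    C <- sd_$C[s]
    flat_set(env, sprintf("enc%d.wb.", s), block_w(C, cfg$heads[s]))
    flat_set(env, sprintf("enc%d.swb.", s), block_w(C, cfg$heads[s]))
    gw <- new_gns_weights(C, gn_groups = cfg$gn_groups, seed = sub())
    flat_set(env, sprintf("enc%d.gns.", s), gw[setdiff(names(gw), "gn_groups")])
    flat_set(env, sprintf("enc%d.merge.", s),
             list(W = rl(mfac * C, 2L * C), b = numeric(2L * C)))
  }
  CB <- sd_$C[cfg$n_stages + 1L]
  for (i in seq_len(cfg$bottleneck_depth))
    flat_set(env, sprintf("bot%d.", i),
             new_ecsa_weights(CB, dwc_kernel = cfg$dwc_kernel,
                              hidden = cfg$mlp_ratio * CB, seed = sub()))
  efac <- if (cfg$depth_halving) 4L else 2L
  flat_set(env, "botexpand.", list(W = rl(CB, efac * CB), b = numeric(efac * CB)))
  for (s in seq_len(cfg$n_stages)) {
    C <- sd_$C[s]
    flat_set(env, sprintf("dec%d.wb.", s), block_w(C, cfg$heads[s], decoder = TRUE))
    flat_set(env, sprintf("dec%d.swb.", s), block_w(C, cfg$heads[s], decoder = TRUE))
    if (s >= 2L)
      flat_set(env, sprintf("dec%d.expand.", s),
               list(W = rl(C, efac * C), b = numeric(efac * C)))
  }
  C0 <- cfg$embed_dim
  flat_set(env, "final.", list(W = rl(C0, C0 * p3), b = numeric(C0 * p3)))
  flat_set(env, "cls.", list(W = rl(C0, cfg$out_channels),
                             b = numeric(cfg$out_channels)))
  env$w
}

collect_prefix <- function(wn, prefix) {
  nm <- names(wn)[startsWith(names(wn), prefix)]
  out <- wn[nm]
  names(out) <- substring(nm, nchar(prefix) + 1L)
  out
}

collect_ecsa <- function(wn, prefix) {
  flat <- collect_prefix(wn, prefix)
  out <- flat[!grepl("^g[qkv]\\.", names(flat))]
  for (g in c("gq", "gk", "gv")) {
    sub <- collect_prefix(flat, paste0(g, "."))
    out[[g]] <- sub
  }
  out
}

## ---- tape builders for the structural ops ----

bld_window_partition <- function(tape, x, win) {
  dm <- dim(x$v); n <- dm[2:4] %/% win
  a <- ag_reshape(tape, x, c(dm[1], win[1], n[1], win[2], n[2], win[3], n[3]))
  a <- ag_aperm(tape, a, c(3, 5, 7, 2, 4, 6, 1))
  ag_reshape(tape, a, c(prod(n), prod(win), dm[1]))
}

bld_window_reverse <- function(tape, tok, dims, win) {
  n <- dims %/% win; C <- dim(tok$v)[3]
  a <- ag_reshape(tape, tok, c(n[1], n[2], n[3], win[1], win[2], win[3], C))
  a <- ag_aperm(tape, a, c(7, 4, 1, 5, 2, 6, 3))
  ag_reshape(tape, a, c(C, dims))
}

bld_patch_embed <- function(tape, vol, Wn, bn, p) {
  dm <- dim(vol$v); Cin <- dm[1]; n <- dm[2:4] %/% p
  a <- ag_reshape(tape, vol, c(Cin, p, n[1], p, n[2], p, n[3]))
  a <- ag_aperm(tape, a, c(3, 5, 7, 1, 2, 4, 6))
  a <- ag_reshape(tape, a, c(prod(n), Cin * p^3))
  t <- ag_lin(tape, a, Wn, bn)
  bld_tok_to_fm(tape, t, c(dim(Wn$v)[2], n))
}

bld_patch_merge <- function(tape, x, Wn, bn, halving) {
  dm <- dim(x$v); C <- dm[1]
  if (halving) {
    n <- dm[2:4] %/% 2L
    a <- ag_reshape(tape, x, c(C, 2, n[1], 2, n[2], 2, n[3]))
    a <- ag_aperm(tape, a, c(3, 5, 7, 1, 2, 4, 6))
    a <- ag_reshape(tape, a, c(prod(n), 8L * C))
  } else {
    n <- c(dm[2], dm[3] %/% 2L, dm[4] %/% 2L)
    a <- ag_reshape(tape, x, c(C, dm[2], 2, n[2], 2, n[3]))
    a <- ag_aperm(tape, a, c(2, 4, 6, 1, 3, 5))
    a <- ag_reshape(tape, a, c(prod(n), 4L * C))
  }
  t <- ag_lin(tape, a, Wn, bn)
  bld_tok_to_fm(tape, t, c(dim(Wn$v)[2], n))
}

bld_patch_expand <- function(tape, x, Wn, bn, halving) {
  dm <- dim(x$v); C <- dm[1]; n <- dm[2:4]
  t <- bld_fm_to_tok(tape, x)
  t <- ag_lin(tape, t, Wn, bn) # (nvox, efac*C) with output channel fastest
  if (halving) {
    C2 <- C %/% 2L
    a <- ag_aperm(tape, t, c(2, 1))
    a <- ag_reshape(tape, a, c(C2, 2, 2, 2, n[1], n[2], n[3]))
    a <- ag_aperm(tape, a, c(1, 2, 5, 3, 6, 4, 7))
    ag_reshape(tape, a, c(C2, 2L * n))
  } else {
    C2 <- C %/% 2L
    a <- ag_aperm(tape, t, c(2, 1))
    a <- ag_reshape(tape, a, c(C2, 2, 2, n[1], n[2], n[3]))
    a <- ag_aperm(tape, a, c(1, 4, 2, 5, 3, 6))
    ag_reshape(tape, a, c(C2, n[1], 2L * n[2], 2L * n[3]))
  }
}

bld_final_expand <- function(tape, x, Wn, bn, p) {
  dm <- dim(x$v); C <- dm[1]; n <- dm[2:4]
  t <- bld_fm_to_tok(tape, x)
  t <- ag_lin(tape, t, Wn, bn) # (nvox, C*p^3), channel fastest
  a <- ag_aperm(tape, t, c(2, 1))
  a <- ag_reshape(tape, a, c(C, p, p, p, n[1], n[2], n[3]))
  a <- ag_aperm(tape, a, c(1, 2, 5, 3, 6, 4, 7))
  ag_reshape(tape, a, c(C, p * n))
}

# positional-encoding feature map for a stage, in window-token layout,
# matching any cyclic shift applied before partitioning
fpe_window_tokens <- function(dims, C, freq, win, shift = c(0L, 0L, 0L)) {
  pe <- fourier_positional_encoding(prod(dims), C, freq) # (nvox, C), voxel order D-fastest
  fm <- array(t(pe), c(C, dims))
  if (any(shift != 0)) fm <- cyclic_shift(fm, -shift)
  window_partition(fm, win)
}

# one VT block: pre-norm windowed attention (+ residual) then pre-norm MLP
# (+ residual). Encoder blocks return their per-head K/V for bridging;
# decoder blocks consume bridged K/V through a cross-attention branch fused
# with self-attention by convex combination, FPE and the MLP tail.
bld_vt_block <- function(tape, x, wn, pre, cfg, heads, shifted, decoder = FALSE,
                         bridge = NULL) {
  dm <- dim(x$v)
  dims <- dm[2:4]
  win <- cfg$window
  shift <- if (shifted) cfg$shift else c(0L, 0L, 0L)
  mask <- if (shifted && any(shift > 0)) swin_attention_mask(dims, win, shift) else NULL
  bias_idx <- if (cfg$relative_bias) relative_bias_index(win) else NULL
  t <- bld_fm_to_tok(tape, x)
  t1 <- ag_layernorm(tape, t, wn[[paste0(pre, "ln1.g")]], wn[[paste0(pre, "ln1.b")]])
  f1 <- bld_tok_to_fm(tape, t1, dm)
  if (any(shift > 0)) f1 <- ag_roll_spatial(tape, f1, -shift)
  xw <- bld_window_partition(tape, f1, win)
  K <- V <- NULL
  if (!decoder) {
    r <- bld_mha(tape, xw, collect_prefix(wn, paste0(pre, "attn.")), heads,
                 mask = mask, bias_index = bias_idx)
    att <- r$out; K <- r$K; V <- r$V
  } else {
    sa <- bld_mha(tape, xw, collect_prefix(wn, paste0(pre, "sa.")), heads,
                  mask = mask, bias_index = bias_idx)
    ca <- bld_cross_attention(tape, xw, bridge$K, bridge$V,
                              collect_prefix(wn, paste0(pre, "ca.")), heads,
                              mask = mask, bias_index = bias_idx)
    lam <- cfg$lambda
    att <- ag_add(tape, ag_scale(tape, ca, 1 - lam), ag_scale(tape, sa$out, lam))
    fpe <- fpe_window_tokens(dims, dm[1], cfg$fpe_freq, win, shift)
    att <- ag_add(tape, att, ag_const(tape, fpe))
  }
  wr <- bld_window_reverse(tape, att, dims, win)
  if (any(shift > 0)) wr <- ag_roll_spatial(tape, wr, shift)
  x <- ag_add(tape, x, wr)
  t2 <- bld_fm_to_tok(tape, x)
  h <- ag_layernorm(tape, t2, wn[[paste0(pre, "ln2.g")]], wn[[paste0(pre, "ln2.b")]])
  h <- ag_lin(tape, h, wn[[paste0(pre, "mlp.W1")]], wn[[paste0(pre, "mlp.b1")]])
  h <- ag_gelu(tape, h)
  h <- ag_lin(tape, h, wn[[paste0(pre, "mlp.W2")]], wn[[paste0(pre, "mlp.b2")]])
  x <- ag_add(tape, x, bld_tok_to_fm(tape, h, dm))
  list(x = x, K = K, V = V)
}

# assemble the whole network on a tape; returns the logits node and a state
# record of K/V bridge production/consumption
bld_getnet <- function(tape, wn, vol, cfg) {
  sd_ <- stage_dims(cfg)
  x <- bld_patch_embed(tape, vol, wn[["embed.W"]], wn[["embed.b"]], cfg$patch_size)
  kv <- list()
  state <- list(kv_produced = character(0), kv_consumed = character(0))
  for (s in seq_len(cfg$n_stages)) {
    r1 <- bld_vt_block(tape, x, wn, sprintf("enc%d.wb.", s), cfg, cfg$heads[s], shifted = FALSE)
    r2 <- bld_vt_block(tape, r1$x, wn, sprintf("enc%d.swb.", s), cfg, cfg$heads[s], shifted = TRUE)
    x <- r2$x
    kv[[sprintf("s%d.w", s)]] <- list(K = r1$K, V = r1$V)
    kv[[sprintf("s%d.sw", s)]] <- list(K = r2$K, V = r2$V)
    state$kv_produced <- c(state$kv_produced, sprintf("s%d.w", s), sprintf("s%d.sw", s))
    gw <- collect_prefix(wn, sprintf("enc%d.gns.", s))
    gw$gn_groups <- cfg$gn_groups %||% divisor_upto(sd_$C[s] %/% 2L, 8L)
    x <- bld_gns(tape, x, gw, layout = cfg$gns_layout)
    x <- bld_patch_merge(tape, x, wn[[sprintf("enc%d.merge.W", s)]],
                         wn[[sprintf("enc%d.merge.b", s)]], cfg$depth_halving)
  }
  for (i in seq_len(cfg$bottleneck_depth))
    x <- bld_enhanced_transformer(tape, x, collect_ecsa(wn, sprintf("bot%d.", i)))
  x <- bld_patch_expand(tape, x, wn[["botexpand.W"]], wn[["botexpand.b"]], cfg$depth_halving)
  for (s in rev(seq_len(cfg$n_stages))) {
    r1 <- bld_vt_block(tape, x, wn, sprintf("dec%d.wb.", s), cfg, cfg$heads[s],
                       shifted = FALSE, decoder = TRUE, bridge = kv[[sprintf("s%d.w", s)]])
    r2 <- bld_vt_block(tape, r1$x, wn, sprintf("dec%d.swb.", s), cfg, cfg$heads[s],
                       shifted = TRUE, decoder = TRUE, bridge = kv[[sprintf("s%d.sw", s)]])
    x <- r2$x
    state$kv_consumed <- c(state$kv_consumed, sprintf("s%d.w", s), sprintf("s%d.sw", s))
    if (s >= 2L)
      x <- bld_patch_expand(tape, x, wn[[sprintf("dec%d.expand.W", s)]],
                            wn[[sprintf("dec%d.expand.b", s)]], cfg$depth_halving)
  }
  x <- bld_final_expand(tape, x, wn[["final.W"]], wn[["final.b"]], cfg$patch_size)
  logits <- bld_channel_linear(tape, x, wn[["cls.W"]], wn[["cls.b"]])
  list(logits = logits, state = state)
}

#' Network forward pass
#'
#' @param cfg a [getnet_config()].
#' @param weights flat weight list from [init_getnet_weights()].
#' @param vol input volume `(in_channels, D, H, W)` matching
#'   `cfg$input_size`.
#' @param return_state also return the K/V bridge production/consumption
#'   record.
#' @return region logits `(out_channels, D, H, W)`; with
#'   `return_state = TRUE`, a list with `logits` and `state`.
#' @export
getnet_forward <- function(cfg, weights, vol, return_state = FALSE) {
  if (!identical(dim(vol), c(cfg$in_channels, cfg$input_size)))
    stop_validation("input shape (%s) does not match the configuration (%s)",
                    paste(dim(vol), collapse = "x"),
                    paste(c(cfg$in_channels, cfg$input_size), collapse = "x"))
  tape <- ag_tape()
  wn <- lapply(weights, function(a) ag_node(tape, a))
  r <- bld_getnet(tape, wn, ag_const(tape, vol), cfg)
  if (return_state) list(logits = r$logits$v, state = r$state) else r$logits$v
}

#' Loss and gradients for one case
#'
#' Runs the forward pass, evaluates the soft Dice loss of the sigmoid
#' region probabilities against binary region targets, and backpropagates.
#'
#' @param cfg,weights as in [getnet_forward()].
#' @param vol input volume.
#' @param targets binary region array `(3, D, H, W)`.
#' @return list with `loss` (scalar) and `grads` (flat list matching
#'   `weights`; parameters the loss does not reach get zero gradients).
#' @export
getnet_loss_grad <- function(cfg, weights, vol, targets) {
  tape <- ag_tape()
  wn <- lapply(weights, function(a) ag_node(tape, a))
  r <- bld_getnet(tape, wn, ag_const(tape, vol), cfg)
  loss <- bld_soft_dice_loss(tape, r$logits, targets)
  ag_backward(tape, loss)
  grads <- lapply(names(weights), function(nm) {
    g <- wn[[nm]]$g
    if (is.null(g)) array(0, dim(weights[[nm]]) %||% length(weights[[nm]])) else g
  })
  names(grads) <- names(weights)
  list(loss = as.numeric(loss$v), grads = grads)
}

#' Predict region masks and BraTS labels for one volume
#'
#' Sigmoid, threshold at 0.5, hierarchy enforcement (TC within WT, ET
#' within TC) and BraTS label encoding.
#'
#' @inheritParams getnet_forward
#' @param threshold probability threshold.
#' @return list with `labels` (integer array), `regions` (binary
#'   `(3, D, H, W)` after hierarchy enforcement) and `probs`.
#' @export
getnet_predict <- function(cfg, weights, vol, threshold = 0.5) {
  logits <- getnet_forward(cfg, weights, vol)
  probs <- stats::plogis(logits)
  dim(probs) <- dim(logits)
  regions <- (probs > threshold) * 1
  labels <- regions_to_labels(regions)
  list(labels = labels, regions = labels_to_regions(labels) * 1, probs = probs)
}

## ---- analytic multiply-accumulate counting ----

#' Analytic multiply-accumulate count
#'
#' Counts one MAC per scalar multiply-add in the linear, convolution and
#' attention (score and apply) terms of every layer, without executing the
#' network. Normalizations, activations and elementwise products are not
#' counted; the convention is fixed so that only ordering comparisons are
#' meaningful across conventions.
#'
#' @param cfg a [getnet_config()].
#' @return list with `layers` (data.frame of per-layer counts) and `total`.
#' @export
count_macs <- function(cfg) {
  sd_ <- stage_dims(cfg)
  p3 <- cfg$patch_size^3
  T_ <- prod(cfg$window)
  rows <- list()
  addr <- function(layer, macs) rows[[length(rows) + 1L]] <<- data.frame(layer = layer, macs = macs)
  N0 <- prod(sd_$dims[[1]])
  addr("embed", N0 * cfg$in_channels * p3 * cfg$embed_dim)
  attn_block <- function(N, C, decoder = FALSE) {
    m <- N * C * 3 * C + 2 * N * T_ * C + N * C * C + 2 * N * C * (cfg$mlp_ratio * C)
    if (decoder) m <- m + N * C * C + 2 * N * T_ * C + N * C * C # CA: q proj, scores+apply, out proj
    m
  }
  mfac <- if (cfg$depth_halving) 8L else 4L
  efac <- if (cfg$depth_halving) 4L else 2L
  for (s in seq_len(cfg$n_stages)) {
    N <- prod(sd_$dims[[s]]); C <- sd_$C[s]; cb <- C %/% 2L
    addr(sprintf("enc%d.blocks", s), 2 * attn_block(N, C))
    addr(sprintf("enc%d.gns", s), N * cb * cb * 2 + N * cb * 27)
    Nn <- prod(sd_$dims[[s + 1L]])
    addr(sprintf("enc%d.merge", s), Nn * (mfac * C) * (2L * C))
  }
  NB <- prod(sd_$dims[[cfg$n_stages + 1L]]); CB <- sd_$C[cfg$n_stages + 1L]
  for (i in seq_len(cfg$bottleneck_depth))
    addr(sprintf("bot%d", i),
         2 * NB * CB^2 +              # FL on the Q and K paths
         3 * 2 * CB^2 +               # three channel gates (two linears each)
         NB * CB * cfg$dwc_kernel^3 + # depth-wise convolution
         2 * NB * CB^2 +              # 1x1x1 aggregation + output linear
         2 * NB * CB * (cfg$mlp_ratio * CB))
  addr("botexpand", NB * CB * efac * CB)
  for (s in rev(seq_len(cfg$n_stages))) {
    N <- prod(sd_$dims[[s]]); C <- sd_$C[s]
    addr(sprintf("dec%d.blocks", s), 2 * attn_block(N, C, decoder = TRUE))
    if (s >= 2L) addr(sprintf("dec%d.expand", s), N * C * efac * C)
  }
  N1 <- prod(sd_$dims[[1]])
  addr("final", N1 * cfg$embed_dim * cfg$embed_dim * p3)
  addr("cls", prod(cfg$input_size) * cfg$embed_dim * cfg$out_channels)
  layers <- do.call(rbind, rows)
  list(layers = layers, total = sum(layers$macs))
}
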