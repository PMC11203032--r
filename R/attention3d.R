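# 3D windowed multi-head self-attention machinery: window partition/reverse,
# cyclic shifts, W-MSA / SW-MSA with the shifted-window attention mask,
# encoder->decoder key/value bridging (cross-attention), Fourier positional
# encoding, and the convex-combination fusion sub-block of the decoder.

as_triple <- function(x) {
  x <- as.integer(x)
  if (length(x) == 1L) rep(x, 3L) else x
}

#' Partition a feature map into non-overlapping window tokens
#'
#' @param x numeric array `(C, D, H, W)`.
#' @param win window size, scalar or length-3 `(wd, wh, ww)`; must divide the
#'   spatial dimensions.
#' @return array `(n_windows, T, C)` with `T = wd*wh*ww` tokens per window.
#' @export
window_partition <- function(x, win) {
  win <- as_triple(win)
  dm <- dim(x)
  if (any(dm[2:4] %% win != 0))
    stop_validation("spatial dims (%s) not divisible by window (%s)",
                    paste(dm[2:4], collapse = ","), paste(win, collapse = ","))
  n <- dm[2:4] %/% win
  a <- array(x, c(dm[1], win[1], n[1], win[2], n[2], win[3], n[3]))
  a <- aperm(a, c(3, 5, 7, 2, 4, 6, 1))
  array(a, c(prod(n), prod(win), dm[1]))
}

#' Reassemble window tokens into a feature map
#'
#' Exact inverse of [window_partition()].
#'
#' @param tokens array `(n_windows, T, C)`.
#' @param dims spatial dimensions `(D, H, W)` of the original map.
#' @param win window size used for partitioning.
#' @return array `(C, D, H, W)`.
#' @export
window_reverse <- function(tokens, dims, win) {
  win <- as_triple(win); dims <- as_triple(dims)
  n <- dims %/% win
  C <- dim(tokens)[3]
  a <- array(tokens, c(n[1], n[2], n[3], win[1], win[2], win[3], C))
  a <- aperm(a, c(7, 4, 1, 5, 2, 6, 3))
  array(a, c(C, dims))
}

#' Cyclically shift a feature map along its spatial axes
#'
#' @param x array `(C, D, H, W)`.
#' @param shift integer length-3 shift; positive values roll content toward
#'   higher indices. `cyclic_shift(cyclic_shift(x, s), -s)` is the identity.
#' @return shifted array, same shape.
#' @export
cyclic_shift <- function(x, shift) {
  shift <- as.integer(as_triple(shift))
  dm <- dim(x)
  ix <- function(n, s) ((seq_len(n) - 1 - s) %% n) + 1
  x[, ix(dm[2], shift[1]), ix(dm[3], shift[2]), ix(dm[4], shift[3]), drop = FALSE]
}

# Additive attention mask for shifted windows: tokens that are adjacent only
# through the cyclic wrap-around must not attend to each other. Axis segments
# follow the standard shifted-window construction.
swin_attention_mask <- function(dims, win, shift, neg = -1e9) {
  dims <- as_triple(dims); win <- as_triple(win); shift <- as_triple(shift)
  seg <- function(n, w, s) {
    if (s == 0) return(rep(0L, n))
    p <- seq_len(n) - 1L
    ifelse(p < n - w, 0L, ifelse(p < n - s, 1L, 2L))
  }
  id <- outer(outer(seg(dims[1], win[1], shift[1]) * 9L,
                    seg(dims[2], win[2], shift[2]) * 3L, "+"),
              seg(dims[3], win[3], shift[3]), "+")
  idw <- window_partition(array(id, c(1L, dims)), win) # (nW, T, 1)
  nW <- dim(idw)[1]; T_ <- dim(idw)[2]
  mask <- array(0, c(T_, T_, nW))
  for (w in seq_len(nW)) {
    v <- idw[w, , 1]
    mask[, , w] <- ifelse(outer(v, v, "!=") , neg, 0)
  }
  mask
}

# Relative-position index (T x T) into a ((2wd-1)(2wh-1)(2ww-1))-row bias table,
# matching the token ordering of window_partition (first window axis fastest).
relative_bias_index <- function(win) {
  win <- as_triple(win)
  off <- expand.grid(od = seq_len(win[1]), oh = seq_len(win[2]), ow = seq_len(win[3]))
  T_ <- nrow(off)
  idx <- matrix(0L, T_, T_)
  for (i in seq_len(T_)) {
    rd <- off$od[i] - off$od + win[1] - 1L
    rh <- off$oh[i] - off$oh + win[2] - 1L
    rw <- off$ow[i] - off$ow + win[3] - 1L
    idx[i, ] <- rd + (2L * win[1] - 1L) * (rh + (2L * win[2] - 1L) * rw) + 1L
  }
  idx
}

ag_cols <- function(tape, x, idx) { # select matrix columns
  dm <- dim(x$v)
  v <- x$v[, idx, drop = FALSE]
  ag_node(tape, v, function(g) {
    gf <- matrix(0, dm[1], dm[2])
    gf[, idx] <- g
    ag_accum(x, gf)
  })
}

ag_gather_rows <- function(tape, tab, idx) { # bias table (Nrel, heads) -> (T,T,heads)
  dmt <- dim(tab$v)
  T_ <- nrow(idx)
  v <- array(tab$v[as.vector(idx), ], c(T_, T_, dmt[2]))
  ag_node(tape, v, function(g) {
    gf <- matrix(0, dmt[1], dmt[2])
    gm <- matrix(g, T_ * T_, dmt[2])
    iv <- as.vector(idx)
    for (h in seq_len(dmt[2])) {
      s <- tapply(gm[, h], iv, sum)
      gf[as.integer(names(s)), h] <- s
    }
    ag_accum(tab, gf)
  })
}

#' Create a random window-attention weight set
#'
#' The packed projection `Wqkv` holds the query, key and value maps as
#' consecutive column blocks; `bias_table` is the learned 3D relative-position
#' bias (one row per relative displacement, one column per head), present only
#' when `win` is given.
#'
#' @param C embedding dimension; `heads` must divide it.
#' @param heads number of attention heads.
#' @param win window size (for the bias table) or `NULL` to omit the bias.
#' @param seed RNG seed.
#' @param sd init scale of the projections; default is the
#'   variance-preserving `1/sqrt(C)`.
#' @return named list of arrays.
#' @export
new_attention_weights <- function(C, heads, win = NULL, seed = 1L, sd = NULL) {
  if (C %% heads != 0) stop_validation("heads (%d) must divide dim (%d)", heads, C)
  if (is.null(sd)) sd <- 1 / sqrt(C) # variance-preserving (Glorot) scale
  with_seed(seed, {
    w <- list(Wqkv = matrix(stats::rnorm(C * 3 * C, sd = sd), C, 3 * C),
              bqkv = numeric(3 * C),
              Wo = matrix(stats::rnorm(C * C, sd = sd), C, C),
              bo = numeric(C))
    if (!is.null(win)) {
      win <- as_triple(win)
      w$bias_table <- matrix(0, prod(2L * win - 1L), heads)
    }
    w
  })
}

# Tape builder: windowed multi-head attention on token node (nW, T, C).
# wn: list of weight *nodes* (Wqkv, bqkv, Wo, bo, optionally bias_table).
# Returns out tokens node plus the per-head K and V nodes for bridging.
bld_mha <- function(tape, xw, wn, heads, mask = NULL, bias_index = NULL) {
  dm <- dim(xw$v); nW <- dm[1]; T_ <- dm[2]; C <- dm[3]
  dh <- C %/% heads
  xm <- ag_reshape(tape, xw, c(nW * T_, C))
  qkv <- ag_lin(tape, xm, wn$Wqkv, wn$bqkv)
  split_head <- function(cols) {
    h <- ag_cols(tape, qkv, cols)
    ag_reshape(tape, h, c(nW, T_, dh, heads))
  }
  Q <- split_head(seq_len(C))
  K <- split_head(C + seq_len(C))
  V <- split_head(2L * C + seq_len(C))
  bias <- if (!is.null(bias_index) && !is.null(wn$bias_table))
    ag_gather_rows(tape, wn$bias_table, bias_index) else NULL
  o <- ag_attention(tape, Q, K, V, nW, heads, mask = mask, bias = bias)
  om <- ag_reshape(tape, o, c(nW * T_, C))
  om <- ag_lin(tape, om, wn$Wo, wn$bo)
  list(out = ag_reshape(tape, om, c(nW, T_, C)), K = K, V = V)
}

# Tape builder: cross-attention of decoder queries against bridged K/V nodes.
bld_cross_attention <- function(tape, xw, Kn, Vn, wn, heads, mask = NULL, bias_index = NULL) {
  dm <- dim(xw$v); nW <- dm[1]; T_ <- dm[2]; C <- dm[3]
  dh <- C %/% heads
  if (!identical(dim(Kn$v), c(nW, dim(Kn$v)[2], dh, heads)))
    stop_validation("bridged K/V are not shape-compatible with the decoder stage")
  xm <- ag_reshape(tape, xw, c(nW * T_, C))
  q <- ag_lin(tape, xm, wn$Wq, wn$bq)
  Q <- ag_reshape(tape, q, c(nW, T_, dh, heads))
  bias <- if (!is.null(bias_index) && !is.null(wn$bias_table))
    ag_gather_rows(tape, wn$bias_table, bias_index) else NULL
  o <- ag_attention(tape, Q, Kn, Vn, nW, heads, mask = mask, bias = bias)
  om <- ag_reshape(tape, o, c(nW * T_, C))
  om <- ag_lin(tape, om, wn$Wo, wn$bo)
  ag_reshape(tape, om, c(nW, T_, C))
}

wrap_weights <- function(tape, w) lapply(w, function(a) ag_node(tape, a))

#' Window-based multi-head self-attention (W-MSA)
#'
#' Standard scaled-dot-product multi-head attention computed independently
#' within each window; attention weights per query are a probability vector
#' over the window's (unmasked) tokens. The per-head key and value arrays are
#' returned for bridging to the matching decoder stage.
#'
#' @param tokens array `(n_windows, T, C)` from [window_partition()].
#' @param weights list from [new_attention_weights()].
#' @param heads number of heads (must divide `C`).
#' @param mask optional additive mask `(T, T, n_windows)` (0 or large
#'   negative).
#' @param bias_index optional `(T, T)` relative-position index matrix; used
#'   with `weights$bias_table`.
#' @return list with `out` `(n_windows, T, C)`, `K`, `V`
#'   `(n_windows, T, dh, heads)`, and `probs`, the attention probabilities
#'   `(T, T, n_windows, heads)`.
#' @export
wmsa <- function(tokens, weights, heads, mask = NULL, bias_index = NULL) {
  tape <- ag_tape()
  wn <- wrap_weights(tape, weights)
  r <- bld_mha(tape, ag_const(tape, tokens), wn, heads, mask = mask, bias_index = bias_index)
  probs <- NULL
  for (i in seq_len(tape$k)) {
    p <- attr(tape$nodes[[i]], "probs")
    if (!is.null(p)) probs <- p
  }
  list(out = r$out$v, K = r$K$v, V = r$V$v, probs = probs)
}

#' Shifted-window multi-head self-attention (SW-MSA)
#'
#' Cyclically shifts the feature map by `-shift`, applies masked window
#' attention (pairs adjacent only through the wrap-around are masked out),
#' and shifts back. With `shift = 0` this is exactly W-MSA.
#'
#' @param x feature map `(C, D, H, W)`.
#' @param weights list from [new_attention_weights()].
#' @param heads number of heads.
#' @param win window size (scalar or triple).
#' @param shift shift per axis, strictly less than `win`.
#' @param bias_index optional relative-position index matrix.
#' @return list with `out` `(C, D, H, W)`, `K`, `V` per-head arrays and
#'   `probs`.
#' @export
swmsa <- function(x, weights, heads, win, shift, bias_index = NULL) {
  win <- as_triple(win); shift <- as_triple(shift)
  if (any(shift >= win)) stop_validation("shift must be strictly less than the window size")
  dm <- dim(x)[2:4]
  xs <- cyclic_shift(x, -shift)
  mask <- if (all(shift == 0)) NULL else swin_attention_mask(dm, win, shift)
  r <- wmsa(window_partition(xs, win), weights, heads, mask = mask, bias_index = bias_index)
  out <- cyclic_shift(window_reverse(r$out, dm, win), shift)
  list(out = out, K = r$K, V = r$V, probs = r$probs)
}

#' Cross-attention against bridged encoder keys/values
#'
#' Decoder queries (projected from `tokens`) attend to the encoder's
#' per-head key/value arrays delivered over the skip bridge. If `K`/`V`
#' equal the decoder's own key/value projections, the result equals
#' self-attention.
#'
#' @param tokens decoder tokens `(n_windows, T, C)`.
#' @param bridged list with per-head arrays `K`, `V` `(n_windows, Tk, dh,
#'   heads)`.
#' @param weights list with `Wq`, `bq`, `Wo`, `bo` (and optionally
#'   `bias_table`).
#' @param heads number of heads.
#' @param mask optional additive mask.
#' @param bias_index optional relative-position index matrix.
#' @return output tokens `(n_windows, T, C)`.
#' @export
cross_attention <- function(tokens, bridged, weights, heads, mask = NULL, bias_index = NULL) {
  tape <- ag_tape()
  wn <- wrap_weights(tape, weights)
  o <- bld_cross_attention(tape, ag_const(tape, tokens),
                           ag_const(tape, bridged$K), ag_const(tape, bridged$V),
                           wn, heads, mask = mask, bias_index = bias_index)
  o$v
}

#' Sinusoidal Fourier positional encoding
#'
#' For position `p` (0-based) and channel pair `i`, the code is
#' `sin(p / freq^(2i/dim))` and `cos(p / freq^(2i/dim))`: wavelengths form a
#' geometric progression controlled by the frequency coefficient.
#'
#' @param n_positions number of positions.
#' @param dim embedding dimension (even).
#' @param freq frequency coefficient (default 10000, the value used
#'   throughout the network).
#' @return matrix `(n_positions, dim)` with entries in `[-1, 1]`.
#' @export
fourier_positional_encoding <- function(n_positions, dim, freq = 10000) {
  if (dim %% 2 != 0) stop_validation("encoding dim must be even")
  if (freq <= 0) stop_validation("freq must be positive")
  p <- seq_len(n_positions) - 1
  i <- seq_len(dim %/% 2) - 1
  div <- freq^(2 * i / dim)
  ang <- outer(p, div, "/")
  pe <- matrix(0, n_positions, dim)
  pe[, 2 * i + 1] <- sin(ang)
  pe[, 2 * i + 2] <- cos(ang)
  pe
}

#' Create weights for the fusion sub-block
#' @param C embedding dimension.
#' @param hidden MLP hidden width (default `4 * C`).
#' @param seed RNG seed.
#' @return named list with layer-norm and MLP parameters.
#' @export
new_fuse_weights <- function(C, hidden = 4L * C, seed = 1L) {
  with_seed(seed, list(
    ln.g = rep(1, C), ln.b = numeric(C),
    W1 = matrix(stats::rnorm(C * hidden, sd = sqrt(2 / (C + hidden))), C, hidden),
    b1 = numeric(hidden),
    W2 = matrix(stats::rnorm(hidden * C, sd = sqrt(2 / (C + hidden))), hidden, C),
    b2 = numeric(C)))
}

# Tape builder for the fusion tail: y = comb + FPE; out = y + MLP(LN(y)).
bld_fuse_tail <- function(tape, comb, fpe, wn) {
  y <- ag_add(tape, comb, ag_const(tape, fpe))
  h <- ag_layernorm(tape, y, wn$ln.g, wn$ln.b)
  h <- ag_lin(tape, h, wn$W1, wn$b1)
  h <- ag_gelu(tape, h)
  h <- ag_lin(tape, h, wn$W2, wn$b2)
  ag_add(tape, y, h)
}

#' Fuse cross- and self-attention branches
#'
#' Convex combination `(1 - lambda) * ca + lambda * sa`, followed by additive
#' Fourier positional encoding (positions are the row indices), layer
#' normalization and an MLP with residual connection. With `lambda = 1` the
#' combination equals the self-attention branch; with `lambda = 0` the
#' cross-attention branch.
#'
#' @param ca,sa token matrices `(n, C)` from the two branches.
#' @param weights list from [new_fuse_weights()].
#' @param lambda convex weight of the self-attention branch in `[0, 1]`
#'   (default 0.5, the ablation optimum).
#' @param freq Fourier-encoding frequency coefficient (default 10000).
#' @return fused token matrix `(n, C)`.
#' @export
fuse <- function(ca, sa, weights, lambda = 0.5, freq = 10000) {
  if (!identical(dim(ca), dim(sa))) stop_validation("ca and sa must share a shape")
  if (lambda < 0 || lambda > 1) stop_validation("lambda must be in [0, 1]")
  tape <- ag_tape()
  wn <- wrap_weights(tape, weights)
  comb <- ag_add(tape, ag_scale(tape, ag_const(tape, ca), 1 - lambda),
                 ag_scale(tape, ag_const(tape, sa), lambda))
  fpe <- fourier_positional_encoding(nrow(ca), ncol(ca), freq)
  bld_fuse_tail(tape, comb, fpe, wn)$v
}
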