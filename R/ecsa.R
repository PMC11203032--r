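# Enhanced Channel Self-Attention (ECSA) and its pre-norm transformer
# wrapper, used twice in the bottleneck. The block gates the channels of
# query/key/value paths with squeeze-style sigmoid gates, mixes the gated
# query-key product through a large-kernel (7x7x7) depth-wise convolution and
# a 1x1x1 channel-aggregation convolution, normalizes with a channel softmax,
# and gates the value path with the result.

#' Create ECSA weights
#'
#' @param C channel count.
#' @param dwc_kernel depth-wise kernel size (default 7).
#' @param hidden MLP hidden width of the transformer wrapper (default `4*C`).
#' @param seed RNG seed.
#' @param sd init scale override (default: fan-scaled).
#' @return named list of arrays; gates (`gq`, `gk`, `gv`) each hold the two
#'   linear maps of `sigmoid(FL(ReLU(FL(AP(x)))))`.
#' @export
new_ecsa_weights <- function(C, dwc_kernel = 7L, hidden = 4L * C, seed = 1L, sd = NULL) {
  with_seed(seed, {
    lin <- function(a, b) # variance-preserving (Glorot) scale unless overridden
      matrix(stats::rnorm(a * b, sd = sd %||% sqrt(2 / (a + b))), a, b)
    gate <- function() list(W1 = lin(C, C), b1 = numeric(C), W2 = lin(C, C), b2 = numeric(C))
    list(ln1.g = rep(1, C), ln1.b = numeric(C),
         flq.W = lin(C, C), flq.b = numeric(C),
         flk.W = lin(C, C), flk.b = numeric(C),
         gq = gate(), gk = gate(), gv = gate(),
         dwc.w = array(stats::rnorm(C * dwc_kernel^3, sd = sd %||% sqrt(2 / dwc_kernel^3)),
                       c(C, dwc_kernel, dwc_kernel, dwc_kernel)),
         dwc.b = numeric(C),
         conv.W = lin(C, C), conv.b = numeric(C),
         flo.W = lin(C, C), flo.b = numeric(C),
         ln2.g = rep(1, C), ln2.b = numeric(C),
         mlp.W1 = lin(C, hidden), mlp.b1 = numeric(hidden),
         mlp.W2 = lin(hidden, C), mlp.b2 = numeric(C))
  })
}

# feature map (C,D,H,W) node -> token matrix (nvox, C) node and back
bld_fm_to_tok <- function(tape, x) {
  dm <- dim(x$v)
  ag_aperm(tape, ag_reshape(tape, x, c(dm[1], prod(dm[2:4]))), c(2, 1))
}
bld_tok_to_fm <- function(tape, t, dm) {
  ag_reshape(tape, ag_aperm(tape, t, c(2, 1)), dm)
}

# channel-wise linear (1x1x1 convolution) on a feature-map node
bld_channel_linear <- function(tape, x, Wn, bn = NULL) {
  dm <- dim(x$v)
  t <- bld_fm_to_tok(tape, x)
  t <- ag_lin(tape, t, Wn, bn)
  bld_tok_to_fm(tape, t, c(dim(Wn$v)[2], dm[2:4]))
}

bld_channel_gate <- function(tape, x, gn) {
  p <- ag_gap(tape, x) # length-C vector node
  pm <- ag_reshape(tape, p, c(1L, length(p$v)))
  h <- ag_relu(tape, ag_lin(tape, pm, gn$W1, gn$b1))
  h <- ag_sigmoid(tape, ag_lin(tape, h, gn$W2, gn$b2))
  ag_reshape(tape, h, length(h$v)) # back to vector
}

#' Squeeze-style channel gate
#'
#' `sigmoid(FL(ReLU(FL(AP(x)))))` where AP is global spatial average pooling:
#' one weight per channel, strictly in (0, 1), invariant to any permutation
#' of spatial positions.
#'
#' @param x feature map `(C, D, H, W)`.
#' @param gate list with `W1`, `b1`, `W2`, `b2` (two channel-space linear
#'   maps).
#' @return numeric vector of length `C`.
#' @export
channel_gate <- function(x, gate) {
  tape <- ag_tape()
  gn <- list(W1 = ag_const(tape, gate$W1), b1 = ag_const(tape, gate$b1),
             W2 = ag_const(tape, gate$W2), b2 = ag_const(tape, gate$b2))
  as.vector(bld_channel_gate(tape, ag_const(tape, x), gn)$v)
}

# softmax over the channel axis at every voxel
bld_channel_softmax <- function(tape, x) {
  dm <- dim(x$v)
  t <- bld_fm_to_tok(tape, x) # (nvox, C): rows are voxels
  t <- ag_softmax_rows(tape, t)
  bld_tok_to_fm(tape, t, dm)
}

# The ECSA body. wn is a list of weight nodes mirroring new_ecsa_weights().
bld_ecsa <- function(tape, x, wn) {
  qf <- bld_channel_linear(tape, x, wn$flq.W, wn$flq.b) # FL(x) for the Q path
  kf <- bld_channel_linear(tape, x, wn$flk.W, wn$flk.b) # FL(x) for the K path
  Qw <- bld_channel_gate(tape, qf, wn$gq)
  Kw <- bld_channel_gate(tape, kf, wn$gk)
  Vw <- bld_channel_gate(tape, x, wn$gv)
  Qp <- ag_mul_channel(tape, qf, Qw)
  Kp <- ag_mul_channel(tape, kf, Kw)
  Vp <- ag_mul_channel(tape, x, Vw)
  z <- ag_mul(tape, Kp, Qp) # Hadamard product of the gated paths
  z <- ag_conv_dw(tape, z, wn$dwc.w, wn$dwc.b) # 7x7x7 depth-wise, local context
  z <- bld_channel_linear(tape, z, wn$conv.W, wn$conv.b) # 1x1x1 aggregation
  z <- bld_channel_softmax(tape, z)
  z <- ag_mul(tape, z, Vp)
  bld_channel_linear(tape, z, wn$flo.W, wn$flo.b)
}

wrap_ecsa_weights <- function(tape, w) {
  wn <- lapply(w[setdiff(names(w), c("gq", "gk", "gv"))], function(a) ag_node(tape, a))
  for (g in c("gq", "gk", "gv")) wn[[g]] <- lapply(w[[g]], function(a) ag_node(tape, a))
  wn
}

#' Enhanced Channel Self-Attention forward pass
#'
#' Computes the gated channel attention: per-channel gates for the query, key
#' and value paths; Hadamard product of the gated query and key features;
#' 7x7x7 depth-wise convolution and 1x1x1 aggregation; channel softmax; gate
#' onto the value path; output linear. Shape preserving.
#'
#' @param x feature map `(C, D, H, W)`.
#' @param weights list from [new_ecsa_weights()].
#' @return feature map of the same shape.
#' @export
ecsa_forward <- function(x, weights) {
  if (dim(x)[1] != nrow(weights$flq.W))
    stop_validation("channel count %d does not match weights (%d)",
                    dim(x)[1], nrow(weights$flq.W))
  tape <- ag_tape()
  bld_ecsa(tape, ag_const(tape, x), wrap_ecsa_weights(tape, weights))$v
}

# Pre-norm transformer wrapper: y = ECSA(LN(x)) + x; Z = y + MLP(LN(y)).
bld_enhanced_transformer <- function(tape, x, wn) {
  dm <- dim(x$v)
  t <- bld_fm_to_tok(tape, x)
  t1 <- ag_layernorm(tape, t, wn$ln1.g, wn$ln1.b)
  y <- ag_add(tape, x, bld_ecsa(tape, bld_tok_to_fm(tape, t1, dm), wn))
  ty <- bld_fm_to_tok(tape, y)
  h <- ag_layernorm(tape, ty, wn$ln2.g, wn$ln2.b)
  h <- ag_lin(tape, h, wn$mlp.W1, wn$mlp.b1)
  h <- ag_gelu(tape, h)
  h <- ag_lin(tape, h, wn$mlp.W2, wn$mlp.b2)
  ag_add(tape, y, bld_tok_to_fm(tape, h, dm))
}

#' Enhanced Transformer layer (ECSA with pre-norm residuals)
#'
#' `y = ECSA(LN(x)) + x; Z = y + MLP(LN(y))` — the conventional pre-norm
#' residual pair, with ECSA as the token mixer.
#'
#' @inheritParams ecsa_forward
#' @return feature map of the same shape.
#' @export
enhanced_transformer <- function(x, weights) {
  tape <- ag_tape()
  bld_enhanced_transformer(tape, ag_const(tape, x), wrap_ecsa_weights(tape, weights))$v
}
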