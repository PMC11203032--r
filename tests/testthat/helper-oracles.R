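# Independent loop-based oracles. These re-derive every block directly from
# its defining formulas with explicit scalar loops, sharing no code with the
# package implementation (which is vectorized and tape-based).

o_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  out <- x
  for (i in seq_len(nrow(x))) {
    mu <- mean(x[i, ])
    va <- mean((x[i, ] - mu)^2)
    out[i, ] <- (x[i, ] - mu) / sqrt(va + eps) * gamma + beta
  }
  out
}

o_gelu <- function(x) x * pnorm(x)

o_mlp <- function(x, W1, b1, W2, b2) {
  h <- x %*% W1
  for (j in seq_len(ncol(h))) h[, j] <- h[, j] + b1[j]
  h <- o_gelu(h)
  h <- h %*% W2
  for (j in seq_len(ncol(h))) h[, j] <- h[, j] + b2[j]
  h
}

o_softmax_vec <- function(s) { e <- exp(s - max(s)); e / sum(e) }

# multi-head attention in one window: X (T, C) queries, XK (Tk, C) keys/values
# (XK = X for self-attention). Returns list(out, K, V, probs).
o_window_attention <- function(X, w, heads, mask_row = NULL, bias = NULL,
                               KV = NULL) {
  T_ <- nrow(X); C <- ncol(X); dh <- C %/% heads
  Wq <- w$Wqkv[, 1:C]; Wk <- w$Wqkv[, C + 1:C]; Wv <- w$Wqkv[, 2 * C + 1:C]
  bq <- w$bqkv[1:C]; bk <- w$bqkv[C + 1:C]; bv <- w$bqkv[2 * C + 1:C]
  Q <- X %*% Wq; for (j in 1:C) Q[, j] <- Q[, j] + bq[j]
  if (is.null(KV)) {
    K <- X %*% Wk; for (j in 1:C) K[, j] <- K[, j] + bk[j]
    V <- X %*% Wv; for (j in 1:C) V[, j] <- V[, j] + bv[j]
  } else { K <- KV$K; V <- KV$V }
  Tk <- nrow(K)
  out <- matrix(0, T_, C)
  probs <- array(0, c(T_, Tk, heads))
  for (h in seq_len(heads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    for (i in seq_len(T_)) {
      s <- numeric(Tk)
      for (j in seq_len(Tk)) {
        s[j] <- sum(Q[i, cols] * K[j, cols]) / sqrt(dh)
        if (!is.null(bias)) s[j] <- s[j] + bias[i, j, h]
        if (!is.null(mask_row)) s[j] <- s[j] + mask_row[i, j]
      }
      p <- o_softmax_vec(s)
      probs[i, , h] <- p
      for (j in seq_len(Tk)) out[i, cols] <- out[i, cols] + p[j] * V[j, cols]
    }
  }
  out <- out %*% w$Wo
  for (j in 1:C) out[, j] <- out[, j] + w$bo[j]
  list(out = out, K = K, V = V, probs = probs)
}

# cross-attention oracle: queries from X through w$Wq; K/V supplied per head
# as (T, dh, heads) slices of a window
o_cross_attention <- function(X, Kh, Vh, w, heads, mask_row = NULL) {
  T_ <- nrow(X); C <- ncol(X); dh <- C %/% heads
  Q <- X %*% w$Wq; for (j in 1:C) Q[, j] <- Q[, j] + w$bq[j]
  Tk <- dim(Kh)[1]
  out <- matrix(0, T_, C)
  for (h in seq_len(heads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    for (i in seq_len(T_)) {
      s <- numeric(Tk)
      for (j in seq_len(Tk)) {
        s[j] <- sum(Q[i, cols] * Kh[j, , h]) / sqrt(dh)
        if (!is.null(mask_row)) s[j] <- s[j] + mask_row[i, j]
      }
      p <- o_softmax_vec(s)
      for (j in seq_len(Tk)) out[i, cols] <- out[i, cols] + p[j] * Vh[j, , h]
    }
  }
  out <- out %*% w$Wo
  for (j in 1:C) out[, j] <- out[, j] + w$bo[j]
  out
}

# shifted-window attention oracle on a full feature map, deriving the valid
# token pairs independently: after shifting by -s, a token's original
# coordinate on an axis is wrapped iff its shifted position lies in the last
# s positions; two tokens in the same window may attend iff their wrapped
# status agrees on every axis.
o_swmsa <- function(x, w, heads, win, shift) {
  dm <- dim(x); C <- dm[1]; dims <- dm[2:4]
  ix <- function(n, s) ((seq_len(n) - 1 - s) %% n) + 1
  xs <- x[, ix(dims[1], -shift[1]), ix(dims[2], -shift[2]), ix(dims[3], -shift[3]), drop = FALSE]
  n <- dims %/% win
  out_s <- array(0, dim(xs))
  for (wd in seq_len(n[1])) for (wh in seq_len(n[2])) for (ww in seq_len(n[3])) {
    dspan <- (wd - 1) * win[1] + seq_len(win[1])
    hspan <- (wh - 1) * win[2] + seq_len(win[2])
    wspan <- (ww - 1) * win[3] + seq_len(win[3])
    coords <- expand.grid(d = dspan, h = hspan, w = wspan)
    T_ <- nrow(coords)
    X <- matrix(0, T_, C)
    for (t in seq_len(T_)) X[t, ] <- xs[, coords$d[t], coords$h[t], coords$w[t]]
    wrapped <- cbind(coords$d > dims[1] - shift[1],
                     coords$h > dims[2] - shift[2],
                     coords$w > dims[3] - shift[3])
    mask_row <- matrix(0, T_, T_)
    for (i in seq_len(T_)) for (j in seq_len(T_))
      if (any(wrapped[i, ] != wrapped[j, ])) mask_row[i, j] <- -1e9
    r <- o_window_attention(X, w, heads, mask_row = mask_row)
    for (t in seq_len(T_)) out_s[, coords$d[t], coords$h[t], coords$w[t]] <- r$out[t, ]
  }
  out_s[, ix(dims[1], shift[1]), ix(dims[2], shift[2]), ix(dims[3], shift[3]), drop = FALSE]
}

## ---- ECSA oracle (direct evaluation of the defining equations) ----

o_channel_linear <- function(x, W, b) { # 1x1x1 conv: out[c2] = sum_c x[c] W[c,c2] + b[c2]
  C2 <- ncol(W); dm <- dim(x)
  out <- array(0, c(C2, dm[2:4]))
  for (d in seq_len(dm[2])) for (h in seq_len(dm[3])) for (w_ in seq_len(dm[4]))
    out[, d, h, w_] <- as.vector(x[, d, h, w_] %*% W) + b
  out
}

o_gate <- function(x, g) {
  C <- dim(x)[1]
  ap <- numeric(C)
  for (c in seq_len(C)) ap[c] <- mean(x[c, , , ])
  h <- as.vector(ap %*% g$W1) + g$b1
  h <- pmax(h, 0)
  1 / (1 + exp(-(as.vector(h %*% g$W2) + g$b2)))
}

o_conv_dw <- function(x, w, b) {
  dm <- dim(x); C <- dm[1]; k <- dim(w)[2]; p <- (k - 1) %/% 2
  out <- array(0, dm)
  for (c in seq_len(C)) for (d in seq_len(dm[2])) for (h in seq_len(dm[3])) for (w_ in seq_len(dm[4])) {
    acc <- b[c]
    for (i in seq_len(k)) for (j in seq_len(k)) for (l in seq_len(k)) {
      dd <- d + i - 1 - p; hh <- h + j - 1 - p; ww <- w_ + l - 1 - p
      if (dd >= 1 && dd <= dm[2] && hh >= 1 && hh <= dm[3] && ww >= 1 && ww <= dm[4])
        acc <- acc + w[c, i, j, l] * x[c, dd, hh, ww]
    }
    out[c, d, h, w_] <- acc
  }
  out
}

o_channel_softmax <- function(x) {
  dm <- dim(x)
  out <- x
  for (d in seq_len(dm[2])) for (h in seq_len(dm[3])) for (w_ in seq_len(dm[4]))
    out[, d, h, w_] <- o_softmax_vec(x[, d, h, w_])
  out
}

o_ecsa <- function(x, w) {
  qf <- o_channel_linear(x, w$flq.W, w$flq.b)
  kf <- o_channel_linear(x, w$flk.W, w$flk.b)
  Qw <- o_gate(qf, w$gq); Kw <- o_gate(kf, w$gk); Vw <- o_gate(x, w$gv)
  dm <- dim(x)
  Qp <- qf; Kp <- kf; Vp <- x
  for (c in seq_len(dm[1])) {
    Qp[c, , , ] <- Qw[c] * qf[c, , , ]
    Kp[c, , , ] <- Kw[c] * kf[c, , , ]
    Vp[c, , , ] <- Vw[c] * x[c, , , ]
  }
  z <- Kp * Qp
  z <- o_conv_dw(z, w$dwc.w, w$dwc.b)
  z <- o_channel_linear(z, w$conv.W, w$conv.b)
  z <- o_channel_softmax(z)
  o_channel_linear(z * Vp, w$flo.W, w$flo.b)
}

o_ln_fm <- function(x, gamma, beta, eps = 1e-5) { # layer norm over channels per voxel
  dm <- dim(x)
  out <- x
  for (d in seq_len(dm[2])) for (h in seq_len(dm[3])) for (w_ in seq_len(dm[4])) {
    v <- x[, d, h, w_]
    mu <- mean(v); va <- mean((v - mu)^2)
    out[, d, h, w_] <- (v - mu) / sqrt(va + eps) * gamma + beta
  }
  out
}

o_enhanced_transformer <- function(x, w) {
  y <- x + o_ecsa(o_ln_fm(x, w$ln1.g, w$ln1.b), w)
  dm <- dim(x)
  t <- o_ln_fm(y, w$ln2.g, w$ln2.b)
  z <- y
  for (d in seq_len(dm[2])) for (h in seq_len(dm[3])) for (w_ in seq_len(dm[4])) {
    hv <- o_gelu(as.vector(t[, d, h, w_] %*% w$mlp.W1) + w$mlp.b1)
    z[, d, h, w_] <- y[, d, h, w_] + as.vector(hv %*% w$mlp.W2) + w$mlp.b2
  }
  z
}

## ---- GNS oracle ----

o_groupnorm <- function(x, groups, gamma, beta, eps = 1e-5) {
  C <- dim(x)[1]; cg <- C %/% groups
  out <- x
  for (g in seq_len(groups)) {
    ch <- (g - 1) * cg + seq_len(cg)
    vals <- x[ch, , , ]
    mu <- mean(vals); va <- mean((vals - mu)^2)
    for (c in ch)
      out[c, , , ] <- (x[c, , , ] - mu) / sqrt(va + eps) * gamma[c] + beta[c]
  }
  out
}

o_gns <- function(x, w, layout = "E") {
  C <- dim(x)[1]; cb <- C %/% 2
  left <- x[seq_len(cb), , , , drop = FALSE]
  r <- x[cb + seq_len(cb), , , , drop = FALSE]
  unit <- function(z, kind) {
    z <- switch(kind,
      "gn+gelu" = o_gelu(o_groupnorm(z, w$gn_groups, rep(1, cb), numeric(cb))),
      "gn" = o_groupnorm(z, w$gn_groups, rep(1, cb), numeric(cb)),
      "bn+relu" = pmax(o_groupnorm(z, cb, rep(1, cb), numeric(cb)), 0),
      "bn" = o_groupnorm(z, cb, rep(1, cb), numeric(cb)))
    z
  }
  kinds <- switch(layout,
    A = c("bn+relu", "bn", "bn+relu"),
    E = c("gn+gelu", "gn", "gn+gelu"))
  r <- o_channel_linear(r, w$conv1.W, w$conv1.b)
  r <- unit(r, kinds[1])
  r <- o_conv_dw(r, w$dwc.w, w$dwc.b)
  r <- unit(r, kinds[2])
  r <- o_channel_linear(r, w$conv2.W, w$conv2.b)
  r <- unit(r, kinds[3])
  cat_ <- array(0, dim(x))
  cat_[seq_len(cb), , , ] <- left
  cat_[cb + seq_len(cb), , , ] <- r
  # group-transpose permutation with 2 groups, derived directly
  perm <- integer(C)
  for (k in seq_len(C)) perm[k] <- ((k - 1) %% 2) * cb + (k - 1) %/% 2 + 1
  cat_[perm, , , , drop = FALSE]
}

## ---- metric oracles ----

o_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] != 0; t_ <- truth[i] != 0
    if (p && t_) tp <- tp + 1L else if (p) fp <- fp + 1L
    else if (t_) fn <- fn + 1L else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

o_boundary <- function(mask) {
  dm <- dim(mask)
  out <- array(FALSE, dm)
  for (d in seq_len(dm[1])) for (h in seq_len(dm[2])) for (w_ in seq_len(dm[3])) {
    if (!mask[d, h, w_]) next
    nb <- FALSE
    for (off in list(c(-1,0,0), c(1,0,0), c(0,-1,0), c(0,1,0), c(0,0,-1), c(0,0,1))) {
      dd <- d + off[1]; hh <- h + off[2]; ww <- w_ + off[3]
      if (dd < 1 || dd > dm[1] || hh < 1 || hh > dm[2] || ww < 1 || ww > dm[3] ||
          !mask[dd, hh, ww]) { nb <- TRUE; break }
    }
    out[d, h, w_] <- nb
  }
  out
}

o_hd95 <- function(pred, truth, spacing = c(1, 1, 1), q = 0.95) {
  A <- which(o_boundary(pred != 0), arr.ind = TRUE)
  B <- which(o_boundary(truth != 0), arr.ind = TRUE)
  if (nrow(A) == 0 || nrow(B) == 0) return(NA_real_)
  directed <- function(S1, S2) {
    d <- numeric(nrow(S1))
    for (i in seq_len(nrow(S1))) {
      best <- Inf
      for (j in seq_len(nrow(S2)))
        best <- min(best, sqrt(sum(((S1[i, ] - S2[j, ]) * spacing)^2)))
      d[i] <- best
    }
    quantile(d, q, names = FALSE, type = 7)
  }
  max(directed(A, B), directed(B, A))
}

## ---- shared fixtures ----

rand_fm <- function(C, sp, seed) {
  set.seed(seed)
  array(rnorm(C * prod(rep(sp, 3))), c(C, sp, sp, sp))
}
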