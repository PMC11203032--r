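# Minimal reverse-mode autodiff over dense R arrays.
#
# A tape records nodes in creation order; ag_backward() walks it in reverse.
# Nodes are environments: $v value array, $g accumulated gradient (lazily
# allocated), $bk backward closure mapping the node's gradient onto its
# parents. Only the primitives the network needs are provided; each backward
# rule is the standard analytic one.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$k <- 0L
  t
}

ag_node <- function(tape, value, backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$v <- value
  n$g <- NULL
  n$bk <- backward
  k <- tape$k + 1L
  if (k > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[k]] <- n
  tape$k <- k
  n
}

ag_const <- function(tape, value) ag_node(tape, value)

ag_accum <- function(node, g) {
  node$g <- if (is.null(node$g)) g else node$g + g
  invisible(NULL)
}

#' @keywords internal
ag_backward <- function(tape, root) {
  root$g <- if (is.null(dim(root$v))) rep(1, length(root$v)) else array(1, dim(root$v))
  for (i in rev(seq_len(tape$k))) {
    n <- tape$nodes[[i]]
    if (!is.null(n$g) && !is.null(n$bk)) n$bk(n$g)
  }
  invisible(NULL)
}

## ---- elementwise ----

ag_add <- function(tape, a, b) {
  ag_node(tape, a$v + b$v, function(g) { ag_accum(a, g); ag_accum(b, g) })
}

ag_sub <- function(tape, a, b) {
  ag_node(tape, a$v - b$v, function(g) { ag_accum(a, g); ag_accum(b, -g) })
}

ag_mul <- function(tape, a, b) {
  av <- a$v; bv <- b$v
  ag_node(tape, av * bv, function(g) { ag_accum(a, g * bv); ag_accum(b, g * av) })
}

ag_div <- function(tape, a, b) {
  av <- a$v; bv <- b$v
  ag_node(tape, av / bv, function(g) {
    ag_accum(a, g / bv); ag_accum(b, -g * av / (bv * bv))
  })
}

ag_scale <- function(tape, a, s) {
  ag_node(tape, a$v * s, function(g) ag_accum(a, g * s))
}

ag_shift <- function(tape, a, s) { # add a numeric constant
  ag_node(tape, a$v + s, function(g) ag_accum(a, g))
}

ag_relu <- function(tape, a) {
  av <- a$v
  ag_node(tape, pmax(av, 0), function(g) ag_accum(a, g * (av > 0)))
}

ag_gelu <- function(tape, a) { # exact Gaussian-CDF form
  av <- a$v
  v <- av * stats::pnorm(av)
  if (!is.null(dim(av))) dim(v) <- dim(av)
  ag_node(tape, v, function(g) ag_accum(a, g * (stats::pnorm(av) + av * stats::dnorm(av))))
}

ag_sigmoid <- function(tape, a) {
  v <- stats::plogis(a$v)
  if (!is.null(dim(a$v))) dim(v) <- dim(a$v)
  ag_node(tape, v, function(g) ag_accum(a, g * v * (1 - v)))
}

ag_sum <- function(tape, a) {
  dm <- dim(a$v); ln <- length(a$v)
  ag_node(tape, sum(a$v), function(g) {
    gg <- rep(as.numeric(g), ln)
    if (!is.null(dm)) dim(gg) <- dm
    ag_accum(a, gg)
  })
}

## ---- shape ----

ag_reshape <- function(tape, a, dm) {
  v <- a$v
  odm <- dim(v)
  dim(v) <- dm
  ag_node(tape, v, function(g) { dim(g) <- odm; ag_accum(a, g) })
}

ag_aperm <- function(tape, a, perm) {
  inv <- order(perm)
  ag_node(tape, aperm(a$v, perm), function(g) ag_accum(a, aperm(g, inv)))
}

## ---- linear / normalization on token matrices (n x C) ----

ag_lin <- function(tape, x, W, b = NULL) {
  v <- x$v %*% W$v
  if (!is.null(b)) v <- sweep(v, 2L, b$v, "+")
  ag_node(tape, v, function(g) {
    ag_accum(x, g %*% t(W$v))
    ag_accum(W, crossprod(x$v, g))
    if (!is.null(b)) ag_accum(b, colSums(g))
  })
}

ag_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- x$v
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  v <- sweep(xhat, 2L, gamma$v, "*")
  v <- sweep(v, 2L, beta$v, "+")
  ag_node(tape, v, function(g) {
    ag_accum(gamma, colSums(g * xhat))
    ag_accum(beta, colSums(g))
    gx <- sweep(g, 2L, gamma$v, "*")
    m1 <- rowMeans(gx)
    m2 <- rowMeans(gx * xhat)
    ag_accum(x, inv * (gx - m1 - xhat * m2))
  })
}

ag_softmax_rows <- function(tape, x) {
  xv <- x$v
  m <- apply(xv, 1L, max)
  e <- exp(xv - m)
  v <- e / rowSums(e)
  ag_node(tape, v, function(g) {
    ag_accum(x, (g - rowSums(g * v)) * v)
  })
}

## ---- channel-first feature maps (C, D, H, W) ----

ag_index_c <- function(tape, x, idx) { # select/permute first-dimension slices
  dm <- dim(x$v)
  v <- x$v[idx, , , , drop = FALSE]
  ag_node(tape, v, function(g) {
    gf <- array(0, dm)
    gf[idx, , , ] <- g
    ag_accum(x, gf)
  })
}

ag_concat_c <- function(tape, a, b) {
  da <- dim(a$v); db <- dim(b$v)
  v <- array(0, c(da[1] + db[1], da[2:4]))
  v[seq_len(da[1]), , , ] <- a$v
  v[da[1] + seq_len(db[1]), , , ] <- b$v
  ag_node(tape, v, function(g) {
    ag_accum(a, g[seq_len(da[1]), , , , drop = FALSE])
    ag_accum(b, g[da[1] + seq_len(db[1]), , , , drop = FALSE])
  })
}

ag_roll_spatial <- function(tape, x, shift) { # circular roll of axes 2:4 of (C,D,H,W)
  dm <- dim(x$v)
  ix <- function(n, s) ((seq_len(n) - 1 - s) %% n) + 1
  v <- x$v[, ix(dm[2], shift[1]), ix(dm[3], shift[2]), ix(dm[4], shift[3]), drop = FALSE]
  ag_node(tape, v, function(g) {
    ag_accum(x, g[, ix(dm[2], -shift[1]), ix(dm[3], -shift[2]), ix(dm[4], -shift[3]), drop = FALSE])
  })
}

ag_gap <- function(tape, x) { # global average pool (C,D,H,W) -> length-C vector
  dm <- dim(x$v)
  n <- prod(dm[2:4])
  v <- rowMeans(matrix(x$v, nrow = dm[1]))
  ag_node(tape, v, function(g) {
    gg <- array(rep(g / n, n), dm) # column-major recycling fills channels first
    ag_accum(x, gg)
  })
}

ag_mul_channel <- function(tape, x, s) { # broadcast per-channel vector over (C,D,H,W)
  xv <- x$v; sv <- as.vector(s$v)
  dm <- dim(xv)
  v <- xv * sv # recycles along the first (channel) dimension
  ag_node(tape, v, function(g) {
    ag_accum(x, g * sv)
    ag_accum(s, rowSums(matrix(g * xv, nrow = dm[1])))
  })
}

ag_groupnorm <- function(tape, x, groups, gamma, beta, eps = 1e-5) {
  xv <- x$v
  dm <- dim(xv)
  C <- dm[1]; nvox <- prod(dm[2:4]); cg <- C %/% groups
  xm <- matrix(xv, nrow = C) # C x nvox
  gidx <- rep(seq_len(groups), each = cg)
  mu <- va <- numeric(groups)
  xhat <- xm
  inv <- numeric(groups)
  for (g_ in seq_len(groups)) {
    rows <- which(gidx == g_)
    blk <- xm[rows, , drop = FALSE]
    mu[g_] <- mean(blk)
    va[g_] <- mean((blk - mu[g_])^2)
    inv[g_] <- 1 / sqrt(va[g_] + eps)
    xhat[rows, ] <- (blk - mu[g_]) * inv[g_]
  }
  v <- xhat * gamma$v + beta$v # per-channel affine, recycled over columns
  dim(v) <- dm
  ag_node(tape, v, function(g) {
    gm <- matrix(g, nrow = C)
    ag_accum(gamma, rowSums(gm * xhat))
    ag_accum(beta, rowSums(gm))
    gx <- gm * gamma$v
    out <- gx
    for (g_ in seq_len(groups)) {
      rows <- which(gidx == g_)
      blk <- gx[rows, , drop = FALSE]
      xh <- xhat[rows, , drop = FALSE]
      m1 <- mean(blk)
      m2 <- mean(blk * xh)
      out[rows, ] <- inv[g_] * (blk - m1 - xh * m2)
    }
    dim(out) <- dm
    ag_accum(x, out)
  })
}

ag_conv_dw <- function(tape, x, w, b = NULL) {
  # depth-wise 3D convolution, zero padding (k-1)/2 per axis, shape preserving
  xv <- x$v; wv <- w$v
  dm <- dim(xv); C <- dm[1]; D <- dm[2]; H <- dm[3]; W <- dm[4]
  k <- dim(wv)[2]; p <- (k - 1L) %/% 2L
  xp <- array(0, c(C, D + 2 * p, H + 2 * p, W + 2 * p))
  xp[, p + seq_len(D), p + seq_len(H), p + seq_len(W)] <- xv
  out <- if (is.null(b)) array(0, dm) else array(rep(b$v, prod(dm[2:4])), dm)
  for (i in seq_len(k)) for (j in seq_len(k)) for (l in seq_len(k)) {
    wij <- wv[, i, j, l]
    if (all(wij == 0)) next
    sl <- xp[, (i - 1) + seq_len(D), (j - 1) + seq_len(H), (l - 1) + seq_len(W), drop = FALSE]
    out <- out + sl * wij
  }
  ag_node(tape, out, function(g) {
    gxp <- array(0, dim(xp))
    gw <- array(0, dim(wv))
    for (i in seq_len(k)) for (j in seq_len(k)) for (l in seq_len(k)) {
      sl <- xp[, (i - 1) + seq_len(D), (j - 1) + seq_len(H), (l - 1) + seq_len(W), drop = FALSE]
      gw[, i, j, l] <- rowSums(matrix(sl * g, nrow = C))
      gxp[, (i - 1) + seq_len(D), (j - 1) + seq_len(H), (l - 1) + seq_len(W)] <-
        gxp[, (i - 1) + seq_len(D), (j - 1) + seq_len(H), (l - 1) + seq_len(W), drop = FALSE] +
        g * wv[, i, j, l]
    }
    ag_accum(w, gw)
    if (!is.null(b)) ag_accum(b, rowSums(matrix(g, nrow = C)))
    ag_accum(x, gxp[, p + seq_len(D), p + seq_len(H), p + seq_len(W), drop = FALSE])
  })
}

## ---- batched scaled-dot-product attention ----

# Q, K, V: (nW, T, dh, heads). mask: (T, T, nW) additive or NULL.
# bias: node (T, T, heads) additive relative-position bias or NULL.
# Returns (nW, T, dh, heads); attention probabilities are kept for backward.
ag_attention <- function(tape, Q, K, V, nW, heads, mask = NULL, bias = NULL) {
  qv <- Q$v; kv <- K$v; vv <- V$v
  T_ <- dim(qv)[2]; dh <- dim(qv)[3]
  Tk <- dim(kv)[2] # key/value token count may differ (cross-attention)
  sc <- 1 / sqrt(dh)
  out <- array(0, dim(qv))
  P <- array(0, c(T_, Tk, nW, heads))
  for (h in seq_len(heads)) for (w in seq_len(nW)) {
    q <- matrix(qv[w, , , h], nrow = T_); kk <- matrix(kv[w, , , h], nrow = Tk)
    s <- (q %*% t(kk)) * sc
    if (!is.null(bias)) s <- s + bias$v[, , h]
    if (!is.null(mask)) s <- s + mask[, , w]
    s <- s - apply(s, 1L, max)
    e <- exp(s)
    p <- e / rowSums(e)
    P[, , w, h] <- p
    out[w, , , h] <- p %*% matrix(vv[w, , , h], nrow = Tk)
  }
  node <- ag_node(tape, out, function(g) {
    gQ <- array(0, dim(qv)); gK <- array(0, dim(kv)); gV <- array(0, dim(vv))
    gB <- if (!is.null(bias)) array(0, c(T_, Tk, heads)) else NULL
    for (h in seq_len(heads)) for (w in seq_len(nW)) {
      go <- matrix(g[w, , , h], nrow = T_)
      p <- matrix(P[, , w, h], nrow = T_)
      vvm <- matrix(vv[w, , , h], nrow = Tk)
      gP <- go %*% t(vvm)
      gV[w, , , h] <- t(p) %*% go
      gS <- (gP - rowSums(gP * p)) * p
      if (!is.null(bias)) gB[, , h] <- gB[, , h] + gS
      gQ[w, , , h] <- (gS %*% matrix(kv[w, , , h], nrow = Tk)) * sc
      gK[w, , , h] <- (t(gS) %*% matrix(qv[w, , , h], nrow = T_)) * sc
    }
    ag_accum(Q, gQ); ag_accum(K, gK); ag_accum(V, gV)
    if (!is.null(bias)) ag_accum(bias, gB)
  })
  attr(node, "probs") <- P
  node
}
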