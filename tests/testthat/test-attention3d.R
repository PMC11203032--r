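test_that("window partition/reverse and cyclic shift are exact inverses", {
  x <- rand_fm(3, 8, seed = 1)
  tok <- window_partition(x, 4)
  expect_identical(dim(tok), c(8L, 64L, 3L))
  expect_identical(window_reverse(tok, dim(x)[2:4], 4), x)

  expect_equal(dim(window_partition(x, 8))[1], 1L) # full-volume window
  expect_equal(dim(window_partition(x, 4))[1], 8L)
  expect_error(window_partition(x, 3), "divisible")

  s <- c(1L, -2L, 3L)
  expect_identical(cyclic_shift(cyclic_shift(x, s), -s), x)
  expect_identical(cyclic_shift(x, c(0, 0, 0)), x)
  expect_equal(sum(cyclic_shift(x, s)), sum(x))
})

test_that("W-MSA matches the loop oracle and is a proper attention", {
  for (seed in 1:5) {
    set.seed(seed)
    C <- 4L; heads <- 2L; T_ <- 8L; nW <- 2L
    w <- new_attention_weights(C, heads, seed = seed + 100)
    tok <- array(rnorm(nW * T_ * C), c(nW, T_, C))
    r <- wmsa(tok, w, heads)
    for (win_i in seq_len(nW)) {
      o <- o_window_attention(tok[win_i, , ], w, heads)
      expect_lt(max(abs(r$out[win_i, , ] - o$out)), 1e-6)
      for (h in 1:heads) {
        expect_lt(max(abs(r$K[win_i, , , h] - o$K[, (h - 1) * 2 + 1:2])), 1e-6)
        expect_lt(max(abs(r$probs[, , win_i, h] - o$probs[, , h])), 1e-6)
      }
    }
    expect_lt(max(abs(apply(r$probs, c(1, 3, 4), sum) - 1)), 1e-6)
  }
})

test_that("a single-token window returns its value projection", {
  C <- 4L
  w <- new_attention_weights(C, 2L, seed = 3)
  tok <- array(rnorm(C), c(1, 1, C))
  r <- wmsa(tok, w, 2L)
  vproj <- tok[1, 1, ] %*% w$Wqkv[, 2 * C + 1:C] + w$bqkv[2 * C + 1:C]
  expected <- vproj %*% w$Wo + w$bo
  expect_lt(max(abs(r$out[1, 1, ] - expected)), 1e-8)
})

test_that("SW-MSA equals W-MSA at zero shift and matches the pair-enumeration oracle", {
  C <- 4L; heads <- 2L
  w <- new_attention_weights(C, heads, seed = 9)
  x <- rand_fm(C, 4, seed = 2)

  r0 <- swmsa(x, w, heads, win = 2, shift = 0)
  rw <- wmsa(window_partition(x, 2), w, heads)
  expect_identical(r0$out, window_reverse(rw$out, dim(x)[2:4], 2))

  rs <- swmsa(x, w, heads, win = 2, shift = 1)
  oracle <- o_swmsa(x, w, heads, win = c(2L, 2L, 2L), shift = c(1L, 1L, 1L))
  expect_lt(max(abs(rs$out - oracle)), 1e-6)

  # masked (wrap-adjacent) pairs receive exactly zero attention weight
  mask <- getnet:::swin_attention_mask(c(4, 4, 4), c(2, 2, 2), c(1, 1, 1))
  expect_true(any(mask < 0))
  masked <- which(mask < 0, arr.ind = TRUE)
  for (h in 1:heads) {
    p <- rs$probs[, , , h]
    expect_lt(max(p[masked]), 1e-12)
  }
  expect_error(swmsa(x, w, heads, win = 2, shift = 2), "strictly less")
})

test_that("cross-attention degenerates to self-attention with the decoder's own K/V", {
  C <- 4L; heads <- 2L
  w <- new_attention_weights(C, heads, seed = 21)
  tok <- array(rnorm(2 * 8 * C), c(2, 8, C))
  r <- wmsa(tok, w, heads)
  cw <- list(Wq = w$Wqkv[, 1:C], bq = w$bqkv[1:C], Wo = w$Wo, bo = w$bo)
  o <- cross_attention(tok, list(K = r$K, V = r$V), cw, heads)
  expect_lt(max(abs(o - r$out)), 1e-8)
})

test_that("cross-attention matches the loop oracle and handles singleton encoders", {
  set.seed(4)
  C <- 4L; heads <- 2L; dh <- C / heads
  cw <- list(Wq = matrix(rnorm(C * C, sd = 0.5), C, C), bq = rnorm(C),
             Wo = matrix(rnorm(C * C, sd = 0.5), C, C), bo = rnorm(C))
  tok <- array(rnorm(1 * 4 * C), c(1, 4, C))
  K <- array(rnorm(1 * 3 * dh * heads), c(1, 3, dh, heads))
  V <- array(rnorm(1 * 3 * dh * heads), c(1, 3, dh, heads))
  o <- cross_attention(tok, list(K = K, V = V), cw, heads)
  oo <- o_cross_attention(tok[1, , ], K[1, , , , drop = TRUE], V[1, , , , drop = TRUE], cw, heads)
  expect_lt(max(abs(o[1, , ] - oo)), 1e-6)

  # single encoder token: softmax over one key puts weight 1 on its value
  K1 <- K[, 1, , , drop = FALSE]; V1 <- V[, 1, , , drop = FALSE]
  o1 <- cross_attention(tok, list(K = K1, V = V1), cw, heads)
  vcat <- c(V1[1, 1, , 1], V1[1, 1, , 2])
  expected <- matrix(rep(vcat %*% cw$Wo + cw$bo, 4), 4, C, byrow = TRUE)
  expect_lt(max(abs(o1[1, , ] - expected)), 1e-8)
})

test_that("Fourier positional encoding has the stated structure", {
  pe <- fourier_positional_encoding(16, 8, freq = 10000)
  expect_true(all(pe[1, c(1, 3, 5, 7)] == 0)) # sines at position 0
  expect_true(all(pe[1, c(2, 4, 6, 8)] == 1)) # cosines at position 0
  expect_true(all(pe >= -1 & pe <= 1))
  pe2 <- fourier_positional_encoding(16, 8, freq = 20000)
  expect_equal(pe[, 1:2], pe2[, 1:2]) # i = 0 channels do not depend on freq
  expect_false(isTRUE(all.equal(pe[, 7:8], pe2[, 7:8])))
  expect_error(fourier_positional_encoding(4, 3), "even")
})

test_that("fusion respects the convex-combination endpoints", {
  set.seed(5)
  C <- 4L
  fw <- new_fuse_weights(C, seed = 6)
  ca <- matrix(rnorm(8 * C), 8, C)
  sa <- matrix(rnorm(8 * C), 8, C)
  expect_identical(fuse(ca, sa, fw, lambda = 1), fuse(sa, sa, fw, lambda = 0.5))
  expect_identical(fuse(ca, sa, fw, lambda = 0), fuse(ca, ca, fw, lambda = 0.5))
  z <- matrix(rnorm(8 * C), 8, C)
  # equal branches: the combination stage returns the common value
  f1 <- fuse(z, z, fw, lambda = 0.5)
  f2 <- fuse(z, z, fw, lambda = 0.9)
  expect_equal(f1, f2)
  expect_error(fuse(ca, sa, fw, lambda = 1.5), "lambda")
})
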