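# a minimal configuration small enough for repeated forward/backward passes
tiny_cfg <- function(window = 2L, ...) {
  getnet_config(input_size = 8L, patch_size = 2L, embed_dim = 4L, n_stages = 1L,
                heads = 2L, window = window, mlp_ratio = 2L, ...)
}

test_that("configuration validation catches inconsistent settings", {
  expect_error(getnet_config(input_size = 30), "divisible")
  expect_error(getnet_config(heads = 3), "divide")
  expect_error(tiny_cfg(window = 3L), "divide")
  expect_error(getnet_config(lambda = 2), "lambda")
})

test_that("patch merge and expand honor the shape contracts", {
  tape <- getnet:::ag_tape()
  x <- getnet:::ag_const(tape, rand_fm(24, 4, seed = 1))
  W <- getnet:::ag_const(tape, matrix(rnorm(8 * 24 * 48, sd = 0.05), 8 * 24, 48))
  b <- getnet:::ag_const(tape, numeric(48))
  m <- getnet:::bld_patch_merge(tape, x, W, b, halving = TRUE)
  expect_identical(dim(m$v), c(48L, 2L, 2L, 2L))

  W2 <- getnet:::ag_const(tape, matrix(rnorm(4 * 24 * 48, sd = 0.05), 4 * 24, 48))
  m2 <- getnet:::bld_patch_merge(tape, x, W2, b, halving = FALSE)
  expect_identical(dim(m2$v), c(48L, 4L, 2L, 2L))

  We <- getnet:::ag_const(tape, matrix(rnorm(48 * 4 * 48, sd = 0.05), 48, 4 * 48))
  be <- getnet:::ag_const(tape, numeric(4 * 48))
  e <- getnet:::bld_patch_expand(tape, m, We, be, halving = TRUE)
  expect_identical(dim(e$v), c(24L, 4L, 4L, 4L)) # expand inverts merge's shape

  # minimal channel case
  x2 <- getnet:::ag_const(tape, rand_fm(2, 2, seed = 2))
  We2 <- getnet:::ag_const(tape, matrix(rnorm(2 * 8, sd = 0.1), 2, 8))
  be2 <- getnet:::ag_const(tape, numeric(8))
  e2 <- getnet:::bld_patch_expand(tape, x2, We2, be2, halving = TRUE)
  expect_identical(dim(e2$v), c(1L, 4L, 4L, 4L))
})

test_that("the network maps the input grid to region logits deterministically", {
  cfg <- tiny_cfg()
  w <- init_getnet_weights(cfg, seed = 2)
  set.seed(3)
  vol <- array(rnorm(4 * 8^3), c(4, 8, 8, 8))
  a <- getnet_forward(cfg, w, vol)
  b <- getnet_forward(cfg, w, vol)
  expect_identical(dim(a), c(3L, 8L, 8L, 8L))
  expect_identical(a, b)
  expect_error(getnet_forward(cfg, w, vol[, 1:4, , ]), "shape")
})

test_that("every encoder K/V cache is produced and consumed exactly once", {
  cfg <- getnet_config(input_size = 16L, patch_size = 2L, embed_dim = 4L,
                       n_stages = 2L, heads = c(2L, 2L), window = 2L, mlp_ratio = 2L)
  w <- init_getnet_weights(cfg, seed = 4)
  set.seed(5)
  vol <- array(rnorm(4 * 16^3), c(4, 16, 16, 16))
  r <- getnet_forward(cfg, w, vol, return_state = TRUE)
  expect_setequal(r$state$kv_produced, c("s1.w", "s1.sw", "s2.w", "s2.sw"))
  expect_identical(sort(r$state$kv_consumed), sort(r$state$kv_produced))
  expect_false(any(duplicated(r$state$kv_consumed)))
})

test_that("soft-Dice gradients are finite and reach every parameter group", {
  cfg <- tiny_cfg()
  w <- init_getnet_weights(cfg, seed = 6)
  ph <- generate_phantom(phantom_spec(shape = c(8L, 8L, 8L),
                                      region_radii = list(wt = c(2.5, 2.5, 2.5),
                                                          tc = c(1.6, 1.6, 1.6),
                                                          et = c(0.8, 0.8, 0.8)),
                                      seed = 7))
  tg <- labels_to_regions(ph$labels) * 1
  lg <- getnet_loss_grad(cfg, w, ph$volume, tg)
  expect_true(is.finite(lg$loss))
  norms <- vapply(lg$grads, function(g) sqrt(sum(g^2)), numeric(1))
  expect_true(all(is.finite(norms)))
  expect_true(all(norms > 0)) # no dead parameter group
})

test_that("a handful of network gradients match numerical differentiation", {
  cfg <- tiny_cfg()
  w <- init_getnet_weights(cfg, seed = 8)
  set.seed(9)
  vol <- array(rnorm(4 * 8^3), c(4, 8, 8, 8))
  tg <- array(rbinom(3 * 8^3, 1, 0.3), c(3, 8, 8, 8))
  lg <- getnet_loss_grad(cfg, w, vol, tg)
  eps <- 1e-5
  for (nm in c("embed.W", "enc1.wb.attn.Wqkv", "enc1.gns.dwc.w", "bot1.dwc.w",
               "dec1.wb.ca.Wq", "cls.W")) {
    i <- 1L
    wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
    wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
    fp <- soft_dice_loss(plogis(getnet_forward(cfg, wp, vol)), tg)
    fm <- soft_dice_loss(plogis(getnet_forward(cfg, wm, vol)), tg)
    expect_equal(lg$grads[[nm]][i], (fp - fm) / (2 * eps), tolerance = 1e-4,
                 label = sprintf("numerical gradient of %s", nm))
  }
})

test_that("MAC counting follows the stated convention and ordering", {
  # a single 1x1x1 convolution: C_in * C_out * voxels
  cfg <- tiny_cfg()
  mc <- count_macs(cfg)
  expect_equal(mc$total, sum(mc$layers$macs)) # additivity
  expect_true(all(mc$layers$macs >= 0))
  cls_row <- mc$layers$macs[mc$layers$layer == "cls"]
  expect_equal(cls_row, 8^3 * cfg$embed_dim * 3) # closed form for the classifier conv

  cfg_h <- getnet_config(input_size = 32L, patch_size = 4L, embed_dim = 8L,
                         n_stages = 2L, heads = c(2L, 4L), window = 2L)
  cfg_f <- getnet_config(input_size = 32L, patch_size = 4L, embed_dim = 8L,
                         n_stages = 2L, heads = c(2L, 4L), window = 2L,
                         depth_halving = FALSE)
  expect_lt(count_macs(cfg_h)$total, count_macs(cfg_f)$total)
})

test_that("the fixed-depth merging variant also runs end to end", {
  cfg <- getnet_config(input_size = 8L, patch_size = 2L, embed_dim = 4L,
                       n_stages = 1L, heads = 2L, window = 2L, mlp_ratio = 2L,
                       depth_halving = FALSE)
  w <- init_getnet_weights(cfg, seed = 10)
  set.seed(11)
  vol <- array(rnorm(4 * 8^3), c(4, 8, 8, 8))
  out <- getnet_forward(cfg, w, vol)
  expect_identical(dim(out), c(3L, 8L, 8L, 8L))
})

test_that("prediction enforces the region hierarchy and the label alphabet", {
  cfg <- tiny_cfg()
  w <- init_getnet_weights(cfg, seed = 12)
  set.seed(13)
  vol <- array(rnorm(4 * 8^3), c(4, 8, 8, 8))
  pr <- getnet_predict(cfg, w, vol)
  expect_true(all(pr$labels %in% c(0L, 1L, 2L, 4L)))
  r <- labels_to_regions(pr$labels)
  expect_true(all(r[1, , , ][r[2, , , ]]))
  expect_true(all(r[2, , , ][r[3, , , ]]))
})
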