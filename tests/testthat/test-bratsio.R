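make_case_dir <- function(seed = 1, with_seg = TRUE, shape = c(16L, 16L, 16L)) {
  ph <- generate_phantom(phantom_spec(shape = shape,
                                      region_radii = list(wt = c(5, 4, 4), tc = c(3, 3, 3),
                                                          et = c(1, 1, 1)),
                                      seed = seed))
  d <- file.path(withr::local_tempdir(.local_envir = parent.frame()), "CASE_0001")
  write_case(d, ph$volume, labels = if (with_seg) ph$labels else NULL)
  list(dir = d, ph = ph)
}

test_that("case round trip through NIfTI is exact and seg is optional", {
  x <- make_case_dir(seed = 3)
  cs <- read_case(x$dir)
  expect_equal(cs$volume, x$ph$volume)
  expect_identical(cs$labels, x$ph$labels)

  y <- make_case_dir(seed = 3, with_seg = FALSE)
  cs2 <- read_case(y$dir)
  expect_null(cs2$labels)
  expect_equal(cs2$volume, y$ph$volume)
})

test_that("missing modality and mismatched grids are reported", {
  x <- make_case_dir(seed = 4)
  file.remove(file.path(x$dir, "CASE_0001_t1ce.nii.gz"))
  expect_error(read_case(x$dir), "t1ce")

  y <- make_case_dir(seed = 5)
  small <- x$ph$volume[2, 1:8, 1:8, 1:8]
  getnet:::write_nifti_canonical(small, file.path(y$dir, "CASE_0001_t2.nii.gz"), c(1, 1, 1))
  expect_error(read_case(y$dir), "grid")
})

test_that("clip_and_zscore standardizes nonzero voxels and keeps zeros", {
  ph <- generate_phantom(phantom_spec(seed = 6))
  z <- clip_and_zscore(ph$volume)
  for (ch in 1:4) {
    orig_nz <- ph$volume[ch, , , ] != 0
    v <- z[ch, , , ][orig_nz]
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(mean((v - mean(v))^2) - 1), 1e-6)
    expect_true(all(z[ch, , , ][!orig_nz] == 0))
  }
  # near-idempotent on outlier-free phantoms; the residual is bounded by the
  # order-statistic gap at the 1%/99% tails that interpolated percentiles
  # re-clip on a second pass
  z2 <- clip_and_zscore(z)
  expect_lt(max(abs(z2 - z)), 1e-2)
  expect_lt(mean(abs(z2 - z)), 1e-4)
})

test_that("clipping pins an extreme outlier to the 99th-percentile bound", {
  ph <- generate_phantom(phantom_spec(seed = 7))
  vol <- ph$volume
  nzidx <- which(vol[1, , , ] != 0)
  v <- vol[1, , , ]
  v[nzidx[1]] <- 1e6
  q99 <- quantile(v[v != 0], 0.99, names = FALSE, type = 7)
  vol[1, , , ] <- v
  z <- clip_and_zscore(vol)
  clipped <- pmin(pmax(v[v != 0], quantile(v[v != 0], 0.01, names = FALSE)), q99)
  mu <- mean(clipped); sd_ <- sqrt(mean((clipped - mu)^2))
  expect_equal(z[1, , , ][nzidx[1]], (q99 - mu) / sd_, tolerance = 1e-10)
})

test_that("all-zero channels are rejected", {
  vol <- array(0, c(4, 8, 8, 8))
  vol[2:4, 2:6, 2:6, 2:6] <- 1
  expect_error(clip_and_zscore(vol), "all zero")
})

test_that("crop_to_patch is seed-deterministic, brain-preserving and pads small inputs", {
  # blob with slack on every side, so the feasible windows are genuinely random
  vol <- array(0, c(2, 32, 32, 32))
  vol[, 10:20, 10:20, 10:20] <- 1
  lab <- array(0L, c(32, 32, 32)); lab[12:18, 12:18, 12:18] <- 2L
  a <- crop_to_patch(vol, lab, size = c(16, 16, 16), seed = 9)
  b <- crop_to_patch(vol, lab, size = c(16, 16, 16), seed = 9)
  expect_identical(a, b)
  expect_identical(dim(a$volume), c(2L, 16L, 16L, 16L))
  expect_equal(sum(a$volume != 0), sum(vol != 0)) # whole blob retained
  expect_equal(sum(a$labels == 2L), sum(lab == 2L))
  offs <- vapply(1:20, function(s) crop_to_patch(vol, size = c(16, 16, 16), seed = s)$offset[1],
                 numeric(1))
  expect_gt(length(unique(offs)), 1) # the window really is sampled

  ph <- generate_phantom(phantom_spec(shape = c(16L, 16L, 16L),
                                      region_radii = list(wt = c(4, 4, 4), tc = c(2.5, 2.5, 2.5),
                                                          et = c(1, 1, 1)),
                                      seed = 8))
  p <- crop_to_patch(ph$volume, ph$labels, size = c(24, 24, 24), seed = 1)
  expect_identical(dim(p$volume), c(4L, 24L, 24L, 24L))
  expect_equal(sum(p$volume != 0), sum(ph$volume != 0)) # zero-padded, brain preserved

  # a brain bounding box that exactly fills the patch admits a single window
  tight <- array(1, c(1, 8, 8, 8))
  crops <- vapply(1:5, function(s) crop_to_patch(tight, size = c(8, 8, 8), seed = s)$offset[1],
                  numeric(1))
  expect_true(all(crops == 0))
})

test_that("augmentation honors p_apply, seeds and the gamma identity", {
  ph <- generate_phantom(phantom_spec(seed = 10))
  a0 <- augment(ph$volume, ph$labels, seed = 3, p_apply = 0)
  expect_identical(a0$volume, ph$volume)
  expect_identical(a0$labels, ph$labels)

  a1 <- augment(ph$volume, ph$labels, seed = 4, p_apply = 1)
  a2 <- augment(ph$volume, ph$labels, seed = 4, p_apply = 1)
  expect_identical(a1$volume, a2$volume)
  expect_true(all(unique(as.vector(a1$labels)) %in% c(0L, 1L, 2L, 4L)))

  expect_equal(getnet:::gamma_transform(ph$volume[1, , , ], 1), ph$volume[1, , , ],
               tolerance = 1e-12)
})

test_that("rotating labels by an angle and back approximately preserves label counts", {
  ph <- generate_phantom(phantom_spec(seed = 12))
  ang <- 17.3
  f <- getnet:::rotate_plane_3d(ph$labels, ang, c(2, 3), nearest = TRUE)
  b <- getnet:::rotate_plane_3d(f, -ang, c(2, 3), nearest = TRUE)
  for (lab in c(1, 2, 4)) {
    n0 <- sum(ph$labels == lab)
    n1 <- sum(b == lab)
    expect_lt(abs(n1 - n0) / n0, 0.15)
  }
})

test_that("label/region mapping is exact on all per-voxel patterns", {
  # all 8 region-bit patterns in a 2x2x2 volume
  bits <- expand.grid(wt = 0:1, tc = 0:1, et = 0:1)
  regions <- array(0, c(3, 2, 2, 2))
  for (i in 1:8) regions[, ((i - 1) %% 2) + 1, ((i - 1) %/% 2 %% 2) + 1, ((i - 1) %/% 4) + 1] <-
      as.numeric(bits[i, ])
  lab <- regions_to_labels(regions)
  expect_true(all(lab %in% c(0L, 1L, 2L, 4L)))
  # round trip after hierarchy enforcement is the identity
  back <- labels_to_regions(lab)
  expect_identical(labels_to_regions(regions_to_labels(back * 1)), back)
  # hierarchy-consistent input round-trips exactly
  consistent <- array(0, c(3, 1, 1, 1)); consistent[, 1, 1, 1] <- c(1, 1, 0)
  expect_equal(regions_to_labels(consistent)[1, 1, 1], 1L)
  expect_identical(labels_to_regions(regions_to_labels(consistent)) * 1, consistent)

  # ET outside WT is suppressed
  stray <- array(0, c(3, 1, 1, 1)); stray[3, 1, 1, 1] <- 1
  expect_equal(regions_to_labels(stray)[1, 1, 1], 0L)
  # all three set -> enhancing label
  full <- array(1, c(3, 1, 1, 1))
  expect_equal(regions_to_labels(full)[1, 1, 1], 4L)

  expect_error(labels_to_regions(array(3L, c(1, 1, 1))), "label")
})

test_that("single-label voxels decode to the expected regions", {
  lab <- array(0L, c(1, 1, 1))
  lab[1] <- 4L
  expect_equal(as.vector(labels_to_regions(lab)), c(TRUE, TRUE, TRUE))
  lab[1] <- 2L
  expect_equal(as.vector(labels_to_regions(lab)), c(TRUE, FALSE, FALSE))
  lab[1] <- 0L
  expect_equal(as.vector(labels_to_regions(lab)), c(FALSE, FALSE, FALSE))
})
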