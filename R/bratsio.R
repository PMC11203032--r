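# BraTS2021-style case I/O, preprocessing (percentile clipping + Z-score over
# nonzero voxels, random patch cropping) and augmentation, plus the mapping
# between the BraTS label alphabet {0,1,2,4} and the three nested evaluation
# regions WT = {1,2,4}, TC = {1,4}, ET = {4}.

BRATS_MODALITIES <- c("t1", "t2", "t1ce", "flair")
BRATS_LABELS <- c(0L, 1L, 2L, 4L)

nifti_path <- function(case_dir, suffix) {
  base <- file.path(case_dir, paste0(basename(case_dir), "_", suffix))
  for (ext in c(".nii.gz", ".nii")) if (file.exists(paste0(base, ext))) return(paste0(base, ext))
  paste0(base, ".nii.gz")
}

write_nifti_canonical <- function(arr, path, spacing) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, spacing)
  RNifti::writeNifti(img, path)
}

#' Write one case in the BraTS directory layout
#'
#' @param case_dir directory named after the case; the five files
#'   `<case>_t1/t2/t1ce/flair/seg.nii.gz` are written into it.
#' @param volume numeric array `(4, D, H, W)`, channel order T1, T2, T1ce, FLAIR.
#' @param labels optional integer array `(D, H, W)` over \{0,1,2,4\}.
#' @param spacing per-axis voxel size in mm.
#' @return Invisibly, `case_dir`.
#' @export
write_case <- function(case_dir, volume, labels = NULL, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(volume)) == 4L, dim(volume)[1] == 4L)
  dir.create(case_dir, recursive = TRUE, showWarnings = FALSE)
  for (m in seq_along(BRATS_MODALITIES))
    write_nifti_canonical(volume[m, , , ], nifti_path(case_dir, BRATS_MODALITIES[m]), spacing)
  if (!is.null(labels))
    write_nifti_canonical(array(as.double(labels), dim(labels)),
                          nifti_path(case_dir, "seg"), spacing)
  invisible(case_dir)
}

read_nifti_canonical <- function(path) {
  img <- RNifti::readNifti(path)
  # reorient to one fixed axis convention so NIfTI affine dialects cannot
  # leak downstream; phantoms written by this package are already canonical
  ok <- try({
    orc <- RNifti::orientation(img)
    if (!is.na(orc) && nzchar(orc) && orc != "RAS") RNifti::orientation(img) <- "RAS"
  }, silent = TRUE)
  list(data = as.array(img), spacing = RNifti::pixdim(img)[1:3])
}

#' Read a BraTS-style case directory
#'
#' Loads the four modality volumes (and the segmentation when present, as in
#' training cases) into a single channel-first array.
#'
#' @param case_dir case directory following the `{case}_{modality}.nii.gz`
#'   naming convention.
#' @return A list with `volume` `(4, D, H, W)`, `labels` (integer array or
#'   `NULL` for unlabeled validation cases) and `spacing` (mm).
#' @export
read_case <- function(case_dir) {
  if (!dir.exists(case_dir)) stop("case directory not found: ", case_dir)
  vols <- vector("list", 4L)
  spacing <- NULL
  for (m in seq_along(BRATS_MODALITIES)) {
    p <- nifti_path(case_dir, BRATS_MODALITIES[m])
    if (!file.exists(p)) stop("missing modality file: ", p)
    r <- read_nifti_canonical(p)
    vols[[m]] <- r$data
    if (is.null(spacing)) spacing <- r$spacing
    if (!identical(dim(r$data), dim(vols[[1]])))
      stop_validation("modality %s grid %s does not match %s",
                      BRATS_MODALITIES[m], paste(dim(r$data), collapse = "x"),
                      paste(dim(vols[[1]]), collapse = "x"))
  }
  shape <- dim(vols[[1]])
  volume <- array(0, c(4L, shape))
  for (m in 1:4) volume[m, , , ] <- vols[[m]]
  labels <- NULL
  segp <- nifti_path(case_dir, "seg")
  if (file.exists(segp)) {
    r <- read_nifti_canonical(segp)
    if (!identical(dim(r$data), shape))
      stop_validation("segmentation grid does not match the modalities")
    labels <- array(as.integer(round(r$data)), shape)
    bad <- setdiff(unique(as.vector(labels)), BRATS_LABELS)
    if (length(bad)) stop_validation("unknown label value(s): %s", paste(bad, collapse = ", "))
  }
  list(volume = volume, labels = labels, spacing = spacing)
}

#' Percentile clipping and Z-score standardization
#'
#' Per channel, clips intensities to the 1st and 99th percentiles of the
#' channel's nonzero-voxel distribution (linear-interpolation percentiles),
#' then standardizes the nonzero voxels to zero mean and unit variance.
#' Background zeros are untouched, so the exact-zero background survives.
#'
#' @param volume numeric array `(4, D, H, W)` (any channel count is accepted).
#' @param probs clipping percentiles, default `c(0.01, 0.99)`.
#' @return The transformed array, same shape.
#' @export
clip_and_zscore <- function(volume, probs = c(0.01, 0.99)) {
  stopifnot(length(dim(volume)) == 4L)
  out <- volume
  for (ch in seq_len(dim(volume)[1])) {
    x <- volume[ch, , , ]
    nz <- x != 0
    if (!any(nz)) stop_validation("channel %d is all zero; cannot standardize", ch)
    v <- x[nz]
    q <- stats::quantile(v, probs, names = FALSE, type = 7)
    v <- pmin(pmax(v, q[1]), q[2])
    mu <- mean(v)
    sd_ <- stats::sd(v) * sqrt((length(v) - 1) / length(v)) # population SD
    if (sd_ == 0) sd_ <- 1
    x[nz] <- (v - mu) / sd_
    out[ch, , , ] <- x
  }
  out
}

brain_bbox <- function(volume) {
  nz <- apply(volume != 0, 2:4, any)
  idx <- which(nz, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  list(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

pad_to <- function(volume, labels, size) {
  shape <- dim(volume)[2:4]
  need <- pmax(size - shape, 0L)
  if (all(need == 0L)) return(list(volume = volume, labels = labels))
  lo <- need %/% 2L
  newshape <- shape + need
  v <- array(0, c(dim(volume)[1], newshape))
  v[, lo[1] + seq_len(shape[1]), lo[2] + seq_len(shape[2]), lo[3] + seq_len(shape[3])] <- volume
  l <- NULL
  if (!is.null(labels)) {
    l <- array(0L, newshape)
    l[lo[1] + seq_len(shape[1]), lo[2] + seq_len(shape[2]), lo[3] + seq_len(shape[3])] <- labels
  }
  list(volume = v, labels = l)
}

#' Random patch crop containing the whole brain
#'
#' Crops volume and labels to a fixed patch, choosing the crop window
#' uniformly at random among all windows that contain the brain bounding box
#' (the nonzero-voxel extent). Inputs smaller than the patch are zero-padded
#' first, so the brain is always preserved.
#'
#' @param volume numeric array `(C, D, H, W)`.
#' @param labels optional integer array `(D, H, W)` cropped identically.
#' @param size length-3 target patch size (default `c(128, 128, 128)`).
#' @param seed integer seed; the same seed always selects the same window.
#' @return list with `volume`, `labels` (or `NULL`) and `offset`, the 0-based
#'   crop origin in the (possibly padded) input grid.
#' @export
crop_to_patch <- function(volume, labels = NULL, size = c(128L, 128L, 128L), seed = 1L) {
  size <- as.integer(size)
  p <- pad_to(volume, labels, size)
  volume <- p$volume; labels <- p$labels
  shape <- dim(volume)[2:4]
  bb <- brain_bbox(volume)
  if (is.null(bb)) bb <- list(lo = rep(1L, 3), hi = rep(1L, 3))
  start <- with_seed(seed, {
    s <- integer(3)
    for (a in 1:3) {
      lo_a <- max(1L, bb$hi[a] - size[a] + 1L)
      hi_a <- min(bb$lo[a], shape[a] - size[a] + 1L)
      if (hi_a < lo_a) { lo_a <- 1L; hi_a <- shape[a] - size[a] + 1L } # brain larger than patch
      s[a] <- if (hi_a == lo_a) lo_a else lo_a + floor(stats::runif(1) * (hi_a - lo_a + 1))
    }
    s
  })
  v <- volume[, start[1] + seq_len(size[1]) - 1L,
              start[2] + seq_len(size[2]) - 1L,
              start[3] + seq_len(size[3]) - 1L, drop = FALSE]
  l <- if (is.null(labels)) NULL else
    labels[start[1] + seq_len(size[1]) - 1L,
           start[2] + seq_len(size[2]) - 1L,
           start[3] + seq_len(size[3]) - 1L]
  list(volume = v, labels = l, offset = start - 1L)
}

## ---- augmentation ----

rotate_plane_3d <- function(arr, angle_deg, axes, nearest = FALSE) {
  # rotate a 3D array by angle_deg in the plane of `axes` (two of 1:3),
  # bilinear (or nearest) interpolation, zero outside the grid
  perm <- c(axes, setdiff(1:3, axes))
  a <- aperm(arr, perm)
  n1 <- dim(a)[1]; n2 <- dim(a)[2]; n3 <- dim(a)[3]
  th <- angle_deg * pi / 180
  c1 <- (n1 + 1) / 2; c2 <- (n2 + 1) / 2
  g1 <- rep(seq_len(n1), times = n2) - c1
  g2 <- rep(seq_len(n2), each = n1) - c2
  # source coordinates: inverse rotation of the output grid
  s1 <- cos(th) * g1 + sin(th) * g2 + c1
  s2 <- -sin(th) * g1 + cos(th) * g2 + c2
  out <- array(0, dim(a))
  if (nearest) {
    i <- round(s1); j <- round(s2)
    ok <- i >= 1 & i <= n1 & j >= 1 & j <= n2
    flat <- (j[ok] - 1L) * n1 + i[ok]
    for (k in seq_len(n3)) {
      sl <- a[, , k]
      o <- numeric(n1 * n2)
      o[ok] <- sl[flat]
      out[, , k] <- o
    }
  } else {
    i0 <- floor(s1); j0 <- floor(s2)
    fi <- s1 - i0; fj <- s2 - j0
    for (di in 0:1) for (dj in 0:1) {
      ii <- i0 + di; jj <- j0 + dj
      wgt <- (if (di == 0) 1 - fi else fi) * (if (dj == 0) 1 - fj else fj)
      ok <- ii >= 1 & ii <= n1 & jj >= 1 & jj <= n2 & wgt > 0
      if (!any(ok)) next
      flat <- (jj[ok] - 1L) * n1 + ii[ok]
      w_ok <- wgt[ok]
      for (k in seq_len(n3)) {
        sl <- a[, , k]
        o <- out[, , k]
        o[ok] <- o[ok] + w_ok * sl[flat]
        out[, , k] <- o
      }
    }
  }
  aperm(out, order(perm))
}

gaussian_blur_3d <- function(arr, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  for (ax in 1:3) {
    n <- dim(arr)[ax]
    acc <- array(0, dim(arr))
    for (t in seq_along(k)) {
      off <- t - r - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n) # edge-clamp padding
      acc <- acc + k[t] * switch(ax,
        arr[idx, , , drop = FALSE],
        arr[, idx, , drop = FALSE],
        arr[, , idx, drop = FALSE])
    }
    arr <- acc
  }
  arr
}

gamma_transform <- function(x, gamma) {
  rng <- range(x)
  if (rng[2] <= rng[1]) return(x)
  ((x - rng[1]) / (rng[2] - rng[1]))^gamma * (rng[2] - rng[1]) + rng[1]
}

#' Random augmentation of a case
#'
#' Independently applies, each with probability `p_apply`: rotation by an
#' angle uniform in \[-30, 30\] degrees about a random orthogonal plane
#' (labels rotated with nearest-neighbour interpolation), additive Gaussian
#' noise of standard deviation 0.1, Gaussian blurring with sigma uniform in
#' \[0.5, 1\], and a gamma intensity transform with exponent uniform in
#' \[0.7, 1.5\]. Labels are only ever transformed geometrically.
#'
#' @param volume numeric array `(C, D, H, W)`.
#' @param labels optional integer array `(D, H, W)`.
#' @param seed integer seed; the same seed reproduces the same transforms.
#' @param p_apply per-transform application probability (default 0.5).
#' @param noise_sd,angle_range,blur_range,gamma_range transform parameters.
#' @return list with `volume`, `labels` and `applied`, a named logical vector.
#' @export
augment <- function(volume, labels = NULL, seed = 1L, p_apply = 0.5,
                    noise_sd = 0.1, angle_range = c(-30, 30),
                    blur_range = c(0.5, 1), gamma_range = c(0.7, 1.5)) {
  stopifnot(length(dim(volume)) == 4L)
  draws <- with_seed(seed, list(
    u = stats::runif(4),
    angle = stats::runif(1, angle_range[1], angle_range[2]),
    plane = sample(list(c(1, 2), c(1, 3), c(2, 3)), 1)[[1]],
    sigma = stats::runif(1, blur_range[1], blur_range[2]),
    gam = stats::runif(1, gamma_range[1], gamma_range[2]),
    noise = NULL))
  applied <- draws$u < p_apply
  names(applied) <- c("rotate", "noise", "blur", "gamma")
  C <- dim(volume)[1]
  if (applied["rotate"]) {
    for (ch in seq_len(C))
      volume[ch, , , ] <- rotate_plane_3d(volume[ch, , , ], draws$angle, draws$plane)
    if (!is.null(labels))
      labels <- array(as.integer(round(
        rotate_plane_3d(labels, draws$angle, draws$plane, nearest = TRUE))), dim(labels))
  }
  if (applied["noise"]) {
    noise <- with_seed(seed + 1L, array(stats::rnorm(length(volume), sd = noise_sd), dim(volume)))
    volume <- volume + noise
  }
  if (applied["blur"]) {
    for (ch in seq_len(C))
      volume[ch, , , ] <- gaussian_blur_3d(volume[ch, , , ], draws$sigma)
  }
  if (applied["gamma"]) {
    for (ch in seq_len(C))
      volume[ch, , , ] <- gamma_transform(volume[ch, , , ], draws$gam)
  }
  list(volume = volume, labels = labels, applied = applied,
       params = list(angle = draws$angle, plane = draws$plane,
                     sigma = draws$sigma, gamma = draws$gam))
}

## ---- label / region mapping ----

#' Decode BraTS labels into the three nested evaluation regions
#'
#' WT (whole tumor) = \{1, 2, 4\}, TC (tumor core) = \{1, 4\},
#' ET (enhancing tumor) = \{4\}; containment WT \eqn{\supseteq} TC
#' \eqn{\supseteq} ET holds by construction.
#'
#' @param labels integer array `(D, H, W)` over \{0, 1, 2, 4\}.
#' @return logical array `(3, D, H, W)`, channel order WT, TC, ET.
#' @export
labels_to_regions <- function(labels) {
  bad <- setdiff(unique(as.vector(labels)), BRATS_LABELS)
  if (length(bad)) stop_validation("unknown label value(s): %s", paste(bad, collapse = ", "))
  shape <- dim(labels)
  r <- array(FALSE, c(3L, shape))
  r[1, , , ] <- labels %in% c(1L, 2L, 4L)
  r[2, , , ] <- labels %in% c(1L, 4L)
  r[3, , , ] <- labels == 4L
  r
}

#' Encode region masks back into BraTS labels
#'
#' The region hierarchy is enforced first (TC := TC & WT, ET := ET & TC), so
#' any hierarchy-inconsistent voxels are suppressed; then ET maps to 4,
#' TC without ET to 1, and WT without TC to 2. Inverse of
#' [labels_to_regions()] on hierarchy-consistent inputs.
#'
#' @param regions logical/binary array `(3, D, H, W)`, channels WT, TC, ET.
#' @return integer array `(D, H, W)` over \{0, 1, 2, 4\}.
#' @export
regions_to_labels <- function(regions) {
  stopifnot(length(dim(regions)) == 4L, dim(regions)[1] == 3L)
  wt <- regions[1, , , ] != 0
  tc <- regions[2, , , ] != 0 & wt
  et <- regions[3, , , ] != 0 & tc
  labels <- array(0L, dim(regions)[2:4])
  labels[wt] <- 2L
  labels[tc] <- 1L
  labels[et] <- 4L
  labels
}
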