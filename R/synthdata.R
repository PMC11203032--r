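# Deterministic BraTS-like phantoms: four co-registered MRI channels over an
# ellipsoidal "brain" on a zero background, with a nested lesion
# (whole tumor >= tumor core >= enhancing tumor) built from axis-aligned
# ellipsoids so containment and volumes are analytically checkable.

#' Specify a synthetic multi-modal phantom
#'
#' Defines the geometry, contrast noise and seed of a synthetic BraTS-style
#' case: an ellipsoidal brain of nonzero intensity on an exactly-zero
#' background, carrying a nested lesion of three axis-aligned ellipsoids
#' (whole tumor WT, tumor core TC, enhancing tumor ET, with
#' WT \eqn{\supseteq} TC \eqn{\supseteq} ET). Tissue intensities are
#' piecewise-constant per modality with additive Gaussian noise, chosen so
#' that edema is brightest in the FLAIR channel and the enhancing rim is
#' brightest in the T1ce channel, as in real BraTS contrasts.
#'
#' @param shape integer length-3 voxel grid (D, H, W).
#' @param lesion_center voxel coordinate of the lesion center (defaults to
#'   the grid center).
#' @param region_radii list with elements `wt`, `tc`, `et`, each a length-3
#'   ellipsoid semi-axis triple in voxels; must be strictly decreasing
#'   WT > TC > ET on every axis (an `et` radius of 0 gives an empty ET).
#' @param noise_sd additive Gaussian noise standard deviation, in the same
#'   arbitrary intensity units as the tissue means (which are of order 1).
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 32L),
                         lesion_center = NULL,
                         region_radii = list(wt = c(9, 8, 8), tc = c(6, 5, 5), et = c(3, 3, 3)),
                         noise_sd = 0.1,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stop_validation("shape must be three voxel dimensions >= 4")
  if (is.null(lesion_center)) lesion_center <- (shape + 1) / 2
  r <- lapply(region_radii[c("wt", "tc", "et")], as.numeric)
  if (any(vapply(r, length, 1L) != 3L))
    stop_validation("region_radii must hold three length-3 triples (wt, tc, et)")
  dec_tc <- all(r$tc < r$wt)
  dec_et <- all(r$et < r$tc) || all(r$et == 0)
  if (!dec_tc || !dec_et)
    stop_validation("region radii must be strictly decreasing WT > TC > ET on every axis")
  brain_semi <- 0.46 * shape
  if (any(abs(lesion_center - (shape + 1) / 2) / brain_semi +
          r$wt / brain_semi > 1))
    stop_validation("lesion (WT ellipsoid) must lie fully inside the brain ellipsoid")
  structure(list(shape = shape, lesion_center = as.numeric(lesion_center),
                 region_radii = r, noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipsoid_mask <- function(shape, center, semi) {
  if (all(semi == 0)) return(array(FALSE, shape))
  d <- outer(outer(((seq_len(shape[1]) - center[1]) / semi[1])^2,
                   ((seq_len(shape[2]) - center[2]) / semi[2])^2, "+"),
             ((seq_len(shape[3]) - center[3]) / semi[3])^2, "+")
  d <= 1
}

# Piecewise-constant tissue means, channel order T1, T2, T1ce, FLAIR.
# Rows: normal brain, edema (WT \ TC), necrotic core (TC \ ET), enhancing (ET).
phantom_tissue_means <- function() {
  rbind(brain    = c(1.0, 0.8, 1.0, 0.9),
        edema    = c(0.8, 1.5, 0.9, 1.8),
        necrotic = c(0.6, 1.2, 0.7, 1.3),
        enhancing = c(1.1, 1.1, 1.9, 1.4))
}

#' Generate a synthetic multi-modal phantom case
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` (numeric array `(4, D, H, W)`, channel order
#'   T1, T2, T1ce, FLAIR; exactly zero outside the brain ellipsoid),
#'   `labels` (integer array `(D, H, W)` over the BraTS alphabet 0/1/2/4),
#'   and `spacing` (mm per voxel, 1 mm isotropic).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  brain <- ellipsoid_mask(shape, (shape + 1) / 2, 0.46 * shape)
  wt <- ellipsoid_mask(shape, spec$lesion_center, spec$region_radii$wt)
  tc <- ellipsoid_mask(shape, spec$lesion_center, spec$region_radii$tc)
  et <- ellipsoid_mask(shape, spec$lesion_center, spec$region_radii$et)
  tc <- tc & wt; et <- et & tc # containment by construction
  labels <- array(0L, shape)
  labels[wt] <- 2L # peritumoral edema
  labels[tc] <- 1L # necrotic / non-enhancing core
  labels[et] <- 4L # enhancing tumor
  mu <- phantom_tissue_means()
  vol <- array(0, c(4L, shape))
  tissue <- array(1L, shape) # 1 brain, 2 edema, 3 necrotic, 4 enhancing
  tissue[wt] <- 2L; tissue[tc] <- 3L; tissue[et] <- 4L
  noise <- with_seed(spec$seed,
                     array(stats::rnorm(4 * prod(shape), sd = spec$noise_sd), c(4L, shape)))
  for (ch in 1:4) {
    img <- mu[tissue, ch]
    dim(img) <- shape
    img <- img + noise[ch, , , ]
    img[!brain] <- 0
    img[brain & img <= 0] <- 1e-3 # keep brain voxels strictly nonzero
    vol[ch, , , ] <- img
  }
  list(volume = vol, labels = labels, spacing = c(1, 1, 1))
}

#' Write phantom cases as BraTS2021-style NIfTI directories
#'
#' Each case directory `<out_dir>/<case>` receives the five files
#' `<case>_t1.nii.gz`, `_t2`, `_t1ce`, `_flair` and `_seg`, mirroring the
#' BraTS2021 layout so the case readers are exercised end to end.
#'
#' @param n_cases number of cases.
#' @param out_dir output directory (created if absent).
#' @param seed integer master seed; case `i` uses `seed + i - 1`.
#' @param shape voxel grid passed to [phantom_spec()].
#' @param prefix case-name prefix.
#' @return Invisibly, the character vector of case directories (the manifest).
#' @export
write_phantom_cases <- function(n_cases, out_dir, seed = 1L,
                                shape = c(32L, 32L, 32L), prefix = "PHANTOM") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  dirs <- character(0)
  for (i in seq_len(n_cases)) {
    # jitter geometry deterministically per case
    geo <- with_seed(seed + i - 1L, list(
      center = (shape + 1) / 2 + stats::runif(3, -0.06, 0.06) * shape,
      wt = stats::runif(3, 0.24, 0.30) * shape,
      shrink1 = stats::runif(1, 0.55, 0.75),
      shrink2 = stats::runif(1, 0.35, 0.5)))
    spec <- phantom_spec(shape = shape, lesion_center = geo$center,
                         region_radii = list(wt = geo$wt, tc = geo$wt * geo$shrink1,
                                             et = geo$wt * geo$shrink2),
                         seed = seed + i - 1L)
    ph <- generate_phantom(spec)
    case <- sprintf("%s_%05d", prefix, i)
    cdir <- file.path(out_dir, case)
    dir.create(cdir, showWarnings = FALSE)
    write_case(cdir, ph$volume, labels = ph$labels, spacing = ph$spacing)
    dirs <- c(dirs, cdir)
  }
  manifest <- file.path(out_dir, "manifest.txt")
  writeLines(basename(dirs), manifest)
  invisible(dirs)
}
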