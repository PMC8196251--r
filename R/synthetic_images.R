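# Synthetic 3D map generator.
#
# Stands in for the modulated grey-matter-volume and skeletonised FA/MD
# inputs: per subject, map = baseline + group-specific effects inside
# spherical blobs + linear covariate effects + i.i.d. Gaussian noise, on
# a desk-scale grid with an analysis mask and a seven-region label atlas.

#' Image effect specification
#'
#' @param grid_shape 3D voxel counts (default `c(24, 24, 24)`).
#' @param blob_centers Integer matrix (blobs x 3) of blob centers in
#'   1-based voxel coordinates; default: four blobs spread through the
#'   grid.
#' @param blob_radii Blob radii in voxels.
#' @param effect_sizes Numeric matrix (groups x blobs) of mean shifts in
#'   map units; rows follow `control, type1..type4`.  Default: no effect
#'   for control/type4 and graded atrophy-like negative shifts growing
#'   from type1 to type3 in blobs 1-3 (echoing the ordered severity the
#'   trend contrast targets), plus a type4-specific effect in blob 4.
#' @param covariate_betas Named slopes for `age`, `sex`, `tiv` applied to
#'   standardized covariates, in map units per SD.
#' @param noise_sd Gaussian noise SD, map units (> 0).
#' @param noise_smooth_sigma Optional spatial smoothing of the noise field
#'   (Gaussian sigma in voxels, see [gaussian_smooth_3d()]); 0 = white
#'   noise.  Use ~1.7 to emulate 8-mm FWHM smoothing on 2-mm voxels.
#' @param baseline Baseline map value.
#' @param atlas_labels Integer in 1..7 per blob, recorded for reference;
#'   the atlas itself tiles the whole mask into 7 slabs.
#' @param seed Integer seed.
#' @return Object of class `"image_effect_spec"`.
#' @export
image_effect_spec <- function(
    grid_shape = c(24, 24, 24),
    blob_centers = rbind(c(7, 7, 7), c(17, 17, 8), c(8, 16, 16),
                         c(16, 8, 17)),
    blob_radii = c(3.5, 3.5, 3.5, 3.5),
    effect_sizes = rbind(control = c(0, 0, 0, 0),
                         type1 = c(-0.4, -0.3, 0, 0),
                         type2 = c(-0.8, -0.6, -0.3, 0),
                         type3 = c(-1.2, -0.9, -0.6, 0),
                         type4 = c(0, 0, 0, -1.0)),
    covariate_betas = c(age = -0.1, sex = 0.05, tiv = 0.1),
    noise_sd = 1, noise_smooth_sigma = 0, baseline = 10,
    atlas_labels = c(1, 4, 6, 2),
    seed = 20210520) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  blob_centers <- rbind(blob_centers)
  if (nrow(blob_centers) != length(blob_radii) ||
      nrow(blob_centers) != ncol(effect_sizes))
    stop("blob_centers, blob_radii and effect_sizes disagree on the blob count")
  lo <- sweep(blob_centers, 1, blob_radii, "-")
  hi <- sweep(blob_centers, 1, blob_radii, "+")
  if (any(lo < 1) || any(t(hi) > grid_shape))
    stop("grid too small to host the blobs")
  if (any(!atlas_labels %in% 1:7)) stop("atlas_labels must be in 1..7")
  structure(as.list(environment())[c(
    "grid_shape", "blob_centers", "blob_radii", "effect_sizes",
    "covariate_betas", "noise_sd", "noise_smooth_sigma", "baseline",
    "atlas_labels", "seed")],
    class = "image_effect_spec")
}

#' Separable 3D Gaussian smoothing
#'
#' Zero-padded separable convolution, used to emulate the spatial
#' smoothness of processed morphometry maps (e.g. an 8-mm FWHM kernel on
#' 2-mm voxels is `sigma = 4 / 2.355` ~ 1.7 voxels).
#'
#' @param img 3D numeric array.
#' @param sigma Kernel standard deviation in voxels (0 returns the input).
#' @return Smoothed 3D array of the same dimensions.
#' @export
gaussian_smooth_3d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  dims <- dim(img)
  if (length(dims) != 3L) stop("img must be a 3D array")
  r <- ceiling(3 * sigma)
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  band <- function(m) {
    K <- matrix(0, m, m)
    for (off in -r:r) {
      i <- seq_len(m); j <- i + off
      ok <- j >= 1 & j <= m
      K[cbind(i[ok], j[ok])] <- k[off + r + 1]
    }
    K
  }
  x <- array(band(dims[1]) %*% matrix(img, dims[1]), dims)
  x <- aperm(x, c(2, 1, 3))
  x <- array(band(dims[2]) %*% matrix(x, dims[2]), dims[c(2, 1, 3)])
  x <- aperm(x, c(2, 1, 3))
  x <- aperm(x, c(3, 1, 2))
  x <- array(band(dims[3]) %*% matrix(x, dims[3]), dims[c(3, 1, 2)])
  aperm(x, c(2, 3, 1))
}

# logical sphere mask on a grid
sphere_mask <- function(grid_shape, center, radius) {
  co <- arrayInd(seq_len(prod(grid_shape)), grid_shape)
  d2 <- (co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
        (co[, 3] - center[3])^2
  array(d2 <= radius^2, dim = grid_shape)
}

#' Generate per-subject 3D maps plus mask and atlas
#'
#' @param cohort Subject table from [generate_cohort()] (columns `group`,
#'   `age`, `sex`, `tiv` are used).
#' @param spec An [image_effect_spec()].
#' @return List: `images` (4D array, x-y-z-subject), `mask` (3D logical:
#'   all voxels at least one voxel from the grid border), `atlas` (3D
#'   integer, labels 1..7 tiling the mask by z-slab, 0 outside), `spec`.
#' @export
generate_images <- function(cohort, spec = image_effect_spec()) {
  stopifnot(inherits(spec, "image_effect_spec"))
  if (!nrow(cohort)) stop("cohort is empty")
  if (!is.null(spec$seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
  }
  gs <- spec$grid_shape
  nvox <- prod(gs)
  n <- nrow(cohort)

  mask <- array(TRUE, dim = gs)
  mask[c(1, gs[1]), , ] <- FALSE
  mask[, c(1, gs[2]), ] <- FALSE
  mask[, , c(1, gs[3])] <- FALSE

  # atlas: tile in-mask voxels into 7 z-slabs
  atlas <- array(0L, dim = gs)
  zlab <- as.integer(cut(seq_len(gs[3]), breaks = 7, labels = FALSE))
  atlas[] <- rep(zlab, each = gs[1] * gs[2])
  atlas[!mask] <- 0L

  blobs <- lapply(seq_len(nrow(spec$blob_centers)), function(b)
    sphere_mask(gs, spec$blob_centers[b, ], spec$blob_radii[b]))

  gidx <- match(as.character(cohort$group), rownames(spec$effect_sizes))
  if (anyNA(gidx))
    stop("cohort group(s) absent from effect_sizes rows: ",
         paste(unique(cohort$group[is.na(gidx)]), collapse = ", "))
  zscore <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  cov_eff <- spec$covariate_betas[["age"]] * zscore(cohort$age) +
    spec$covariate_betas[["sex"]] * as.numeric(cohort$sex == "male") +
    spec$covariate_betas[["tiv"]] * zscore(cohort$tiv)

  base <- array(spec$baseline, dim = gs)
  images <- array(rnorm(nvox * n, sd = spec$noise_sd), dim = c(gs, n))
  if (spec$noise_smooth_sigma > 0)
    for (i in seq_len(n))
      images[, , , i] <- gaussian_smooth_3d(images[, , , i],
                                            spec$noise_smooth_sigma)
  for (i in seq_len(n)) {
    m <- base + cov_eff[i]
    for (b in seq_along(blobs))
      m[blobs[[b]]] <- m[blobs[[b]]] + spec$effect_sizes[gidx[i], b]
    images[, , , i] <- images[, , , i] + m
  }
  list(images = images, mask = mask, atlas = atlas, spec = spec)
}
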