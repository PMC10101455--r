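#' Phantom specification for a synthetic NM-MRI subject
#'
#' Parameterizes a neuromelanin-sensitive MRI phantom: the acquisition grid
#' (15-ish thick slices at 0.39 x 0.39 x 3 mm), a 7-measurement series with
#' small inter-measurement rigid motion, bilateral hyperintense structures —
#' a crescent-shaped substantia nigra pars compacta (SNc) band in the upper
#' slices and a thin locus coeruleus (LC) rod pair lower down — over a
#' homogeneous cerebral-peduncle-like reference region, plus Gaussian or
#' Rician noise and a mild acquisition blur.
#'
#' Contrast is parametric (intensity units above background), not
#' biophysical. Defaults put SNc at 6 and LC at 10 measurement-SDs above
#' background so the 2.8/3.9 segmentation thresholds sit well inside the
#' contrast range. The background carries a fixed per-subject smooth
#' tissue-heterogeneity field (`tissue_sd`), present in the reference
#' region and in the search regions alike and not averaging away across
#' measurements, so (i) the reference SD of the averaged image — the
#' quantity the thresholds multiply — is dominated by tissue variance
#' rather than by thermal noise, as in acquired NM-MRI, (ii) the
#' reference-ROI statistics genuinely represent the search-region
#' background, which is the homogeneity assumption the thresholding method
#' rests on, and (iii) rigid registration has a fixed intensity pattern to
#' lock onto. An optional deterministic sinusoidal texture (`texture_amp`,
#' default off) can break that homogeneity on purpose for robustness
#' experiments.
#'
#' @param grid_shape integer length-3 grid size
#' @param voxel_dims mm triple; default the NM-MRI acquisition grid
#' @param n_measurements repeated measurements per subject
#' @param background_mean,background_sd background intensity and noise SD
#' @param ref_region_mean,ref_region_sd reference-region mean intensity
#'   (mu_ref_true) and noise SD (sigma_ref_true)
#' @param snc_contrast,lc_contrast structure intensity above background
#' @param snc_volume_true,lc_volume_true target bilateral volumes, mm^3
#' @param lc_diameter,lc_length nominal LC rod size, mm (the painted rod is
#'   scaled isotropically to hit `lc_volume_true`)
#' @param blur_fwhm Gaussian acquisition blur FWHM, mm
#' @param texture_amp,texture_wavelength background texture amplitude
#'   (intensity units) and wavelength (mm)
#' @param tissue_sd SD of the fixed smooth tissue-heterogeneity field
#'   (intensity units; correlation length ~1.2 mm in-plane, ~two slices
#'   through-plane so anatomy varies smoothly across the 3 mm slices)
#' @param noise_model "gaussian" or "rician"
#' @param motion_sd (degrees, mm) SDs of per-measurement rigid jitter
#' @param seed RNG seed; identical seeds give bit-identical phantoms
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 14L),
                         voxel_dims = c(0.39, 0.39, 3.0),
                         n_measurements = 7L,
                         background_mean = 100, background_sd = 5,
                         ref_region_mean = 100, ref_region_sd = 5,
                         snc_contrast = 30, lc_contrast = 50,
                         snc_volume_true = 429, lc_volume_true = 8,
                         lc_diameter = 2, lc_length = 15,
                         blur_fwhm = 0.25,
                         texture_amp = 0, texture_wavelength = 8,
                         tissue_sd = 4.5,
                         noise_model = c("gaussian", "rician"),
                         motion_sd = c(0.5, 0.5),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_dims = voxel_dims, n_measurements = as.integer(n_measurements),
               background_mean = background_mean, background_sd = background_sd,
               ref_region_mean = ref_region_mean, ref_region_sd = ref_region_sd,
               snc_contrast = snc_contrast, lc_contrast = lc_contrast,
               snc_volume_true = snc_volume_true, lc_volume_true = lc_volume_true,
               lc_diameter = lc_diameter, lc_length = lc_length,
               blur_fwhm = blur_fwhm,
               texture_amp = texture_amp, texture_wavelength = texture_wavelength,
               tissue_sd = tissue_sd,
               noise_model = noise_model, motion_sd = motion_sd,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$grid_shape) == 3, all(spec$grid_shape >= 1),
            all(spec$voxel_dims > 0), spec$n_measurements >= 1,
            spec$snc_volume_true > 0, spec$lc_volume_true > 0,
            spec$lc_length <= 15, spec$lc_length > 0, spec$lc_diameter > 0,
            spec$background_sd >= 0, spec$ref_region_sd >= 0,
            spec$tissue_sd >= 0,
            length(spec$motion_sd) == 2, all(spec$motion_sd >= 0))
  invisible(spec)
}

# World coordinates (mm) of every voxel center, given the centered affine.
phantom_world <- function(spec) {
  aff <- affine_scaling(spec$voxel_dims, spec$grid_shape)
  list(affine = aff, xyz = voxel_grid_map(aff, spec$grid_shape))
}

# Inside-ness scores (negative = inside the analytic shape, in mm).
# Structures occupy disjoint slice bands: SNc crescents centered at
# z = +10.5 mm, LC rods at z = -10.5 mm, reference boxes alongside SNc.
phantom_scores <- function(spec, xyz) {
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  ax <- abs(x)
  # SNc: per-hemisphere crescent = outer disc minus an offset cutting disc,
  # extruded over a 3-slice band.
  d_out <- sqrt((ax - 5.5)^2 + y^2)
  d_cut <- sqrt((ax - 5.5)^2 + (y - 3.0)^2)
  snc <- pmax(d_out - 6.0, 5.0 - d_cut, abs(z - 10.5) - 4.6)
  # LC: thin rods along z, scaled isotropically to the requested volume
  # while keeping the nominal diameter:length aspect.
  nominal <- pi * (spec$lc_diameter / 2)^2 * spec$lc_length
  s <- (spec$lc_volume_true / 2 / nominal)^(1 / 3)
  lc <- pmax(sqrt((ax - 3.5)^2 + (y + 6)^2) - s * spec$lc_diameter / 2,
             abs(z + 10.5) - s * spec$lc_length / 2)
  # Reference region: bilateral boxes lateral-superior, same band as SNc.
  ref <- pmax(pmax(ax - 9, 2 - ax), pmax(y - 11.5, 6.5 - y),
              abs(z - 10.5) - 4.6)
  list(snc = snc, lc = lc, ref = ref)
}

# Pick exactly round(volume / voxel_volume) voxels, most-inside first.
# Ties (mirror-symmetric voxels) break on linear index, deterministically.
select_voxels <- function(score, volume, vdims, label) {
  n <- round(volume / prod(vdims))
  eligible <- which(score <= 0.5)
  if (n > length(eligible))
    stop("requested ", label, " volume (", volume,
         " mm^3) too large for the grid")
  eligible[order(score[eligible], eligible)[seq_len(n)]]
}

# Separable Gaussian blur with truncate-renormalize edge handling;
# sigma given per axis in voxels.
gaussian_blur3d <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 0.05) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    arr <- conv_axis(arr, k / sum(k), ax)
  }
  arr
}

conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1L) / 2L
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  out <- matrix(0, nrow = da[1], ncol = ncol(m))
  wsum <- numeric(da[1])
  for (t in -r:r) {
    w <- kernel[t + r + 1L]
    src <- seq_len(da[1]) + t
    ok <- src >= 1 & src <= da[1]
    out[ok, ] <- out[ok, ] + w * m[src[ok], ]
    wsum[ok] <- wsum[ok] + w
  }
  out <- out / wsum
  a <- array(out, dim = da)
  aperm(a, order(perm))
}

#' Generate one phantom subject
#'
#' Paints the ground-truth SNc, LC and reference regions as blocks of a 2x
#' supersampled scene grid (each acquisition voxel holds 2x2x2 scene
#' voxels), applies the acquisition blur and the tissue field on the scene
#' grid, then acquires `n_measurements` images by sampling the scene onto
#' the acquisition grid: measurement 1 at the identity pose, measurements
#' 2..n under independent small rigid jitter, each with independent
#' receiver noise. Because every measurement — including the first — is
#' produced by the same scene-to-grid sampling, partial-volume smoothing is
#' identical across the series, as in a real acquisition.
#'
#' @param spec a [phantom_spec()]
#' @return list with `measurements` (list of `voxel_image`) and
#'   `ground_truth`: SNc/LC/reference masks, the per-measurement jitter
#'   transforms (`true_transforms`; measurement 1 is identity — the inverse
#'   of transform k realigns measurement k to measurement 1), true volumes,
#'   and the probabilistic atlases + native affine for the search regions
#' @export
generate_subject <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  geom <- phantom_world(spec)
  sc <- phantom_scores(spec, geom$xyz)
  vd <- spec$voxel_dims
  vv <- prod(vd)
  shape <- spec$grid_shape

  snc_idx <- select_voxels(sc$snc, spec$snc_volume_true, vd, "SNc")
  lc_idx  <- select_voxels(sc$lc, spec$lc_volume_true, vd, "LC")
  ref_idx <- which(sc$ref <= 0)

  as_mask <- function(idx) {
    m <- array(FALSE, dim = shape); m[idx] <- TRUE
    binary_mask(m, geom$affine)
  }
  snc_mask <- as_mask(snc_idx); lc_mask <- as_mask(lc_idx)
  ref_mask <- as_mask(ref_idx)

  # 2x supersampled scene grid; each acquisition voxel holds a 2x2x2 block
  # of scene voxels, so blocky painting downsamples to exact voxel values
  fshape <- 2L * shape
  fvd <- vd / 2
  faff <- affine_scaling(fvd, fshape)
  upsample_block <- function(idx) {
    m <- array(FALSE, dim = shape); m[idx] <- TRUE
    big <- m[rep(seq_len(shape[1]), each = 2),
             rep(seq_len(shape[2]), each = 2),
             rep(seq_len(shape[3]), each = 2)]
    which(big)
  }
  scene <- array(spec$background_mean, dim = fshape)
  scene[upsample_block(ref_idx)] <- spec$ref_region_mean
  if (spec$texture_amp > 0) {
    fxyz <- voxel_grid_map(faff, fshape)
    lam <- spec$texture_wavelength
    tex <- spec$texture_amp *
      (sin(2 * pi * fxyz[, 1] / lam + 0.7) *
         cos(2 * pi * fxyz[, 2] / lam + 1.3) +
         0.5 * sin(2 * pi * fxyz[, 3] / (1.5 * lam)))
    tex[upsample_block(ref_idx)] <- 0  # reference mean stays homogeneous
    scene <- scene + array(tex, dim = fshape)
  }
  scene[upsample_block(snc_idx)] <- scene[upsample_block(snc_idx)] + spec$snc_contrast
  scene[upsample_block(lc_idx)] <- scene[upsample_block(lc_idx)] + spec$lc_contrast
  if (spec$blur_fwhm > 0)
    scene <- gaussian_blur3d(scene, spec$blur_fwhm / 2.3548200 / fvd)
  if (spec$tissue_sd > 0) {
    # fixed smooth heterogeneity, scaled so the field sampled at the
    # acquisition grid has SD exactly tissue_sd
    field <- gaussian_blur3d(array(stats::rnorm(prod(fshape)), dim = fshape),
                             c(1.2, 1.2, 6) / 2.3548200 / fvd)
    field_img <- voxel_image(field, faff)
    grid_tpl <- voxel_image(array(0, dim = shape), geom$affine)
    at_acq <- resample(field_img, rigid_transform(), grid_tpl)$data
    scene <- scene + field * (spec$tissue_sd / stats::sd(at_acq))
  }
  scene_img <- voxel_image(scene, faff)
  grid_tpl <- voxel_image(array(0, dim = shape), geom$affine)
  clean_img <- resample(scene_img, rigid_transform(), grid_tpl)

  sd_arr <- array(spec$background_sd, dim = shape)
  sd_arr[ref_idx] <- spec$ref_region_sd

  transforms <- vector("list", spec$n_measurements)
  measurements <- vector("list", spec$n_measurements)
  for (t in seq_len(spec$n_measurements)) {
    if (t == 1L || all(spec$motion_sd == 0)) {
      transforms[[t]] <- rigid_transform()
      base <- clean_img$data
    } else {
      transforms[[t]] <- rigid_transform(
        rotation = stats::rnorm(3, 0, spec$motion_sd[1]),
        translation = stats::rnorm(3, 0, spec$motion_sd[2]))
      base <- resample(scene_img, transforms[[t]], grid_tpl)$data
    }
    if (spec$noise_model == "gaussian") {
      noisy <- base + stats::rnorm(length(base), 0, as.vector(sd_arr))
    } else {
      n1 <- stats::rnorm(length(base), 0, as.vector(sd_arr))
      n2 <- stats::rnorm(length(base), 0, as.vector(sd_arr))
      noisy <- sqrt((as.vector(base) + n1)^2 + n2^2)
    }
    if (all(sd_arr == 0)) noisy <- as.vector(base)
    measurements[[t]] <- voxel_image(array(noisy, dim = shape), geom$affine)
  }

  atlases <- phantom_atlases(snc_mask, lc_mask, vd)
  list(measurements = measurements,
       ground_truth = list(
         snc_mask = snc_mask, lc_mask = lc_mask, ref_mask = ref_mask,
         true_transforms = transforms,
         true_volumes = c(snc = length(snc_idx) * vv, lc = length(lc_idx) * vv),
         snc_atlas = atlases$snc, lc_atlas = atlases$lc,
         clean = clean_img, affine = geom$affine))
}

# The phantom's own "standard-space" probabilistic atlases: the ground-truth
# masks smoothed (2 mm in-plane, one-slice leak through-plane) and peak-
# normalized, so thresholding at 5% + dilation yields a search region with
# margin around the structure. For phantoms, standard space coincides with
# native space and the ground-truth chain is the identity.
phantom_atlases <- function(snc_mask, lc_mask, vdims) {
  smooth <- function(mask) {
    p <- gaussian_blur3d(array(as.numeric(mask$data), dim = dim(mask$data)),
                         c(2, 2, 3.2) / 2.3548200 / vdims)
    prob_atlas(p / max(p), mask$affine)
  }
  list(snc = smooth(snc_mask), lc = smooth(lc_mask))
}
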