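#' Reference-region intensity statistics
#'
#' Sample mean (mu_ref) and sample SD (sigma_ref, n-1 denominator) of the
#' image intensities inside the reference ROI — the cerebral-peduncle
#' statistics that anchor the segmentation thresholds mu_ref + k*sigma_ref.
#'
#' @param image `voxel_image`
#' @param ref_mask `binary_mask` on the same grid
#' @return object of class `reference_stats`: `mu_ref`, `sigma_ref`, `n_ref`
#' @export
reference_stats <- function(image, ref_mask) {
  if (!same_grid(image, ref_mask))
    stop("reference mask must live on the image grid")
  vals <- image$data[ref_mask$data]
  if (length(vals) < 2) stop("fewer than 2 reference voxels")
  s <- stats::sd(vals)
  if (s == 0) stop("degenerate reference region: zero intensity variance")
  structure(list(mu_ref = mean(vals), sigma_ref = s, n_ref = length(vals)),
            class = "reference_stats")
}

#' Segmentation parameters
#'
#' @param k threshold multiplier: voxels with intensity strictly above
#'   mu_ref + k*sigma_ref are kept. 2.8 for SNc; 3.9 for LC (the higher LC
#'   cut compensates for susceptibility effects near the 4th ventricle).
#' @param atlas_threshold probability cut applied to the mapped atlas
#'   (default 0.05, i.e. the 5% level)
#' @param dilation_iterations binary dilations (6-connected) applied to the
#'   thresholded atlas so the search region surely covers the structure
#' @return object of class `segmentation_params`
#' @export
segmentation_params <- function(k, atlas_threshold = 0.05,
                                dilation_iterations = 2L) {
  stopifnot(k > 0, atlas_threshold > 0, atlas_threshold < 1,
            dilation_iterations >= 0)
  structure(list(k = k, atlas_threshold = atlas_threshold,
                 dilation_iterations = as.integer(dilation_iterations)),
            class = "segmentation_params")
}

#' Build the search region from a native-space atlas
#'
#' Thresholds the probabilistic atlas at `atlas_threshold` (strict >) and
#' binary-dilates the result `dilation_iterations` times with a 3D
#' 6-connected structuring element.
#'
#' @param atlas `prob_atlas` already mapped to the native grid
#' @param params [segmentation_params()]
#' @return `binary_mask` search region
#' @export
build_search_region <- function(atlas, params) {
  m <- atlas$data > params$atlas_threshold
  if (!any(m)) stop("empty search region: no atlas voxel above threshold")
  if (params$dilation_iterations > 0)
    for (i in seq_len(params$dilation_iterations)) m <- dilate6(m)
  binary_mask(m, atlas$affine)
}

# One 6-connected binary dilation (face neighbours only).
dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

#' Threshold segmentation within a search region
#'
#' The core measurement: voxels of the search region whose intensity is
#' strictly greater than mu_ref + k*sigma_ref form the structure; both
#' hemispheres contribute to one bilateral volume. An empty result is a
#' valid outcome (volume 0).
#'
#' @param image averaged `voxel_image` in native space
#' @param search `binary_mask` search region
#' @param ref [reference_stats()]
#' @param params [segmentation_params()]
#' @return object of class `segmentation_result`: `mask`, `voxel_count`,
#'   `volume` (mm^3), `threshold_value`, `params`, `ref_stats`
#' @export
segment_structure <- function(image, search, ref, params) {
  if (!same_grid(image, search)) stop("search mask must be on the image grid")
  if (!any(search$data)) stop("empty search region")
  thr <- ref$mu_ref + params$k * ref$sigma_ref
  keep <- search$data & (image$data > thr)
  mask <- binary_mask(keep, image$affine)
  vol <- mask_volume(mask)
  structure(list(mask = mask, voxel_count = sum(keep), volume = vol,
                 threshold_value = thr, params = params, ref_stats = ref),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "threshold segmentation: %d voxels, %.2f mm^3 (I > %.3f = mu_ref %+0.1f sigma_ref)\n",
    x$voxel_count, x$volume, x$threshold_value, x$params$k))
  invisible(x)
}

#' Segment SNc and LC for one subject
#'
#' The full per-subject procedure on a motion-corrected average: reference
#' statistics once from the cerebral-peduncle ROI, then per-structure
#' search-region construction and thresholding with k = 2.8 (SNc) and 3.9
#' (LC).
#'
#' @param averaged motion-corrected averaged `voxel_image`
#' @param snc_atlas,lc_atlas `prob_atlas` in native space
#' @param ref_mask `binary_mask` reference ROI in native space
#' @param params_snc,params_lc per-structure [segmentation_params()]
#' @param component_count if TRUE, also report the number of 6-connected
#'   components in each mask (informational; no filtering is applied)
#' @return list with `snc` and `lc` `segmentation_result`s and `ref_stats`
#' @export
segment_subject <- function(averaged, snc_atlas, lc_atlas, ref_mask,
                            params_snc = segmentation_params(2.8),
                            params_lc = segmentation_params(3.9),
                            component_count = FALSE) {
  ref <- reference_stats(averaged, ref_mask)
  snc <- segment_structure(averaged, build_search_region(snc_atlas, params_snc),
                           ref, params_snc)
  lc <- segment_structure(averaged, build_search_region(lc_atlas, params_lc),
                          ref, params_lc)
  if (component_count) {
    snc$n_components <- count_components6(snc$mask$data)
    lc$n_components <- count_components6(lc$mask$data)
  }
  list(snc = snc, lc = lc, ref_stats = ref)
}

# 6-connected component count by flood fill (informational reporting only).
count_components6 <- function(m) {
  d <- dim(m)
  lab <- array(0L, dim = d)
  nc <- 0L
  idx <- which(m)
  for (start in idx) {
    if (lab[start] != 0L) next
    nc <- nc + 1L
    queue <- start
    lab[start] <- nc
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      k0 <- (v - 1L) %/% (d[1] * d[2])
      rem <- (v - 1L) %% (d[1] * d[2])
      j0 <- rem %/% d[1]; i0 <- rem %% d[1]
      for (step in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
        i <- i0 + step[1]; j <- j0 + step[2]; k <- k0 + step[3]
        if (i < 0 || i >= d[1] || j < 0 || j >= d[2] || k < 0 || k >= d[3])
          next
        w <- 1L + i + d[1] * (j + d[2] * k)
        if (m[w] && lab[w] == 0L) { lab[w] <- nc; queue <- c(queue, w) }
      }
    }
  }
  nc
}
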