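test_that("reference statistics use the sample SD with n-1 denominator", {
  aff <- affine_scaling(c(1, 1, 1))
  img <- voxel_image(array(0, dim = c(3, 1, 1)), aff)
  img$data[] <- c(8, 10, 12)
  mask <- binary_mask(array(TRUE, dim = c(3, 1, 1)), aff)
  rs <- reference_stats(img, mask)
  expect_equal(rs$mu_ref, 10)
  expect_equal(rs$sigma_ref, 2)  # sqrt(((8-10)^2+(12-10)^2)/2)
  expect_equal(rs$n_ref, 3)
  const <- voxel_image(array(5, dim = c(3, 1, 1)), aff)
  expect_error(reference_stats(const, mask), "degenerate")
  tiny <- binary_mask(array(c(TRUE, FALSE, FALSE), dim = c(3, 1, 1)), aff)
  expect_error(reference_stats(img, tiny), "fewer than 2")
})

test_that("search region construction: threshold then 6-connected dilation", {
  aff <- affine_scaling(c(1, 1, 1))
  p <- array(0, dim = c(5, 5, 5))
  expect_error(build_search_region(prob_atlas(p, aff),
                                   segmentation_params(2.8)), "empty")
  p[3, 3, 3] <- 0.6
  cross <- build_search_region(prob_atlas(p, aff),
                               segmentation_params(2.8, dilation_iterations = 1))
  expect_equal(sum(cross$data), 7)  # center + 6 face neighbours
  expect_setequal(which(cross$data), c(63, 58, 68, 62, 64, 38, 88))
  raw <- build_search_region(prob_atlas(p, aff),
                             segmentation_params(2.8, dilation_iterations = 0))
  expect_equal(sum(raw$data), 1)
})

test_that("threshold segmentation keeps strictly supra-threshold voxels", {
  aff <- affine_scaling(c(1, 1, 1))
  img <- voxel_image(array(c(10, 12, 15, 20, 25, rep(0, 3)), dim = c(2, 2, 2)),
                     aff)
  search <- binary_mask(array(c(rep(TRUE, 5), rep(FALSE, 3)), dim = c(2, 2, 2)),
                        aff)
  res <- segment_structure(img, search, ref_stats_of(10, 2),
                           segmentation_params(2.8))
  expect_equal(res$threshold_value, 15.6)
  expect_equal(res$voxel_count, 2)       # 20 and 25
  expect_equal(res$volume, 2)
  # a voxel exactly at the threshold is excluded (strict inequality)
  img$data[3] <- 15.6
  res2 <- segment_structure(img, search, ref_stats_of(10, 2),
                            segmentation_params(2.8))
  expect_equal(res2$voxel_count, 2)
  # image flat at mu_ref: empty result is a valid outcome
  flat <- voxel_image(array(10, dim = c(2, 2, 2)), aff)
  res3 <- segment_structure(flat, search, ref_stats_of(10, 2),
                            segmentation_params(2.8))
  expect_equal(res3$volume, 0)
})

test_that("segmentation agrees voxel-for-voxel with brute-force enumeration", {
  set.seed(77)
  aff <- affine_scaling(c(0.39, 0.39, 3))
  for (rep in 1:200) {
    dat <- array(rnorm(16 * 16 * 8, 10, 3), dim = c(16, 16, 8))
    search <- array(runif(16 * 16 * 8) < 0.4, dim = c(16, 16, 8))
    if (!any(search)) next
    k <- sample(c(2.8, 3.9, 1), 1)
    got <- segment_structure(voxel_image(dat, aff),
                             binary_mask(search, aff),
                             ref_stats_of(10, 1.5), segmentation_params(k))
    expect_identical(got$mask$data, naive_segment(dat, search, 10, 1.5, k))
  }
})

test_that("volume is non-increasing in k and scale-equivariant", {
  set.seed(13)
  aff <- affine_scaling(c(1, 1, 1))
  dat <- array(rnorm(512, 10, 2), dim = c(8, 8, 8))
  img <- voxel_image(dat, aff)
  search <- binary_mask(array(TRUE, dim = c(8, 8, 8)), aff)
  ks <- c(0.5, 1, 1.8, 2.8, 3.9)
  vols <- sapply(ks, function(k)
    segment_structure(img, search, ref_stats_of(10, 2),
                      segmentation_params(k))$volume)
  expect_true(all(diff(vols) <= 0))
  # joint rescaling of intensities and reference stats leaves the mask fixed
  img2 <- voxel_image(dat * 3.7, aff)
  m1 <- segment_structure(img, search, ref_stats_of(10, 2),
                          segmentation_params(2.8))$mask$data
  m2 <- segment_structure(img2, search, ref_stats_of(37, 7.4),
                          segmentation_params(2.8))$mask$data
  expect_identical(m1, m2)
})

test_that("noise-free phantom volumes are recovered exactly through the full procedure", {
  sp <- phantom_spec(motion_sd = c(0, 0), background_sd = 0, ref_region_sd = 0,
                     tissue_sd = 0, blur_fwhm = 0, seed = 3)
  sub <- generate_subject(sp)
  gt <- sub$ground_truth
  avg <- motion_correct_and_average(sub$measurements, moco = FALSE)$average
  # the reference region is exactly flat here, so the generative statistics
  # stand in for the measured ones
  ref <- ref_stats_of(sp$ref_region_mean, 5)
  for (st in c("snc", "lc")) {
    k <- if (st == "snc") 2.8 else 3.9
    search <- build_search_region(gt[[paste0(st, "_atlas")]],
                                  segmentation_params(k))
    res <- segment_structure(avg, search, ref, segmentation_params(k))
    expect_equal(res$volume, gt$true_volumes[[st]])
  }
})

test_that("a structure below its threshold segments to zero volume", {
  # contrast between 2.8 and 3.9 reference-SDs: SNc survives, LC vanishes
  sp <- phantom_spec(motion_sd = c(0, 0), background_sd = 0, ref_region_sd = 0,
                     tissue_sd = 0, blur_fwhm = 0,
                     snc_contrast = 17, lc_contrast = 17, seed = 3)
  sub <- generate_subject(sp)
  gt <- sub$ground_truth
  avg <- motion_correct_and_average(sub$measurements, moco = FALSE)$average
  ref <- ref_stats_of(sp$ref_region_mean, 5)
  seg_lc <- segment_structure(avg, build_search_region(gt$lc_atlas,
                                                       segmentation_params(3.9)),
                              ref, segmentation_params(3.9))
  seg_snc <- segment_structure(avg, build_search_region(gt$snc_atlas,
                                                        segmentation_params(2.8)),
                               ref, segmentation_params(2.8))
  expect_equal(seg_lc$volume, 0)
  expect_gt(seg_snc$volume, 0)
})

test_that("segment_subject applies both structure thresholds coherently", {
  sp <- phantom_spec(seed = 17)
  sub <- generate_subject(sp)
  gt <- sub$ground_truth
  avg <- motion_correct_and_average(sub$measurements, moco = FALSE)$average
  seg <- segment_subject(avg, gt$snc_atlas, gt$lc_atlas, gt$ref_mask,
                         component_count = TRUE)
  expect_gt(seg$lc$threshold_value, seg$snc$threshold_value)
  expect_equal(seg$snc$volume,
               seg$snc$voxel_count * prod(voxel_dims(seg$snc$mask)))
  # masks never leave their search regions
  snc_search <- build_search_region(gt$snc_atlas, segmentation_params(2.8))
  expect_true(all(!seg$snc$mask$data | snc_search$data))
  expect_gte(seg$snc$n_components, 1)
})
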