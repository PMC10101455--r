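test_that("NIfTI round-trip preserves float32 data and affine exactly", {
  aff <- affine_scaling(c(0.39, 0.39, 3.0), c(6L, 5L, 4L))
  dat <- array(as.numeric(sample.int(512, 120, replace = TRUE)) / 4,
               dim = c(6, 5, 4))  # exactly float32-representable
  img <- voxel_image(dat, aff)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_image(img, f)
  back <- read_image(f)
  expect_identical(back$data, dat)
  expect_lt(max(abs(back$affine - aff)), 1e-6)
  expect_equal(voxel_dims(back), c(0.39, 0.39, 3.0), tolerance = 1e-6)
})

test_that("reading a non-3D image fails with a clear error", {
  f2d <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(0, 4, 4)), f2d)
  expect_error(read_image(f2d), "3D")
  expect_error(read_image(tempfile(fileext = ".nii")), "not found")
})

test_that("a 4D measurement series splits into per-measurement volumes", {
  sp <- phantom_spec(n_measurements = 3, snc_volume_true = 100,
                     lc_volume_true = 5, seed = 5)
  sub <- generate_subject(sp)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_series(sub$measurements, f)
  back <- read_series(f)
  expect_length(back, 3)
  expect_equal(back[[2]]$data, sub$measurements[[2]]$data, tolerance = 1e-6)
  expect_error(read_image(f), "read_series")
  expect_equal(voxel_dims(back[[1]]), c(0.39, 0.39, 3.0), tolerance = 1e-6)
})

test_that("mask_volume is the voxel count times the voxel volume", {
  aff <- affine_scaling(c(0.39, 0.39, 3.0))
  empty <- binary_mask(array(FALSE, dim = c(4, 4, 4)), aff)
  expect_equal(mask_volume(empty), 0)
  one <- array(FALSE, dim = c(4, 4, 4)); one[2, 3, 1] <- TRUE
  expect_equal(mask_volume(binary_mask(one, aff)), 0.45630, tolerance = 1e-6)
  fifteen <- array(FALSE, dim = c(8, 8, 4)); fifteen[seq_len(15)] <- TRUE
  expect_equal(mask_volume(binary_mask(fifteen, aff)), 6.8445,
               tolerance = 1e-6)
})

test_that("mask_volume is additive over disjoint masks", {
  set.seed(11)
  aff <- affine_scaling(c(0.5, 0.7, 2))
  for (rep in 1:5) {
    sel <- sample(60, 20)
    a <- array(FALSE, dim = c(5, 4, 3)); a[sel[1:10]] <- TRUE
    b <- array(FALSE, dim = c(5, 4, 3)); b[sel[11:20]] <- TRUE
    u <- binary_mask(a | b, aff)
    expect_equal(mask_volume(u),
                 mask_volume(binary_mask(a, aff)) +
                   mask_volume(binary_mask(b, aff)))
  }
})

test_that("container invariants are enforced", {
  aff <- affine_scaling(c(1, 1, 1))
  expect_error(voxel_image(matrix(0, 3, 3), aff), "3D")
  expect_error(binary_mask(array(2, dim = c(2, 2, 2)), aff), "\\{0, 1\\}")
  expect_error(prob_atlas(array(1.5, dim = c(2, 2, 2)), aff), "\\[0, 1\\]")
  bad <- aff; bad[4, 1] <- 1
  expect_error(voxel_image(array(0, dim = c(2, 2, 2)), bad), "last")
})

test_that("resample with the identity on identical grids is the identity", {
  img <- toy_image(array(rnorm(4 * 5 * 3), dim = c(4, 5, 3)),
                   c(0.39, 0.39, 3))
  out <- resample(img, rigid_transform(), img)
  expect_equal(out$data, img$data, tolerance = 1e-12)
})

test_that("one-voxel translation moves a mask by one voxel, count preserved", {
  aff <- affine_scaling(c(0.39, 0.39, 3.0), c(7L, 7L, 5L))
  m <- array(FALSE, dim = c(7, 7, 5)); m[3, 4, 2] <- TRUE
  mask <- binary_mask(m, aff)
  grid <- voxel_image(array(0, dim = c(7, 7, 5)), aff)
  shifted <- resample(mask, rigid_transform(translation = c(0.39, 0, 0)), grid)
  expect_equal(sum(shifted$data), 1)
  expect_true(shifted$data[4, 4, 2])
})

test_that("single-step composition beats sequential two-pass resampling", {
  # smooth non-linear ramp: trilinear error accumulates per pass, so the
  # composed one-pass transform must track the analytic field better
  shape <- c(24L, 24L, 6L)
  aff <- affine_scaling(c(1, 1, 2), shape)
  xyz <- voxel_grid_map(aff, shape)
  f <- function(x, y, z) sin(0.45 * x) + cos(0.35 * y) + 0.1 * z
  img <- voxel_image(array(f(xyz[, 1], xyz[, 2], xyz[, 3]), dim = shape), aff)
  t1 <- rigid_transform(translation = c(0.4, 0.3, 0.6))
  t2 <- rigid_transform(translation = c(0.35, 0.45, 0.5))
  grid <- img
  one_pass <- resample(img, compose_transforms(t1, t2), grid)
  two_pass <- resample(resample(img, t1, grid), t2, grid)
  # analytic truth: total translation d means value at x is f(x - d)
  d <- c(0.75, 0.75, 1.1)
  truth <- f(xyz[, 1] - d[1], xyz[, 2] - d[2], xyz[, 3] - d[3])
  interior <- which(abs(xyz[, 1]) < 8 & abs(xyz[, 2]) < 8 & abs(xyz[, 3]) < 3)
  err1 <- sqrt(mean((one_pass$data[interior] - truth[interior])^2))
  err2 <- sqrt(mean((two_pass$data[interior] - truth[interior])^2))
  expect_lt(err1, err2)
})

test_that("transform algebra: inverse composes to identity", {
  tr <- rigid_transform(c(3, -2, 5), c(4, -1, 2), center = c(1, 2, 3))
  comp <- compose_transforms(tr, invert_transform(tr))
  expect_lt(max(abs(transform_matrix(comp) - diag(4))), 1e-6)
  af <- affine_transform(transform_matrix(tr) %*% diag(c(1.1, 0.9, 1, 1)))
  comp2 <- compose_transforms(af, invert_transform(af))
  expect_lt(max(abs(transform_matrix(comp2) - diag(4))), 1e-9)
})

test_that("transforms serialize to JSON and back", {
  f <- withr::local_tempfile(fileext = ".json")
  tr <- rigid_transform(c(0.5, -0.2, 0.1), c(1, 2, -0.5), center = c(0, 1, 0))
  write_transform(tr, f)
  back <- read_transform(f)
  expect_equal(back$rotation, tr$rotation)
  expect_equal(back$translation, tr$translation)
  chain <- transform_chain(list(tr, affine_transform(diag(4))),
                           c("standard", "T1", "native"))
  write_transform(chain, f)
  back2 <- read_transform(f)
  expect_s3_class(back2, "transform_chain")
  expect_equal(back2$spaces, c("standard", "T1", "native"))
  expect_lt(max(abs(transform_matrix(back2) - transform_matrix(chain))), 1e-12)
})
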