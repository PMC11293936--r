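test_that("NIfTI round trip preserves values and world geometry", {
  vol <- ball_volume(radius = 8, hu = 500, spacing = 0.5)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(dim(back$values), dim(vol$values))
  expect_vector_equal(back$values, vol$values, 1e-3)
  expect_vector_equal(back$spacing, vol$spacing, 1e-6)
  expect_vector_equal(back$origin, vol$origin, 1e-4)
  expect_vector_equal(back$direction, vol$direction, 1e-6)
  unlink(path)
})

test_that("NIfTI header with 0.5 mm isotropic affine reads as 0.5 spacing", {
  vol <- ct_volume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5),
                   origin = c(1, 2, 3))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  expect_equal(read_volume(path)$spacing, c(0.5, 0.5, 0.5),
               tolerance = 1e-6)
  unlink(path)
})

test_that("DICOM rescale maps stored values to HU", {
  expect_equal(hu_rescale(1024, 1, -1024), 0)
  expect_equal(hu_rescale(c(0, 2048), 1, -1024), c(-1024, 1024))
  expect_equal(hu_rescale(100, 2, -100), 100)
})

test_that("DICOM series round trip preserves HU and geometry", {
  vol <- ball_volume(radius = 6, hu = 300, spacing = 1)
  dir <- tempfile("dcm")
  write_dicom_series(vol, dir)
  back <- read_volume(dir)
  expect_equal(dim(back$values), dim(vol$values))
  expect_vector_equal(back$values, vol$values, 0.51)  # integer storage
  expect_vector_equal(back$spacing, vol$spacing, 1e-6)
  expect_vector_equal(back$origin, vol$origin, 1e-4)
  unlink(dir, recursive = TRUE)
})

test_that("broken DICOM series are reported with offending slices", {
  vol <- ball_volume(radius = 5, hu = 300, spacing = 1)
  dir <- tempfile("dcm")
  write_dicom_series(vol, dir)
  files <- list.files(dir, full.names = TRUE)
  file.remove(files[4])             # missing slice
  expect_error(read_volume(dir), "missing slices")
  unlink(dir, recursive = TRUE)
})

test_that("resampling is exact on identity and constant volumes", {
  vol <- ball_volume(radius = 6, hu = 120, spacing = 1)
  d <- dim(vol$values)
  out <- resample_to_frame(vol, vol$origin, diag(3), vol$spacing, d)
  expect_vector_equal(out$values, vol$values, 1e-9)
  cvol <- ct_volume(array(42, c(12, 12, 12)), origin = c(-6, -6, -6))
  Rz <- pctmorph:::rotation_about_axis(c(0, 0, 1), 30)
  rot <- resample_to_frame(cvol, c(-2, -2, -2), Rz, 1, c(5, 5, 5))
  expect_vector_equal(rot$values, array(42, c(5, 5, 5)), 1e-9)
})

test_that("trilinear interpolation is exact on an affine (ramp) field", {
  ax <- 0:20
  g <- expand.grid(x = ax, y = ax, z = ax)
  vol <- ct_volume(array(g$x, c(21, 21, 21)))
  Rz <- pctmorph:::rotation_about_axis(c(0, 0, 1), 25)
  out <- resample_to_frame(vol, c(6, 6, 6), Rz, 0.7, c(8, 8, 8))
  # expected: HU = world x of each resampled voxel
  i <- as.matrix(expand.grid(0:7, 0:7, 0:7))
  world_x <- (sweep(i, 2, 0.7, "*") %*% t(Rz))[, 1] + 6
  expect_lt(max(abs(as.vector(out$values) - world_x)), 1e-6)
})

test_that("double resampling reproduces interior values of a smooth
           field within twice the single-interpolation error", {
  # affine field: single trilinear interpolation is exact, so the round
  # trip must reproduce interior voxels to numerical precision
  ax <- 0:24
  g <- expand.grid(x = ax, y = ax, z = ax)
  vol <- ct_volume(array(g$x + 0.5 * g$y + 0.25 * g$z, c(25, 25, 25)))
  Rz <- pctmorph:::rotation_about_axis(c(1, 1, 0), 20)
  fwd <- resample_to_frame(vol, c(2, 2, 2), Rz, 0.8, c(26, 26, 26),
                           fill = NA)
  back <- resample_to_frame(fwd, vol$origin, diag(3), vol$spacing,
                            dim(vol$values), fill = NA)
  core <- back$values[9:17, 9:17, 9:17] - vol$values[9:17, 9:17, 9:17]
  expect_gt(sum(!is.na(core)), 100)
  expect_lt(max(abs(core), na.rm = TRUE), 1e-6)
})

test_that("world/index mapping round-trips and mirrors correctly", {
  vol <- ct_volume(array(rnorm(60), c(3, 4, 5)), spacing = c(1, 2, 3),
                   origin = c(-1, 5, 2))
  idx <- rbind(c(0, 0, 0), c(2, 3, 4), c(1, 2, 2))
  expect_vector_equal(world_to_index(vol, index_to_world(vol, idx)), idx,
                      1e-10)
  m <- mirror_sagittal(vol)
  # a world point and its mirror image carry the same value
  p <- index_to_world(vol, c(1, 2, 3))
  pm <- p * c(-1, 1, 1)
  expect_equal(sample_world(m, matrix(pm, 1)), sample_world(vol, matrix(p, 1)),
               tolerance = 1e-9)
})
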