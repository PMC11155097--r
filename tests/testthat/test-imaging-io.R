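# Volume/MIP/mask I/O, subtraction and projection.

test_that("NIfTI volume round trip preserves values and spacing", {
  vol <- array(runif(4 * 6 * 5, 0, 100), dim = c(4, 6, 5))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f, spacing = c(2, 0.7, 0.7))
  got <- load_volume(f, "nifti")
  expect_equal(got$volume, vol, ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(got$spacing, c(2, 0.7, 0.7), tolerance = 1e-6)
})

test_that("loading a missing or non-3D NIfTI errors clearly", {
  expect_error(load_volume(file.path(tempdir(), "nope.nii"), "nifti"),
               "not found")
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(1, dim = c(3, 3, 3, 2))), f)
  expect_error(load_volume(f, "nifti"), "3D")
})

test_that("subtraction is element-wise with negatives clamped to zero", {
  pre <- array(c(5, 10, 0, 7), dim = c(1, 2, 2))
  post <- array(c(9, 4, 3, 7), dim = c(1, 2, 2))
  expect_equal(as.vector(compute_subtraction(pre, post)), c(4, 0, 3, 0))
  expect_error(compute_subtraction(pre, array(0, dim = c(1, 2, 3))),
               "shapes differ")
})

test_that("axial MIP equals the per-pixel maximum over slices", {
  vol <- array(rnorm(3 * 4 * 5)^2, dim = c(3, 4, 5))
  mip <- compute_axial_mip(vol, pixel_spacing = c(0.5, 0.5), case_id = "c1")
  brute <- matrix(0, 4, 5)
  for (r in 1:4) for (c in 1:5) brute[r, c] <- max(vol[, r, c])
  expect_s3_class(mip, "mip_image")
  expect_equal(mip$pixels, brute)
  expect_equal(mip$pixel_spacing, c(0.5, 0.5))
  expect_error(compute_axial_mip(matrix(1, 3, 3)), "3D")
})

test_that("mask round trips through PNG and NIfTI preserve the raster", {
  mk <- binary_mask(matrix(runif(20 * 30) > 0.6, 20, 30), role = "tumor")
  fp <- withr::local_tempfile(fileext = ".png")
  fn <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(mk, fp)
  write_mask(mk, fn)
  expect_equal(read_mask(fp, "tumor")$pixels, mk$pixels)
  expect_equal(read_mask(fn, "tumor")$pixels, mk$pixels)
  expect_error(read_mask(fp, "tumor", expect_dim = c(10, 10)),
               "does not match")
})

test_that("an empty vessel mask is accepted with a warning (edited state)", {
  f <- withr::local_tempfile(fileext = ".png")
  write_mask(binary_mask(matrix(FALSE, 8, 8), role = "vessel"), f)
  expect_warning(m <- read_mask(f, role = "vessel"), "empty")
  expect_false(any(m$pixels))
})

test_that("MIP image round trips through NIfTI exactly and TIFF up to scale", {
  px <- matrix(runif(32 * 32, 0, 400), 32, 32)
  mip <- mip_image(px, pixel_spacing = c(0.8, 0.8), case_id = "rt")
  fn <- withr::local_tempfile(fileext = ".nii.gz")
  ft <- withr::local_tempfile(fileext = ".tif")
  write_mip(mip, fn)
  write_mip(mip, ft)
  rn <- read_mip(fn)
  expect_equal(rn$pixels, px, tolerance = 1e-6)
  expect_equal(rn$pixel_spacing, c(0.8, 0.8), tolerance = 1e-6)
  rt <- read_mip(ft)
  # 16-bit TIFF rescales to the full range; correlation must survive
  expect_gt(stats::cor(as.vector(rt$pixels), as.vector(px)), 0.999999)
})

test_that("a DICOM series loads with the correct geometry and values", {
  set.seed(31)
  px1 <- matrix(sample(0:3000, 6 * 8), 6, 8)
  px2 <- matrix(sample(0:3000, 6 * 8), 6, 8)
  px3 <- matrix(sample(0:3000, 6 * 8), 6, 8)
  d <- withr::local_tempdir()
  write_dicom_series_dir(d, list(px2, px1, px3), c(2.5, 0, 5),
                         pixel_spacing = c(0.6, 0.9), slice_spacing = 2.5)
  got <- load_volume(d, "dicom_dir")
  expect_equal(dim(got$volume), c(3, 6, 8))
  expect_equal(got$spacing, c(2.5, 0.6, 0.9))
  # slices come back ordered by slice location
  expect_equal(got$volume[1, , ], px1 + 0)
  expect_equal(got$volume[2, , ], px2 + 0)
  expect_equal(got$volume[3, , ], px3 + 0)
})

test_that("a DICOM series with a missing slice is rejected", {
  px <- matrix(100, 4, 4)
  d <- withr::local_tempdir()
  # locations 0, 2, 6: one slice of the uniform grid is absent
  write_dicom_series_dir(d, list(px, px, px), c(0, 2, 6))
  expect_error(load_volume(d, "dicom_dir"), "missing slice")
})

test_that("unsupported DICOM transfer syntaxes are rejected", {
  d <- withr::local_tempdir()
  write_dicom_slice(file.path(d, "s1.dcm"), matrix(10, 4, 4), 0,
                    transfer_syntax = "1.2.840.10008.1.2.4.70")
  expect_error(load_volume(d, "dicom_dir"), "transfer syntax")
})
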