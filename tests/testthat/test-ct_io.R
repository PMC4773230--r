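# CT volume I/O: DICOM series, NIfTI volumes, mask serialization.

test_that("hand-assembled DICOM bytes decode to the expected HU grid", {
  dir <- withr::local_tempdir()
  # two slices, 2x2 pixels, stored row-major; slope 1, intercept -1024
  write_raw_dicom_slice(file.path(dir, "a.dcm"),
                        stored = c(1024, 1025, 1026, 1027),
                        rows = 2, cols = 2, z = 0)
  write_raw_dicom_slice(file.path(dir, "b.dcm"),
                        stored = c(2024, 24, 524, 1024),
                        rows = 2, cols = 2, z = 2.5)
  v <- read_dicom_series(dir)
  expect_equal(dim(v$voxels), c(2, 2, 2))
  # stored 1024 with intercept -1024 is HU 0; row-major pixel order
  expect_equal(v$voxels[1, 1, ], c(0, 1))
  expect_equal(v$voxels[1, 2, ], c(2, 3))
  expect_equal(v$voxels[2, 1, ], c(1000, -1000))
  expect_equal(v$voxels[2, 2, ], c(-500, 0))
  # spacing: inter-slice distance, then row/column pixel spacing
  expect_equal(v$spacing_mm, c(2.5, 0.8, 0.75))
})

test_that("a written series re-reads voxel-identical, regardless of file order", {
  set.seed(11)
  vox <- array(round(rnorm(4 * 8 * 8, -500, 300)), c(4, 8, 8))
  v <- ct_volume(vox, c(1.25, 0.6, 0.7), patient_id = "rt")
  dir <- withr::local_tempdir()
  write_dicom_series(v, dir)
  v2 <- read_dicom_series(dir)
  expect_identical(v2$voxels, v$voxels)
  expect_equal(v2$spacing_mm, v$spacing_mm)
  expect_equal(v2$patient_id, "rt")

  # shuffle on disk: reversed file names must not change the volume
  dir2 <- withr::local_tempdir()
  files <- list.files(dir, full.names = TRUE)
  file.copy(files, file.path(dir2, sprintf("Z_%04d.dcm", rev(seq_along(files)))))
  v3 <- read_dicom_series(dir2)
  expect_identical(v3$voxels, v$voxels)
})

test_that("reading is deterministic and rescale calibration is honoured", {
  dir <- withr::local_tempdir()
  write_raw_dicom_slice(file.path(dir, "s.dcm"), stored = rep(512, 9),
                        rows = 3, cols = 3, z = 0, slope = 2,
                        intercept = -1024)
  a <- read_dicom_series(dir)
  b <- read_dicom_series(dir)
  expect_identical(a, b)
  expect_true(all(a$voxels == 2 * 512 - 1024))
})

test_that("mixed series and missing rescale tags are refused", {
  dir <- withr::local_tempdir()
  write_raw_dicom_slice(file.path(dir, "a.dcm"), stored = rep(0, 4),
                        rows = 2, cols = 2, z = 0, series = "1.2.3")
  write_raw_dicom_slice(file.path(dir, "b.dcm"), stored = rep(0, 4),
                        rows = 2, cols = 2, z = 1, series = "9.9.9")
  expect_error(read_dicom_series(dir), "inconsistent series")

  dir2 <- withr::local_tempdir()
  write_raw_dicom_slice(file.path(dir2, "a.dcm"), stored = rep(0, 4),
                        rows = 2, cols = 2, z = 0, rescale = FALSE)
  expect_error(read_dicom_series(dir2), "uncalibrated data")
})

test_that("NIfTI round-trip preserves voxels and anisotropic spacing", {
  set.seed(12)
  v <- ct_volume(array(round(rnorm(3 * 6 * 5, -700, 200)), c(3, 6, 5)),
                 c(1, 0.5, 0.5))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(v, f)
  v2 <- read_nifti(f)
  expect_equal(v2$voxels, v$voxels)
  expect_equal(v2$spacing_mm, c(1, 0.5, 0.5))
})

test_that("4-D NIfTI input is refused", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f)
  expect_error(read_nifti(f), "3-D")
})

test_that("DICOM and NIfTI reads of the same volume agree within 0.5 HU", {
  set.seed(13)
  v <- ct_volume(array(round(rnorm(4 * 10 * 10, -600, 250)), c(4, 10, 10)),
                 c(1, 0.7, 0.7))
  dir <- withr::local_tempdir()
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_dicom_series(v, dir)
  write_nifti(v, f)
  vd <- read_dicom_series(dir)
  vn <- read_nifti(f)
  expect_lt(max(abs(vd$voxels - vn$voxels)), 0.5)
})

test_that("mask serialization keeps geometry, flag counts, and {0,1} values", {
  v <- ct_volume(array(-850, c(4, 6, 6)), c(1, 1, 1))
  m0 <- voxel_mask(array(FALSE, c(4, 6, 6)), "empty")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(m0, v, f)
  expect_equal(sum(as.array(RNifti::readNifti(f))), 0)

  set.seed(14)
  m1 <- voxel_mask(array(runif(4 * 6 * 6) > 0.5, c(4, 6, 6)), "rand")
  write_mask(m1, v, f)
  m2 <- read_mask(f, "rand")
  expect_identical(m2$flags, m1$flags)

  bad <- voxel_mask(array(TRUE, c(4, 6, 5)), "bad")
  expect_error(write_mask(bad, v, f), "dimensions")
})

test_that("HU values are clamped to the 12-bit CT range on construction", {
  v <- ct_volume(array(c(-3000, -1024.5, 0, 5000), c(1, 2, 2)), c(1, 1, 1))
  expect_equal(sort(as.vector(v$voxels)), c(-1024, -1024, 0, 3071))
  expect_error(ct_volume(array(0, c(2, 2)), c(1, 1, 1)), "3-D")
  expect_error(ct_volume(array(0, c(2, 2, 2)), c(1, 0, 1)), "positive")
})
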