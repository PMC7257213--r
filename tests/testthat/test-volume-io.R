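test_that("volume constructor enforces its invariants", {
  expect_error(volume(matrix(1, 2, 2)), "3D")
  expect_error(volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)), "positive")
  expect_error(volume(array(c(1, NA), c(2, 1, 1))), "finite")
  v <- volume(array(1:8, c(2, 2, 2)), spacing = c(1, 2, 3),
              origin = c(-1, 0, 1))
  expect_s3_class(v, "volume")
  expect_equal(vol_spacing(v), c(1, 2, 3))
  expect_equal(vol_origin(v), c(-1, 0, 1))
})

test_that("label volumes demand a complete legend and matched grid", {
  expect_error(label_volume(array(5L, c(2, 2, 2))), "legend")
  lv <- label_volume(array(c(0L, 1L, 2L, 0L), c(2, 2, 1)))
  expect_equal(label_legend(lv), c(background = 0L, vessel = 1L,
                                   aneurysm = 2L))
})

test_that("NIfTI round-trip is the identity on data and geometry", {
  v <- rand_volume(c(8, 8, 8), spacing = c(0.5, 0.5, 1.2),
                   origin = c(10, -5, 3), seed = 2)
  f <- tempfile(fileext = ".nii.gz")
  write_nifti(v, f)
  r <- read_nifti(f)
  expect_identical(dim(r), dim(v))
  expect_equal(max(abs(r - v)), 0)
  expect_equal(vol_spacing(r), vol_spacing(v), tolerance = 1e-6)
  expect_equal(vol_origin(r), vol_origin(v), tolerance = 1e-6)
})

test_that("corrupt NIfTI input raises a format error", {
  f <- tempfile(fileext = ".nii")
  writeBin(as.raw(1:64), f)
  expect_error(suppressWarnings(read_nifti(f)), "NIfTI")
  expect_error(read_nifti(tempfile(fileext = ".nii")), "not found")
})

test_that("DICOM series reading honours metadata and slice order", {
  dir <- write_dicom_fixture(tempfile("dcm"), spacing = c(0.7, 0.8, 1.2))
  expect_false(is.null(dir)) # pydicom oracle writer available in this stack
  v <- read_dicom_series(dir)
  expect_identical(dim(v), c(5L, 6L, 4L))
  expect_equal(vol_spacing(v), c(0.7, 0.8, 1.2), tolerance = 1e-9)
  expect_equal(vol_origin(v), c(1, 2, 5))
  # shuffled file order yields the identical volume
  dir2 <- write_dicom_fixture(tempfile("dcmshuf"), shuffle = TRUE)
  v2 <- read_dicom_series(dir2)
  expect_equal(as.vector(v2), as.vector(v))
})

test_that("degenerate DICOM directories raise format errors", {
  d <- tempfile("empty")
  dir.create(d)
  expect_error(read_dicom_series(d), "no files")
  expect_error(read_dicom_series(tempfile("missing")), "directory")
})

test_that("resampling to isotropic spacing preserves extent and labels", {
  v <- rand_volume(c(100, 100, 50), spacing = c(1, 1, 1.2), seed = 3)
  r <- resample_isotropic(v, 1)
  expect_identical(dim(r), c(100L, 100L, 60L)) # round(50 * 1.2 / 1)
  expect_equal(vol_spacing(r), c(1, 1, 1))
  # identity when already at the target
  expect_identical(as.vector(resample_isotropic(r, 1)), as.vector(r))
  # constant stays constant
  cv <- volume(array(7, c(10, 10, 10)), spacing = c(1, 1, 2))
  expect_true(all(resample_isotropic(cv, 1) == 7))
  # nearest mode never invents label values
  lv <- label_volume(array(sample(c(0L, 1L, 2L), 4 * 4 * 4, TRUE),
                           c(4, 4, 4)), spacing = c(1, 1, 1.7))
  rl <- resample_isotropic(lv, 1, mode = "nearest")
  expect_true(all(unique(as.vector(rl)) %in% unique(as.vector(lv))))
  expect_error(resample_isotropic(lv, 1, mode = "linear"), "nearest")
  expect_error(resample_isotropic(v, -1), "positive")
})

test_that("crop_to_content finds the tight box and keeps world coordinates", {
  v <- box_volume(c(20, 20, 20), lo = c(6, 7, 3), hi = c(10, 11, 7))
  cv <- crop_to_content(v, 0)
  expect_identical(dim(cv), c(5L, 5L, 5L))
  expect_equal(vol_origin(cv), c(5, 6, 2)) # (lo - 1) * spacing
  expect_true(all(cv == 100))
  # volume entirely above threshold is unchanged
  w <- volume(array(5, c(3, 3, 3)))
  expect_identical(dim(crop_to_content(w, 0)), dim(w))
  expect_error(crop_to_content(volume(array(0, c(3, 3, 3))), 0), "empty")
  # crop then pad back reproduces content voxels exactly
  box <- attr(cv, "crop_box")
  back <- array(0, dim(v))
  back[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <-
    as.vector(cv)
  expect_equal(back, unclass(v), ignore_attr = TRUE)
})

test_that("mesh writing round-trips and validates faces", {
  tet <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                      rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
  fo <- tempfile(fileext = ".obj")
  fs <- tempfile(fileext = ".stl")
  write_mesh(tet, fo)
  write_mesh(tet, fs)
  ro <- read_mesh(fo)
  rs <- read_mesh(fs)
  expect_identical(nrow(ro$vertices), 4L)
  expect_identical(nrow(ro$faces), 4L)
  expect_identical(nrow(rs$faces), nrow(ro$faces))
  expect_equal(ro$vertices, tet$vertices, ignore_attr = TRUE)
  expect_error(surface_mesh(tet$vertices, rbind(c(1, 2, 9))), "range")
  expect_error(write_mesh(surface_mesh(matrix(0, 0, 3),
                                       matrix(0L, 0, 3)), fo), "empty")
})
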