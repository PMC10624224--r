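test_that("pa_volume validates amplitudes and spacing", {
  a <- array(1, c(2, 3, 4))
  v <- pa_volume(a, 5, 5, 7.5, label = "lesional")
  expect_s3_class(v, "pa_volume")
  expect_identical(dim(v), c(2L, 3L, 4L))
  expect_error(pa_volume(matrix(1, 2, 2), 5, 5, 7.5), "rank-3")
  expect_error(pa_volume(array(-1, c(2, 2, 2)), 5, 5, 7.5), "non-negative")
  expect_error(pa_volume(a, 0, 5, 7.5), "positive")
  expect_error(pa_volume(a, 5, 5, -1), "positive")
})

test_that("uint16 TIFF round-trips integer amplitudes exactly with metadata", {
  dir <- withr::local_tempdir()
  set.seed(1)
  a <- array(sample(0:65535, 8 * 8 * 4, replace = TRUE), c(8, 8, 4))
  v <- pa_volume(a, 5, 5, 7.5)
  p <- file.path(dir, "v.tif")
  write_volume(v, p)
  r <- read_volume(p, spacing = c(5, 5, 7.5))
  expect_identical(dim(r), c(8L, 8L, 4L))
  expect_equal(r$dz, 7.5)
  expect_true(all(r$amplitude == a))
})

test_that("float32 TIFF preserves values to single precision", {
  dir <- withr::local_tempdir()
  set.seed(2)
  v <- pa_volume(array(runif(6 * 5 * 3), c(6, 5, 3)), 5, 5, 7.5)
  p1 <- file.path(dir, "a.tif"); p2 <- file.path(dir, "b.tif")
  write_volume(v, p1)
  r1 <- read_volume(p1, spacing = c(5, 5, 7.5))
  # values survive to single precision on every trip
  write_volume(r1, p2)
  r2 <- read_volume(p2, spacing = c(5, 5, 7.5))
  expect_equal(r2$amplitude, r1$amplitude, tolerance = 1e-7)
  expect_equal(max(abs(r1$amplitude - v$amplitude)), 0, tolerance = 1e-6)
})

test_that("TIFF export rejects unrepresentable dynamic range", {
  dir <- withr::local_tempdir()
  v <- pa_volume(array(runif(8) * 100, c(2, 2, 2)), 5, 5, 7.5)
  expect_error(write_volume(v, file.path(dir, "x.tif")), "NIfTI")
})

test_that("NIfTI round-trips arbitrary volumes bit-exactly, phantom included", {
  dir <- withr::local_tempdir()
  ph <- generate_phantom(small_spec("epidermal_m", seed = 3))
  p <- file.path(dir, "ph.nii")
  write_volume(ph$volume, p)
  r <- read_volume(p)
  expect_identical(r$amplitude + 0, ph$volume$amplitude)
  expect_equal(c(r$dx, r$dy, r$dz), c(5, 5, 7.5))
  # zero volume
  z <- pa_volume(array(0, c(4, 4, 4)), 1, 1, 2)
  write_volume(z, file.path(dir, "z.nii"))
  expect_identical(read_volume(file.path(dir, "z.nii"))$amplitude + 0, z$amplitude)
})

test_that("negative stored voxels are clipped to zero with a count", {
  dir <- withr::local_tempdir()
  a <- array(runif(27), c(3, 3, 3))
  a[2, 2, 2] <- -3
  p <- file.path(dir, "neg.nii")
  RNifti::writeNifti(RNifti::asNifti(a, reference = list(pixdim = c(-1, 5, 5, 5, 0, 0, 0, 0)),
                                     datatype = "double"), p)
  expect_warning(v <- read_volume(p), "1 negative voxel")
  expect_identical(v$amplitude[2, 2, 2], 0)
})

test_that("reader errors name the offending path and contract violations", {
  dir <- withr::local_tempdir()
  expect_error(read_volume(file.path(dir, "missing.tif"), c(5, 5, 5)), "not found")
  p <- file.path(dir, "v.tif")
  write_volume(pa_volume(array(0:7, c(2, 2, 2)), 5, 5, 5), p)
  expect_error(read_volume(p), "spacing")
  expect_error(read_volume(p, spacing = c(5, 5)), "three positive")
  # rank-2 NIfTI is rejected
  p2 <- file.path(dir, "m.nii")
  RNifti::writeNifti(RNifti::asNifti(matrix(1, 4, 4), datatype = "double"), p2)
  expect_error(read_volume(p2), "rank 3")
  writeLines("x", file.path(dir, "v.xyz"))
  expect_error(read_volume(file.path(dir, "v.xyz"), c(5, 5, 5)), "format")
})

test_that("pages map to depth in file order; a permuted stack reads back permuted", {
  dir <- withr::local_tempdir()
  set.seed(4)
  a <- array(sample(0:100, 4 * 4 * 5, replace = TRUE), c(4, 4, 5))
  v <- pa_volume(a, 5, 5, 7.5)
  perm <- c(5, 3, 1, 2, 4)
  vp <- pa_volume(a[, , perm], 5, 5, 7.5)
  p1 <- file.path(dir, "v.tif"); p2 <- file.path(dir, "vp.tif")
  write_volume(v, p1); write_volume(vp, p2)
  r <- read_volume(p2, spacing = c(5, 5, 7.5))
  expect_true(all(r$amplitude == a[, , perm]))
  expect_false(all(r$amplitude == a))
  expect_true(all(read_volume(p1, spacing = c(5, 5, 7.5))$amplitude == a))
})

test_that("case manifests round-trip both volumes and enforce shared spacing", {
  dir <- withr::local_tempdir()
  les <- pa_volume(array(sample(0:50, 64, TRUE), c(4, 4, 4)), 5, 5, 7.5, "lesional")
  ctl <- pa_volume(array(sample(0:50, 64, TRUE), c(4, 4, 4)), 5, 5, 7.5, "non_lesional")
  man <- write_case(les, ctl, dir, case_id = "P9", format = "nii", notes = "cheek")
  cs <- read_case(man)
  expect_s3_class(cs, "pa_case")
  expect_identical(cs$case_id, "P9")
  expect_identical(cs$lesional$amplitude + 0, les$amplitude + 0)
  expect_identical(cs$control$amplitude + 0, ctl$amplitude + 0)
  expect_identical(cs$lesional$label, "lesional")
  bad <- pa_volume(array(0, c(4, 4, 4)), 5, 5, 10)
  expect_error(write_case(les, bad, dir), "identical voxel spacing")
})
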