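test_that("NIfTI and NRRD round-trips preserve intensities and geometry", {
  vol <- small_phantom$ph$volume
  for (ext in c(".nii.gz", ".nrrd")) {
    f <- tempfile(fileext = ext)
    write_volume(vol, f)
    back <- read_volume(f)
    expect_lt(max(abs(back$data - vol$data)), 0.5)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
    expect_equal(dim(back$data), dim(vol$data))
    unlink(f)
  }
})

test_that("masks round-trip as binary with lung structure recoverable", {
  m <- small_phantom$ph$mask
  f <- tempfile(fileext = ".nii.gz")
  write_volume(m, f)
  back <- read_volume(f, mask = TRUE)
  expect_identical(back$data, m$data)
  unlink(f)
})

test_that("non-3D input is rejected with an explicit error", {
  f <- tempfile(fileext = ".nii.gz")
  arr4 <- array(rnorm(8^3 * 2), c(8, 8, 8, 2))
  RNifti::writeNifti(RNifti::asNifti(arr4), f)
  expect_error(read_volume(f), "expected 3D")
  unlink(f)
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
})

test_that("externally written NRRD headers parse spacing correctly", {
  # attached-header NRRD with a 'spacings' field, as other tools emit
  f <- tempfile(fileext = ".nrrd")
  con <- file(f, "wb")
  hdr <- paste0("NRRD0004\n# produced elsewhere\ntype: float\ndimension: 3\n",
                "sizes: 8 8 8\nendian: little\nencoding: raw\nspacings: 1 1 1\n\n")
  writeChar(hdr, con, eos = NULL)
  writeBin(as.numeric(seq_len(512)), con, size = 4, endian = "little")
  close(con)
  v <- read_volume(f)
  expect_equal(v$spacing, c(1, 1, 1))
  expect_equal(v$data[1, 1, 1], 1)
  expect_equal(v$data[8, 8, 8], 512)
  unlink(f)
})

test_that("resampling follows the extent/target shape rule", {
  arr <- array(rnorm(32^3, -800, 50), c(32, 32, 32))
  v2 <- fg_volume(arr, spacing = c(2, 2, 2))
  r <- resample_isotropic(v2, 1)
  expect_equal(dim(r$data), c(64, 64, 64))
  expect_equal(r$spacing, c(1, 1, 1))
  # identity: already isotropic at target
  v1 <- fg_volume(arr, spacing = c(1, 1, 1))
  expect_identical(resample_isotropic(v1, 1), v1)
  # constant volume stays constant under any resampling
  vc <- fg_volume(array(-700, c(16, 16, 16)), spacing = c(1.7, 1.1, 2.3))
  rc <- resample_isotropic(vc, 1)
  expect_true(all(abs(rc$data + 700) < 1e-10))
  expect_error(resample_isotropic(v1, 0), "positive")
})

test_that("mask resampling preserves binarity and approximate volume", {
  m <- small_phantom$ph$mask
  m2 <- fg_mask(m$data, spacing = c(2, 2, 2), lung = m$lung)
  r <- resample_isotropic(m2, 1)
  expect_type(r$data, "logical")
  vol_in <- sum(m2$data) * 8
  vol_out <- sum(r$data) * 1
  expect_lt(abs(vol_out - vol_in) / vol_in, 0.05)
  # idempotent at target spacing
  expect_identical(resample_isotropic(r, 1), r)
})
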