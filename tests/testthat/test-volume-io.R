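test_that("TIFF stacks round-trip exactly for uint16 volumes and labels", {
  set.seed(11)
  arr <- array(sample(0:65535, 3 * 5 * 4, replace = TRUE), c(3, 5, 4))
  v <- IntensityVolume(arr)
  p <- withr::local_tempfile(fileext = ".tif")
  writeTiffStack(v, p)
  back <- readTiffStack(p)
  expect_identical(volData(back), volData(v))

  lab <- array(0L, c(2, 3, 3))
  lab[1, 1, 1] <- 1L; lab[2, 3, 3] <- 2L; lab[1, 2, 2] <- 2L
  writeTiffStack(LabelVolume(lab), p)
  expect_identical(volData(readTiffStack(p)), lab)
  expect_setequal(unique(as.vector(volData(readTiffStack(p)))),
                  c(0L, 1L, 2L))

  zero <- LabelVolume(array(0L, c(4, 2, 2)))
  writeTiffStack(zero, p)
  expect_true(all(volData(readTiffStack(p)) == 0L))
})

test_that("8-bit stacks are widened without rescaling (0-255 preserved)", {
  p <- withr::local_tempfile(fileext = ".tif")
  slices <- list(matrix(0, 4, 4), matrix(c(0, 128, 255, 7) / 255, 2, 2))
  # heterogeneous page shapes must be rejected
  tiff::writeTIFF(list(matrix(0, 2, 2), matrix(0, 3, 3)), p,
                  bits.per.sample = 8L)
  expect_error(readTiffStack(p), "page shapes")

  tiff::writeTIFF(list(matrix(c(0, 128, 255, 7) / 255, 2, 2),
                       matrix(255 / 255, 2, 2)), p, bits.per.sample = 8L)
  v <- readTiffStack(p)
  expect_identical(dim(v), c(2L, 2L, 2L))
  expect_equal(max(volData(v)), 255L)
  expect_true(all(volData(v) >= 0L & volData(v) <= 255L))
  expect_setequal(as.vector(volData(v)[1, , ]), c(0L, 128L, 255L, 7L))

  # ten-page all-zero stack
  tiff::writeTIFF(rep(list(matrix(0, 3, 2)), 10), p, bits.per.sample = 8L)
  z <- readTiffStack(p)
  expect_identical(dim(z), c(10L, 3L, 2L))
  expect_true(all(volData(z) == 0L))
})

test_that("float stacks require and honour an input range", {
  p <- withr::local_tempfile(fileext = ".tif")
  write_raw_tiff(p, list(matrix(c(-1, 0.5, 0, 2), 2, 2)), 32L, "float")
  expect_error(readTiffStack(p), "inputRange")
  v <- readTiffStack(p, inputRange = c(0, 2))
  # clipped to [0, 2] then mapped 0 -> 0, 2 -> 65535, half-up rounding
  expect_identical(dim(v), c(1L, 2L, 2L))
  # array order is (z, y, x): m[1,1], m[2,1], m[1,2], m[2,2]
  expect_identical(as.vector(volData(v)),
                   as.integer(c(0, floor(0.5 / 2 * 65535 + 0.5), 0, 65535)))
})

test_that("signed 16-bit stacks are un-wrapped and range-mapped", {
  p <- withr::local_tempfile(fileext = ".tif")
  write_raw_tiff(p, list(matrix(c(-1000L, 0L, 500L, 2000L), 2, 2)),
                 16L, "int")
  expect_error(readTiffStack(p), "inputRange")
  v <- readTiffStack(p, inputRange = c(0, 1000))
  # (z, y, x) order: -1000 -> clip 0, 0 -> 0, 500 -> half-up, 2000 -> clip
  expect_identical(as.vector(volData(v)),
                   as.integer(c(0, 0, floor(0.5 * 65535 + 0.5), 65535)))
})

test_that("RGB input is rejected with the encountered type named", {
  p <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(4, 4, 3)), p, bits.per.sample = 8L)
  expect_error(readTiffStack(p), "samples per pixel|RGB")
  expect_error(readTiffStack(file.path(tempdir(), "nope-missing.tif")),
               "no such file")
})

test_that("writeTiffStack enforces the 16-bit label capacity", {
  big <- array(0L, c(1, 1, 2))
  big[1, 1, 1] <- 70000L
  expect_error(writeTiffStack(big, tempfile(fileext = ".tif")),
               "65535")
})

test_that("convertToU16 applies the bit-depth conversion rules", {
  a8 <- array(c(0L, 1L, 254L, 255L), c(1, 2, 2))
  v8 <- convertToU16(a8, "u8")
  expect_identical(volData(v8), a8)  # widened, not stretched

  a16 <- array(c(0L, 65535L), c(1, 1, 2))
  expect_identical(volData(convertToU16(a16, "u16")), a16)

  # affine endpoint mapping with clipping, and half-up midpoint
  f <- array(c(-10, 2, 11, (2 + 10) / 2), c(1, 2, 2))
  vf <- convertToU16(f, "f32", inputRange = c(2, 10))
  expect_identical(as.vector(volData(vf)), c(0L, 0L, 65535L, 32768L))

  expect_error(convertToU16(f, "f32"), "inputRange")
  expect_error(convertToU16(f, "f32", inputRange = c(5, 5)), "low < high")
  expect_error(convertToU16(array(300L, c(1, 1, 1)), "u8"), "\\[0, 255\\]")
})

test_that("convertToU16 is monotone on its input", {
  set.seed(3)
  x <- sort(runif(50, -100, 100))
  v <- convertToU16(array(x, c(50, 1, 1)), "f32", inputRange = c(-40, 60))
  expect_true(all(diff(as.vector(volData(v))) >= 0L))
  xi <- sort(sample(-32768:32767, 64))
  vi <- convertToU16(array(xi, c(64, 1, 1)), "i16",
                     inputRange = c(-1000, 1000))
  expect_true(all(diff(as.vector(volData(vi))) >= 0L))
})

test_that("downsampleVolume computes rounded block means", {
  v <- IntensityVolume(array(7L, c(5, 4, 3)))
  one <- downsampleVolume(v, 1)
  expect_identical(volData(one), volData(v))  # identity at factor 1

  d2 <- downsampleVolume(v, c(2, 2, 2))
  expect_identical(dim(d2), c(3L, 2L, 2L))    # ceil(5/2), ceil(4/2), ceil(3/2)
  expect_true(all(volData(d2) == 7L))         # constant stays constant

  set.seed(21)
  arr <- array(sample(0:65535, 64, replace = TRUE), c(4, 4, 4))
  got <- volData(downsampleVolume(IntensityVolume(arr), 2))
  # hand-computed block means, rounded half-up
  want <- array(0L, c(2, 2, 2))
  for (z in 1:2) for (y in 1:2) for (x in 1:2) {
    blk <- arr[(2 * z - 1):(2 * z), (2 * y - 1):(2 * y),
               (2 * x - 1):(2 * x)]
    want[z, y, x] <- as.integer(floor(mean(blk) + 0.5))
  }
  expect_identical(got, want)

  expect_error(downsampleVolume(v, 0), "factor")
  expect_error(downsampleVolume(v, c(1, 2)), "factor")
})
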