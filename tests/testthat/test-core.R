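test_that("buildSchedule implements the linear threshold descent", {
  s <- buildSchedule(bountiParams(35000, 27000, 10, 28))
  expect_identical(exactStep(s), 800)
  expect_identical(thresholds(s), as.integer(seq(35000, 27000, by = -800)))

  s3 <- buildSchedule(bountiParams(33000, 27000, 3, 1))
  expect_identical(thresholds(s3), c(33000L, 31000L, 29000L, 27000L))

  # degenerate: IT == TT
  sd <- buildSchedule(bountiParams(27000, 27000, 7, 1))
  expect_true(all(thresholds(sd) == 27000L))
  expect_identical(length(thresholds(sd)), 8L)

  # endpoints exact, non-increasing, length NI + 1
  s150 <- buildSchedule(bountiParams(35000, 27000, 150, 28))
  expect_identical(thresholds(s150)[1], 35000L)
  expect_identical(thresholds(s150)[151], 27000L)
  expect_true(all(diff(thresholds(s150)) <= 0L))
  expect_identical(thresholdStep(s150), 53L)  # floor of 53.33

  expect_error(bountiParams(27000, 35000, 10, 28), "initialThreshold")
  expect_error(bountiParams(35000, 27000, 0, 28), "numIterations")
})

test_that("iterationsForStep enforces exact division", {
  expect_identical(iterationsForStep(30000, 27000, 50), 60L)
  expect_identical(iterationsForStep(40000, 27000, 50), 260L)
  expect_error(iterationsForStep(30025, 27000, 50), "30025")
})

test_that("growOnce is a fixed point when the mask adds nothing", {
  vol <- IntensityVolume(array(c(50000L, 10L), c(2, 2, 2)))
  cc <- labelComponents(volData(vol) >= 40000L)
  lab <- cc$labels
  expect_identical(labelArray(growOnce(lab, vol, 40000)),
                   labelArray(lab))
})

test_that("growOnce splits a corridor between two seeds by the tie rule", {
  # 7-voxel straight corridor, 1-voxel seeds at the ends
  arr <- array(0L, c(1, 1, 9))
  arr[1, 1, 2:8] <- 30000L
  arr[1, 1, 2] <- 50000L
  arr[1, 1, 8] <- 50000L
  vol <- IntensityVolume(arr)
  seedlab <- array(0L, c(1, 1, 9))
  seedlab[1, 1, 2] <- 1L
  seedlab[1, 1, 8] <- 2L
  out <- labelArray(growOnce(LabelVolume(seedlab), vol, 30000))
  # centre voxel (x = 5) is equidistant and goes to label 1
  expect_identical(as.vector(out[1, 1, ]),
                   c(0L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 0L))
})

test_that("growOnce leaves unreachable mask components background", {
  arr <- array(0L, c(1, 3, 3))
  arr[1, 1, ] <- 45000L   # seeded line
  arr[1, 3, ] <- 30000L   # separate line, above cit but unreachable
  vol <- IntensityVolume(arr)
  lab <- array(0L, c(1, 3, 3)); lab[1, 1, 1] <- 1L
  out <- labelArray(growOnce(LabelVolume(lab), vol, 30000))
  expect_true(all(out[1, 1, ] == 1L))
  expect_true(all(out[1, 3, ] == 0L))
})

test_that("bounti separates bridged bodies that direct thresholding merges", {
  ph <- two_body_phantom()
  params <- bountiParams(35000, 27000, 10, 2)
  res <- bounti(ph$volume, params)
  expect_identical(nSegments(res), 2L)
  expect_true(all(segmentSizes(res) > 0L))
  # direct target threshold: a single connected component
  tt_cc <- labelComponents(volData(ph$volume) >= 27000L)
  expect_identical(length(tt_cc$sizes), 1L)
  # seed labels survive into the result
  sd <- resultSeed(res)
  on_seed <- labelArray(sd) > 0L
  expect_identical(labelArray(res)[on_seed], labelArray(sd)[on_seed])
})

test_that("bounti snapshots record the requested iterations", {
  ph <- two_body_phantom()
  res <- bounti(ph$volume, bountiParams(35000, 27000, 8, 2),
                snapshotAt = c(0, 4, 8))
  expect_identical(names(snapshots(res)), c("0", "4", "8"))
  expect_identical(labelArray(snapshots(res)[["0"]]),
                   labelArray(resultSeed(res)))
  expect_identical(labelArray(snapshots(res)[["8"]]), labelArray(res))
})

test_that("an initial threshold above the volume maximum is an actionable error", {
  vol <- IntensityVolume(array(100L, c(3, 3, 3)))
  expect_error(bounti(vol, bountiParams(50000, 90, 5, 2)),
               "lower the initial threshold")
  expect_error(seedPreview(vol, bountiParams(50000, 90, 5, 2)),
               "lower the initial threshold")
})

test_that("seedPreview returns exactly the seed a run would use", {
  ph <- two_body_phantom()
  params <- bountiParams(35000, 27000, 5, 2, dilate = TRUE)
  pre <- seedPreview(ph$volume, params)
  res <- bounti(ph$volume, params)
  expect_identical(labelArray(pre), labelArray(resultSeed(res)))
  expect_true(pre@dilated)

  # three bodies above IT, NS = 2: the two largest are kept
  spec3 <- phantomSpec(
    size = c(40L, 40L, 40L),
    bodies = list(
      list(centre = c(20, 20, 8), radius = 6, intensity = 40000),
      list(centre = c(20, 20, 24), radius = 5, intensity = 40000),
      list(centre = c(20, 20, 35), radius = 3, intensity = 40000)),
    bridges = list(), noiseSigma = 0, blurSigma = 0)
  ph3 <- makePhantom(spec3)
  pre3 <- seedPreview(ph3$volume, bountiParams(35000, 27000, 5, 2))
  expect_identical(nSegments(pre3), 2L)
  # the retained segments cover the two largest bodies
  expect_true(all(labelArray(pre3)[labelArray(ph3$groundTruth) == 1L] == 1L))
  expect_true(all(labelArray(pre3)[labelArray(ph3$groundTruth) == 2L] == 2L))
  expect_true(all(labelArray(pre3)[labelArray(ph3$groundTruth) == 3L] == 0L))
})

test_that("a manual preserve-mode seed keeps touching segments separate", {
  arr <- array(20000L, c(1, 1, 7))
  arr[1, 1, 3:5] <- 45000L
  vol <- IntensityVolume(arr)
  lab <- array(0L, c(1, 1, 7))
  lab[1, 1, 3] <- 1L; lab[1, 1, 4] <- 2L  # touching manual segments
  seed <- manualSeed(lab, "preserve")
  res <- bounti(vol, bountiParams(45000, 10000, 4, 2), seed = seed)
  out <- labelArray(res)
  expect_identical(out[1, 1, 3], 1L)
  expect_identical(out[1, 1, 4], 2L)
  expect_identical(nSegments(res), 2L)
  expect_true(all(out > 0L))  # whole line reached at TT 10000
})
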