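# end-to-end command layer on a small phantom written to disk

small_phantom_files <- function(dir) {
  sp <- phantomSpec(size = c(32L, 32L, 32L),
                    bodies = list(
                      list(centre = c(16, 16, 9), radius = 4,
                           intensity = 40000),
                      list(centre = c(16, 16, 23), radius = 4,
                           intensity = 40000)),
                    bridges = list(list(a = 1L, b = 2L, thickness = 3,
                                        intensity = 30000)),
                    noiseSigma = 0, blurSigma = 0)
  vol <- file.path(dir, "phantom.tif")
  truth <- file.path(dir, "truth.tif")
  cmdPhantom(sp, vol, truth)
  list(volume = vol, truth = truth, spec = sp)
}

test_that("cmdSegment writes labels, snapshots and a parseable report", {
  dir <- withr::local_tempdir()
  ph <- small_phantom_files(dir)
  out <- file.path(dir, "seg.tif")
  cfg <- runConfig(ph$volume, out,
                   bountiParams(35000, 27000, 6, 2),
                   snapshots = c(0, 3, 6), logLevel = "quiet")
  got <- cmdSegment(cfg)
  expect_true(file.exists(out))
  snaps <- file.path(dir, sprintf("seg_iter%04d.tif", c(0, 3, 6)))
  expect_true(all(file.exists(snaps)))
  lab <- volData(readTiffStack(out))
  expect_identical(sort(unique(as.vector(lab))), c(0L, 1L, 2L))
  expect_identical(lab, labelArray(got$result))

  report <- jsonlite::read_json(file.path(dir, "seg_report.json"),
                                simplifyVector = TRUE)
  expect_equal(report$params$initialThreshold, 35000)
  expect_equal(report$schedule$reportedStep, 1333)  # floor(8000/6)
  expect_length(report$schedule$thresholds, 7L)
  expect_identical(report$seed$provenance, "auto")
  expect_length(report$segmentSizes, 2L)
})

test_that("cmdSeedPreview exports the seed and dilation enlarges it", {
  dir <- withr::local_tempdir()
  ph <- small_phantom_files(dir)
  off <- file.path(dir, "seed_off.tif")
  on <- file.path(dir, "seed_on.tif")
  cmdSeedPreview(runConfig(ph$volume, off,
                           bountiParams(35000, 27000, 5, 2),
                           logLevel = "quiet"))
  cmdSeedPreview(runConfig(ph$volume, on,
                           bountiParams(35000, 27000, 5, 2,
                                        dilate = TRUE),
                           logLevel = "quiet"))
  a <- volData(readTiffStack(off))
  b <- volData(readTiffStack(on))
  expect_true(all(b[a > 0L] == a[a > 0L]))
  expect_gt(sum(b > 0L), sum(a > 0L))  # dilated support is a superset

  bad <- runConfig(ph$volume, file.path(dir, "x.tif"),
                   bountiParams(60000, 27000, 5, 2), logLevel = "quiet")
  expect_error(cmdSeedPreview(bad), "lower the initial threshold")
})

test_that("cmdDice scores a written segmentation against the truth stack", {
  dir <- withr::local_tempdir()
  ph <- small_phantom_files(dir)
  out <- file.path(dir, "seg.tif")
  cmdSegment(runConfig(ph$volume, out, bountiParams(35000, 27000, 6, 2),
                       logLevel = "quiet"))
  rep <- cmdDice(out, ph$truth)
  expect_s4_class(rep, "DiceReport")
  expect_gte(meanDice(rep), 0.95)
})

test_that("runSweep adjusts iterations for a fixed step and reports provenance", {
  ph <- two_body_phantom()
  base <- bountiParams(35000, 27000, 10, 2)
  sw <- runSweep(ph$volume,
                 sweepSpec("initial_threshold", c(33000, 35000),
                           keepStep = 1000),
                 base)
  expect_identical(sw$summary$numIterations, c(6L, 8L))
  expect_identical(sw$summary$initialThreshold, c(33000, 35000))
  expect_identical(sw$summary$segmentsFound, c(2L, 2L))
  expect_true(all(c("targetThreshold", "connectivity", "dilate",
                    "elapsedSeconds") %in% names(sw$summary)))

  expect_error(runSweep(ph$volume,
                        sweepSpec("initial_threshold", c(33500),
                                  keepStep = 1000),
                        base),
               "33500")

  # a single-value iterations sweep reproduces a plain run
  one <- runSweep(ph$volume, sweepSpec("iterations", 10), base)
  plain <- bounti(ph$volume, base)
  expect_identical(labelArray(one$results[["10"]]), labelArray(plain))
})

test_that("a size sweep downsamples and still finds both bodies", {
  ph <- two_body_phantom()
  base <- bountiParams(35000, 27000, 4, 2)
  sw <- runSweep(ph$volume, sweepSpec("size", c(1, 2)), base)
  expect_identical(sw$summary$voxels, c(48L^3, 24L^3))
  expect_identical(sw$summary$segmentsFound, c(2L, 2L))
  expect_true(all(sw$summary$elapsedSeconds >= 0))
})

test_that("cmdSweep writes per-value stacks and an append-only summary", {
  dir <- withr::local_tempdir()
  ph <- small_phantom_files(dir)
  cfg <- runConfig(ph$volume, file.path(dir, "sweep.tif"),
                   bountiParams(35000, 27000, 4, 2), logLevel = "quiet")
  cmdSweep(sweepSpec("iterations", c(2, 4)), cfg)
  expect_true(file.exists(file.path(dir, "sweep_iterations_2.tif")))
  expect_true(file.exists(file.path(dir, "sweep_iterations_4.tif")))
  summaryPath <- file.path(dir, "sweep_sweep_summary.tsv")
  s1 <- utils::read.delim(summaryPath)
  expect_identical(nrow(s1), 2L)
  cmdSweep(sweepSpec("iterations", c(3)), cfg)
  s2 <- utils::read.delim(summaryPath)
  expect_identical(nrow(s2), 3L)  # appended, not overwritten
  expect_true(all(c("mode", "value", "numIterations",
                    "segmentsFound") %in% names(s2)))
})

test_that("config files parse and malformed lines are rejected", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "run.cfg")
  writeLines(c("# a comment", "initial-threshold = 35000",
               "target-threshold=27000", "", "dilate = true"), p)
  cfg <- readConfigFile(p)
  expect_identical(cfg[["initial-threshold"]], "35000")
  expect_identical(cfg[["dilate"]], "true")
  writeLines("oops no equals", p)
  expect_error(readConfigFile(p), "malformed")
})

test_that("the shell interface segments a phantom end to end", {
  dir <- withr::local_tempdir()
  ph <- small_phantom_files(dir)
  cli <- system.file("cli", "bounti-cli.R", package = "bounti")
  expect_true(nzchar(cli))
  out <- file.path(dir, "cli_seg.tif")
  status <- system2("Rscript",
                    c(cli, "segment", "--input", ph$volume,
                      "--output", out,
                      "--initial-threshold", "35000",
                      "--target-threshold", "27000",
                      "--iterations", "4", "--segments", "2",
                      "--log-level", "quiet"),
                    stdout = TRUE, stderr = TRUE)
  expect_identical(attr(status, "status"), NULL)  # exit 0
  expect_true(file.exists(out))
  lab <- volData(readTiffStack(out))
  expect_identical(max(lab), 2L)

  # parameter errors surface as a non-zero exit with a message
  bad <- suppressWarnings(system2("Rscript",
                 c(cli, "segment", "--input", ph$volume,
                   "--output", out,
                   "--initial-threshold", "20000",
                   "--target-threshold", "27000",
                   "--iterations", "4", "--segments", "2"),
                 stdout = TRUE, stderr = TRUE))
  expect_identical(attr(bad, "status"), 1L)
  expect_true(any(grepl("initialThreshold", bad)))
})
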