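# Command layer: file-in/file-out wrappers around the segmentation
# functions, shared by the shell interface in inst/cli/bounti-cli.R.

.logMsg <- function(config, level, ...) {
  ranks <- c(quiet = 0L, info = 1L, debug = 2L)
  if (ranks[[config@logLevel]] >= ranks[[level]])
    message("[", level, "] ", ...)
  invisible(NULL)
}

.loadSeedFromConfig <- function(config) {
  if (!length(config@seedPath)) return(NULL)
  lab <- readTiffStack(config@seedPath)
  manualSeed(LabelVolume(volData(lab)), mode = config@seedMode,
             ns = config@params@numSegments,
             connectivity = config@params@connectivity)
}

.snapshotPath <- function(output, iteration) {
  base <- tools::file_path_sans_ext(output)
  sprintf("%s_iter%04d.%s", base, iteration,
          tools::file_ext(output))
}

#' Segment a TIFF stack end to end
#'
#' Reads the input volume, builds (or loads) the seed, runs the
#' boundary-preserving threshold iteration, and writes the label stack,
#' any requested snapshot stacks, and a machine-readable JSON report
#' (parameters, schedule, seed and final per-segment sizes, warnings).
#'
#' @param config a [RunConfig].
#' @return Invisibly, a list with the [SegmentationResult], the paths
#'   written (\code{files}) and any warnings collected.
#' @export
cmdSegment <- function(config) {
  stopifnot(is(config, "RunConfig"))
  vol <- readTiffStack(config@input)
  seed <- .loadSeedFromConfig(config)
  warnings <- character(0)
  res <- withCallingHandlers(
    bounti(vol, config@params, seed = seed,
           snapshotAt = config@snapshots),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  files <- config@output
  writeTiffStack(res, config@output)
  for (nm in names(res@snapshots)) {
    p <- .snapshotPath(config@output, as.integer(nm))
    writeTiffStack(res@snapshots[[nm]], p)
    files <- c(files, p)
  }
  k <- nSegments(res)
  ns <- config@params@numSegments
  .logMsg(config, "info", "seed components: ", k, " of ", ns,
          " requested; labeled voxels: ", sum(segmentSizes(res)))
  if (k < ns)
    .logMsg(config, "info", "fewer seed components than requested: ",
            "if expected segments are missing, lower the initial ",
            "threshold")
  report <- list(
    params = list(initialThreshold = config@params@initialThreshold,
                  targetThreshold = config@params@targetThreshold,
                  numIterations = config@params@numIterations,
                  numSegments = config@params@numSegments,
                  connectivity = config@params@connectivity,
                  dilate = config@params@dilate),
    schedule = list(step = exactStep(res@schedule),
                    reportedStep = thresholdStep(res@schedule),
                    thresholds = thresholds(res@schedule)),
    seed = list(provenance = provenance(res@seed),
                dilated = res@seed@dilated,
                segmentSizes = segmentSizes(res@seed)),
    segmentSizes = segmentSizes(res),
    warnings = warnings)
  reportPath <- paste0(tools::file_path_sans_ext(config@output),
                       "_report.json")
  jsonlite::write_json(report, reportPath, auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, reportPath)
  invisible(list(result = res, files = files, warnings = warnings))
}

#' Extract and export the seed without iterating
#'
#' @param config a [RunConfig]; the seed label stack is written to
#'   \code{config@output}.
#' @return Invisibly, a list with the [Seed] and the path written.
#' @export
cmdSeedPreview <- function(config) {
  stopifnot(is(config, "RunConfig"))
  vol <- readTiffStack(config@input)
  seed <- .autoSeed(vol, config@params)
  writeTiffStack(seed, config@output)
  .logMsg(config, "info", "seed has ", nSegments(seed),
          " segment(s) of ", config@params@numSegments, " requested")
  invisible(list(seed = seed, files = config@output))
}

#' Generate a phantom and write volume + ground truth stacks
#'
#' @param spec a [PhantomSpec].
#' @param volumePath path for the grey-value stack.
#' @param truthPath path for the ground-truth label stack.
#' @return Invisibly, the phantom list from [makePhantom()].
#' @export
cmdPhantom <- function(spec, volumePath, truthPath) {
  ph <- makePhantom(spec)
  writeTiffStack(ph$volume, volumePath)
  writeTiffStack(ph$groundTruth, truthPath)
  invisible(ph)
}

#' Score a segmentation stack against a reference stack
#'
#' @param resultPath path to a label TIFF stack.
#' @param referencePath path to the reference label TIFF stack.
#' @return A [DiceReport].
#' @export
cmdDice <- function(resultPath, referencePath) {
  res <- LabelVolume(volData(readTiffStack(resultPath)))
  ref <- LabelVolume(volData(readTiffStack(referencePath)))
  diceReport(res, ref)
}

#' Run a sensitivity sweep and export per-value stacks plus a summary
#'
#' One label stack is written per swept value
#' (\code{<output>_<mode>_<value>.tif}); the summary table, including
#' the full parameter provenance and elapsed time of each run, is
#' appended (tab-delimited) to \code{<output>_sweep_summary.tsv}.
#'
#' @param spec a [SweepSpec].
#' @param config a [RunConfig]; \code{config@output} is the naming stem.
#' @return Invisibly, the list from [runSweep()] plus the files written.
#' @export
cmdSweep <- function(spec, config) {
  stopifnot(is(spec, "SweepSpec"), is(config, "RunConfig"))
  vol <- readTiffStack(config@input)
  sw <- runSweep(vol, spec, config@params)
  base <- tools::file_path_sans_ext(config@output)
  ext <- tools::file_ext(config@output)
  files <- character(0)
  for (key in names(sw$results)) {
    p <- sprintf("%s_%s_%s.%s", base, spec@mode, key, ext)
    writeTiffStack(sw$results[[key]], p)
    files <- c(files, p)
  }
  summaryPath <- paste0(base, "_sweep_summary.tsv")
  utils::write.table(sw$summary, summaryPath, sep = "\t",
                     row.names = FALSE, quote = FALSE,
                     col.names = !file.exists(summaryPath),
                     append = file.exists(summaryPath))
  .logMsg(config, "info", "sweep complete: ", nrow(sw$summary),
          " run(s); summary appended to ", summaryPath)
  invisible(c(sw, list(files = c(files, summaryPath))))
}

#' Parse a flat key=value configuration file
#'
#' Lines are \code{key = value}; blank lines and \code{#} comments are
#' ignored. Keys mirror the command-line flags
#' (\code{initial-threshold}, \code{target-threshold},
#' \code{iterations}, \code{segments}, \code{connectivity},
#' \code{dilate}, \code{input}, \code{output}, \code{seed},
#' \code{seed-mode}, \code{snapshots}, \code{log-level}).
#'
#' @param path path to the configuration file.
#' @return A named character vector.
#' @export
readConfigFile <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]])
  vals <- vapply(kv, function(x) trimws(x[3L]), "")
  names(vals) <- vapply(kv, function(x) trimws(x[2L]), "")
  vals
}
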