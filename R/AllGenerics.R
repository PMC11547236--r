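#' @name bounti-accessors
#' @title Accessors for bounti classes
#'
#' @description Slot accessors: use these rather than \code{@}.
#' \code{volData} returns the grey-value array of an [IntensityVolume];
#' \code{labelArray} the integer label array of a [LabelVolume], [Seed]
#' or [SegmentationResult]; \code{segmentSizes} the per-label voxel
#' counts; \code{nSegments} the number of labels; \code{thresholds} the
#' schedule's per-iteration thresholds; \code{thresholdStep} the integer
#' step reported to the user (\code{floor((IT - TT) / NI)}) and
#' \code{exactStep} the exact rational step; \code{snapshots} the
#' intermediate labelings recorded during a run.
#'
#' @param x the object.
#' @return See description.
#' @examples
#' p <- bountiParams(35000, 27000, 150, 28)
#' thresholdStep(buildSchedule(p))  # 53
NULL

#' @rdname bounti-accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname bounti-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname bounti-accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @rdname bounti-accessors
#' @export
setGeneric("segmentSizes", function(x) standardGeneric("segmentSizes"))
#' @rdname bounti-accessors
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))
#' @rdname bounti-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname bounti-accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
#' @rdname bounti-accessors
#' @export
setGeneric("thresholdStep", function(x) standardGeneric("thresholdStep"))
#' @rdname bounti-accessors
#' @export
setGeneric("exactStep", function(x) standardGeneric("exactStep"))
#' @rdname bounti-accessors
#' @export
setGeneric("bountiParameters", function(x) standardGeneric("bountiParameters"))
#' @rdname bounti-accessors
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))
#' @rdname bounti-accessors
#' @export
setGeneric("resultSeed", function(x) standardGeneric("resultSeed"))
#' @rdname bounti-accessors
#' @export
setGeneric("snapshots", function(x) standardGeneric("snapshots"))
#' @rdname bounti-accessors
#' @export
setGeneric("perSegmentDice", function(x) standardGeneric("perSegmentDice"))

#' Mean Dice score of a report
#'
#' @param x a [DiceReport].
#' @param includeMissing logical; include unmatched reference segments
#'   as zeros (the conservative convention) or average over matched
#'   segments only.
#' @return numeric scalar in \code{[0, 1]}.
#' @export
setGeneric("meanDice", function(x, includeMissing = TRUE)
  standardGeneric("meanDice"))

setMethod("volData", "IntensityVolume", function(x) x@data)
setMethod("spacing", "IntensityVolume", function(x) x@spacing)
setMethod("labelArray", "LabelVolume", function(x) x@labels)
setMethod("labelArray", "Seed", function(x) x@labels@labels)
setMethod("labelArray", "SegmentationResult", function(x) x@labels@labels)
setMethod("segmentSizes", "Seed", function(x) x@segmentSizes)
setMethod("segmentSizes", "SegmentationResult", function(x) x@segmentSizes)
setMethod("nSegments", "LabelVolume", function(x) max(x@labels))
setMethod("nSegments", "Seed", function(x) length(x@segmentSizes))
setMethod("nSegments", "SegmentationResult", function(x) length(x@segmentSizes))
setMethod("provenance", "Seed", function(x) x@provenance)
setMethod("thresholds", "ThresholdSchedule", function(x) x@thresholds)
setMethod("thresholds", "SegmentationResult", function(x) x@schedule@thresholds)
setMethod("thresholdStep", "ThresholdSchedule", function(x) as.integer(floor(x@step)))
setMethod("exactStep", "ThresholdSchedule", function(x) x@step)
setMethod("bountiParameters", "SegmentationResult", function(x) x@params)
setMethod("schedule", "SegmentationResult", function(x) x@schedule)
setMethod("resultSeed", "SegmentationResult", function(x) x@seed)
setMethod("snapshots", "SegmentationResult", function(x) x@snapshots)
setMethod("perSegmentDice", "DiceReport", function(x) x@perSegment)
setMethod("meanDice", "DiceReport", function(x, includeMissing = TRUE)
  if (includeMissing) x@meanWithMissing else x@meanWithoutMissing)

#' @describeIn bounti-accessors dimensions of the voxel grid
#' @export
setMethod("dim", "IntensityVolume", function(x) dim(x@data))
#' @rdname bounti-accessors
#' @export
setMethod("dim", "LabelVolume", function(x) dim(x@labels))
#' @rdname bounti-accessors
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@mask))

setMethod("show", "IntensityVolume", function(object) {
  d <- dim(object@data)
  cat("IntensityVolume ", d[1], " x ", d[2], " x ", d[3],
      " (z,y,x), uint16 grey values in [", min(object@data), ", ",
      max(object@data), "]\n", sep = "")
  if (length(object@spacing) == 3L)
    cat("  voxel spacing (dz,dy,dx):", paste(object@spacing, collapse = " x "),
        "um\n")
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat("LabelVolume ", d[1], " x ", d[2], " x ", d[3], " (z,y,x), ",
      max(object@labels), " segment(s), ",
      sum(object@labels > 0L), " labeled voxel(s)\n", sep = "")
})

setMethod("show", "Seed", function(object) {
  cat("Seed (", object@provenance,
      if (object@dilated) ", dilated" else "", "): ",
      length(object@segmentSizes), " segment(s)\n", sep = "")
  if (length(object@segmentSizes))
    cat("  voxel counts:",
        paste(utils::head(object@segmentSizes, 10L), collapse = ", "),
        if (length(object@segmentSizes) > 10L) "..." else "", "\n")
})

setMethod("show", "BountiParams", function(object) {
  cat("BountiParams: IT=", object@initialThreshold,
      " TT=", object@targetThreshold,
      " NI=", object@numIterations, " NS=", object@numSegments,
      " connectivity=", object@connectivity,
      " dilate=", object@dilate, "\n", sep = "")
})

setMethod("show", "ThresholdSchedule", function(object) {
  ni <- length(object@thresholds) - 1L
  cat("ThresholdSchedule: ", ni, " iteration(s), step ",
      format(object@step), " (reported ", floor(object@step), "), ",
      object@thresholds[1L], " -> ", object@thresholds[ni + 1L], "\n",
      sep = "")
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult: ", length(object@segmentSizes),
      " segment(s), ", sum(object@segmentSizes), " labeled voxel(s)\n",
      sep = "")
  show(object@params)
  if (length(object@snapshots))
    cat("  snapshots at iterations:",
        paste(names(object@snapshots), collapse = ", "), "\n")
})

setMethod("show", "DiceReport", function(object) {
  cat("DiceReport over ", length(object@perSegment),
      " reference segment(s)\n", sep = "")
  cat("  mean Dice (missing counted as 0): ",
      format(object@meanWithMissing, digits = 4), "\n", sep = "")
  cat("  mean Dice (matched only):         ",
      format(object@meanWithoutMissing, digits = 4), "\n", sep = "")
})
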