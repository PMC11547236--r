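#' @useDynLib bounti, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.U16MAX <- 65535L

#' IntensityVolume: a 3D grid of unsigned 16-bit grey values
#'
#' The working representation of a CT (or other tomographic) volume.
#' Grey values are dimensionless attenuation surrogates stored as R
#' integers in \code{[0, 65535]}; axis order is \code{(z, y, x)} with z
#' the slice (TIFF page) index. Optional voxel spacing is
#' \code{(dz, dy, dx)} in micrometres.
#'
#' @slot data integer 3D array of grey values in \code{[0, 65535]}.
#' @slot spacing numeric of length 0 (unknown) or 3, voxel edge lengths
#'   in micrometres, \code{(dz, dy, dx)}.
#'
#' @seealso [IntensityVolume()], [readTiffStack()], [convertToU16()]
#' @exportClass IntensityVolume
setClass("IntensityVolume",
  representation(data = "array", spacing = "numeric"),
  prototype(data = array(0L, c(1L, 1L, 1L)), spacing = numeric(0)))

setValidity("IntensityVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("data must be a 3D array")
  if (any(dim(d) < 1L))
    return("all three dimensions must be strictly positive")
  if (!is.integer(d))
    return("data must have integer storage mode")
  if (anyNA(d))
    return("data must not contain NA")
  r <- range(d)
  if (r[1L] < 0L || r[2L] > .U16MAX)
    return("grey values must lie in [0, 65535]")
  if (!(length(object@spacing) %in% c(0L, 3L)))
    return("spacing must have length 0 or 3")
  if (length(object@spacing) == 3L && any(object@spacing <= 0))
    return("spacing must be positive")
  TRUE
})

#' LabelVolume: a 3D grid of non-negative integer segment labels
#'
#' Aligned voxel-for-voxel with the [IntensityVolume] it annotates;
#' label 0 is background, labels \code{1..K} are segments.
#'
#' @slot labels integer 3D array of labels, all \code{>= 0}.
#'
#' @seealso [LabelVolume()], [bounti()]
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(labels = "array"),
  prototype(labels = array(0L, c(1L, 1L, 1L))))

setValidity("LabelVolume", function(object) {
  l <- object@labels
  if (length(dim(l)) != 3L)
    return("labels must be a 3D array")
  if (!is.integer(l))
    return("labels must have integer storage mode")
  if (anyNA(l))
    return("labels must not contain NA")
  if (any(l < 0L))
    return("labels must be non-negative")
  TRUE
})

#' BinaryMask: a thresholded (superlevel-set) volume
#'
#' The voxels of a volume at or above a grey-value threshold.
#'
#' @slot mask logical 3D array.
#' @slot thresholdUsed numeric, the grey value the mask was taken at
#'   (\code{NA} if not derived from a threshold).
#'
#' @seealso [thresholdMask()]
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(mask = "array", thresholdUsed = "numeric"),
  prototype(mask = array(FALSE, c(1L, 1L, 1L)), thresholdUsed = NA_real_))

setValidity("BinaryMask", function(object) {
  if (length(dim(object@mask)) != 3L)
    return("mask must be a 3D array")
  if (!is.logical(object@mask))
    return("mask must be logical")
  if (length(object@thresholdUsed) != 1L)
    return("thresholdUsed must be a scalar")
  TRUE
})

#' Seed: the initial segmentation the iteration grows from
#'
#' Either the NS largest connected components of the initial-threshold
#' superlevel set (provenance \code{"auto"}), or a user-supplied label
#' volume (\code{"manual_preserve"} / \code{"manual_largest"}).
#'
#' @slot labels a [LabelVolume] with labels \code{1..K}.
#' @slot segmentSizes integer vector of per-label voxel counts
#'   (index i = label i). Non-increasing for auto seeds.
#' @slot provenance one of \code{"auto"}, \code{"manual_preserve"},
#'   \code{"manual_largest"}.
#' @slot dilated logical; has the one-voxel dilation been applied.
#'
#' @seealso [seedPreview()], [manualSeed()], [dilateSeed()]
#' @exportClass Seed
setClass("Seed",
  representation(labels = "LabelVolume", segmentSizes = "integer",
                 provenance = "character", dilated = "logical"),
  prototype(provenance = "auto", dilated = FALSE, segmentSizes = integer(0)))

setValidity("Seed", function(object) {
  if (!(object@provenance %in% c("auto", "manual_preserve", "manual_largest")))
    return("provenance must be auto, manual_preserve or manual_largest")
  k <- length(object@segmentSizes)
  mx <- max(object@labels@labels)
  if (mx != k)
    return("segmentSizes length must equal the number of labels")
  if (object@provenance == "auto" && !object@dilated && k > 1L &&
      any(diff(object@segmentSizes) > 0L))
    return("auto seed segment sizes must be non-increasing")
  if (length(object@dilated) != 1L) return("dilated must be a scalar")
  TRUE
})

#' BountiParams: the four operator parameters plus engine options
#'
#' Holds the initial threshold IT (high grey value yielding
#' disarticulated components), target threshold TT (low grey value with
#' the desired bone definition), the number of iterations NI of the
#' descending threshold schedule, and the number of segments NS retained
#' from the seed; plus the voxel neighbourhood scheme and the optional
#' one-voxel seed dilation.
#'
#' @slot initialThreshold numeric IT in \code{[0, 65535]}, \code{>= targetThreshold}.
#' @slot targetThreshold numeric TT in \code{[0, 65535]}.
#' @slot numIterations integer NI \code{>= 1}.
#' @slot numSegments integer NS \code{>= 1} (at most 65535, the label
#'   capacity of a 16-bit export).
#' @slot connectivity integer, one of 6 (faces), 18 (faces+edges),
#'   26 (faces+edges+corners).
#' @slot dilate logical, expand each seed segment by one voxel before
#'   iterating.
#'
#' @seealso [bountiParams()], [buildSchedule()], [bounti()]
#' @exportClass BountiParams
setClass("BountiParams",
  representation(initialThreshold = "numeric", targetThreshold = "numeric",
                 numIterations = "integer", numSegments = "integer",
                 connectivity = "integer", dilate = "logical"),
  prototype(connectivity = 26L, dilate = FALSE))

setValidity("BountiParams", function(object) {
  it <- object@initialThreshold; tt <- object@targetThreshold
  if (length(it) != 1L || length(tt) != 1L || is.na(it) || is.na(tt))
    return("thresholds must be scalars")
  if (it < 0 || it > .U16MAX || tt < 0 || tt > .U16MAX)
    return("thresholds must lie in [0, 65535]")
  if (it < tt)
    return("initialThreshold must be >= targetThreshold")
  if (object@numIterations < 1L)
    return("numIterations must be >= 1")
  if (object@numSegments < 1L)
    return("numSegments must be >= 1")
  if (object@numSegments > .U16MAX)
    return("numSegments must be <= 65535 (16-bit label capacity)")
  if (!(object@connectivity %in% c(6L, 18L, 26L)))
    return("connectivity must be 6, 18 or 26")
  TRUE
})

#' ThresholdSchedule: the descending per-iteration thresholds
#'
#' Iteration CI runs from 0 (the seed state) to NI; the threshold
#' applied at iteration CI is \code{IT - TS * CI} rounded to the nearest
#' grey value, with the final entry forced to TT exactly. TS, the
#' per-iteration step \code{(IT - TT) / NI}, is kept as a rational; the
#' integer step reported to the user is \code{floor(TS)}.
#'
#' @slot step numeric, the exact (possibly fractional) step TS.
#' @slot thresholds integer vector of length NI + 1, non-increasing,
#'   \code{thresholds[1] == IT} and \code{thresholds[NI + 1] == TT}.
#' @slot currentIteration integer index CI (0-based bookkeeping).
#'
#' @seealso [buildSchedule()], [thresholdStep()]
#' @exportClass ThresholdSchedule
setClass("ThresholdSchedule",
  representation(step = "numeric", thresholds = "integer",
                 currentIteration = "integer"),
  prototype(currentIteration = 0L))

setValidity("ThresholdSchedule", function(object) {
  th <- object@thresholds
  if (length(th) < 2L)
    return("thresholds must have length NI + 1 >= 2")
  if (any(diff(th) > 0L))
    return("thresholds must be non-increasing")
  if (object@currentIteration < 0L ||
      object@currentIteration > length(th) - 1L)
    return("currentIteration out of range")
  TRUE
})

#' SegmentationResult: the output of a boundary-preserving run
#'
#' @slot labels final [LabelVolume]; every seed voxel retains its seed
#'   label, segments are pairwise disjoint.
#' @slot seed the [Seed] the run grew from.
#' @slot params the [BountiParams] used.
#' @slot schedule the [ThresholdSchedule] used.
#' @slot snapshots named list of intermediate [LabelVolume]s keyed by
#'   iteration index (as character), if requested.
#' @slot segmentSizes integer vector of final per-label voxel counts.
#'
#' @seealso [bounti()]
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(labels = "LabelVolume", seed = "Seed",
                 params = "BountiParams", schedule = "ThresholdSchedule",
                 snapshots = "list", segmentSizes = "integer"),
  prototype(snapshots = list()))

#' PhantomSpec: recipe for a synthetic multi-body test volume
#'
#' Describes the intensity structure the segmentation algorithm assumes:
#' high-intensity spherical bodies (bone), joined by intermediate-intensity
#' cylindrical bridges (sutures), over a low-intensity background (soft
#' tissue / air), optionally degraded by Gaussian blur (sharpness) and
#' additive Gaussian noise (contrast resolution).
#'
#' @slot size integer (nz, ny, nx).
#' @slot bodies list of \code{list(centre = c(z, y, x), radius, intensity)}.
#' @slot bridges list of \code{list(a, b, thickness, intensity)} joining
#'   bodies by index; thickness is the full width of the cylindrical slab.
#' @slot backgroundIntensity numeric grey value.
#' @slot noiseSigma numeric, standard deviation of additive Gaussian
#'   noise in grey values (applied after blur).
#' @slot blurSigma numeric, Gaussian blur standard deviation in voxels.
#' @slot rngSeed integer seed making the render deterministic.
#'
#' @seealso [phantomSpec()], [makePhantom()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(size = "integer", bodies = "list", bridges = "list",
                 backgroundIntensity = "numeric", noiseSigma = "numeric",
                 blurSigma = "numeric", rngSeed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@size) != 3L || any(object@size < 1L))
    return("size must be three positive voxel counts")
  if (length(object@bodies) < 1L)
    return("at least one body is required")
  for (b in object@bodies) {
    if (any(b$centre - b$radius < 1) || any(b$centre + b$radius > object@size))
      return("bodies must fit inside the volume")
    if (b$intensity <= object@backgroundIntensity)
      return("core intensity must exceed background intensity")
  }
  for (br in object@bridges) {
    if (br$a < 1L || br$a > length(object@bodies) ||
        br$b < 1L || br$b > length(object@bodies) || br$a == br$b)
      return("bridge endpoints must index two distinct bodies")
    if (br$intensity <= object@backgroundIntensity)
      return("bridge intensity must exceed background intensity")
    ia <- object@bodies[[br$a]]$intensity; ib <- object@bodies[[br$b]]$intensity
    if (br$intensity >= min(ia, ib))
      return("bridge intensity must be below the core intensity of the bodies it joins")
  }
  TRUE
})

#' DiceReport: per-segment Dice scores against a reference labeling
#'
#' Segments are matched by maximal overlap (greedy, each reference
#' segment matched at most once); unmatched reference segments score 0
#' in \code{meanWithMissing} and are omitted from
#' \code{meanWithoutMissing}.
#'
#' @slot perSegment named numeric, Dice coefficient per reference label.
#' @slot matched named integer, result label matched to each reference
#'   label (NA where unmatched).
#' @slot meanWithMissing numeric, average including missing segments as 0.
#' @slot meanWithoutMissing numeric, average over matched segments only.
#'
#' @seealso [diceReport()], [diceCoefficient()]
#' @exportClass DiceReport
setClass("DiceReport",
  representation(perSegment = "numeric", matched = "integer",
                 meanWithMissing = "numeric", meanWithoutMissing = "numeric"))

setValidity("DiceReport", function(object) {
  p <- object@perSegment
  if (length(p) && (any(p < 0) || any(p > 1)))
    return("Dice coefficients must lie in [0, 1]")
  if (object@meanWithMissing > object@meanWithoutMissing + 1e-12)
    return("meanWithMissing cannot exceed meanWithoutMissing")
  TRUE
})

#' RunConfig: a fully-specified segmentation job
#'
#' Bundles the input/output paths and parameters consumed by the
#' command-layer functions ([cmdSegment()], [cmdSeedPreview()],
#' [cmdSweep()]) and the shell interface built on them.
#'
#' @slot input character path to the input TIFF stack.
#' @slot output character path for the label-stack output.
#' @slot params a [BountiParams].
#' @slot seedPath optional character path to a manual-seed label stack
#'   (length 0 when absent).
#' @slot seedMode \code{"preserve"} or \code{"largest"}.
#' @slot snapshots integer iterations at which to export snapshots.
#' @slot logLevel \code{"quiet"}, \code{"info"} or \code{"debug"}.
#'
#' @seealso [runConfig()]
#' @exportClass RunConfig
setClass("RunConfig",
  representation(input = "character", output = "character",
                 params = "BountiParams", seedPath = "character",
                 seedMode = "character", snapshots = "integer",
                 logLevel = "character"),
  prototype(seedPath = character(0), seedMode = "preserve",
            snapshots = integer(0), logLevel = "info"))

setValidity("RunConfig", function(object) {
  if (length(object@input) != 1L) return("input must be a single path")
  if (length(object@output) != 1L) return("output must be a single path")
  if (!(object@seedMode %in% c("preserve", "largest")))
    return("seedMode must be preserve or largest")
  if (!(object@logLevel %in% c("quiet", "info", "debug")))
    return("logLevel must be quiet, info or debug")
  TRUE
})
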