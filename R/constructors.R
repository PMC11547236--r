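#' Construct an IntensityVolume
#'
#' Wraps a 3D numeric/integer array of grey values (axis order z, y, x)
#' into an [IntensityVolume]. Non-integer storage is accepted when every
#' value is a whole number in \code{[0, 65535]}; use [convertToU16()]
#' for data that needs bit-depth conversion first.
#'
#' @param data 3D array of grey values.
#' @param spacing optional numeric(3), voxel edges (dz, dy, dx) in
#'   micrometres.
#' @return An [IntensityVolume].
#' @examples
#' v <- IntensityVolume(array(0L, c(4, 4, 4)))
#' dim(v)
#' @export
IntensityVolume <- function(data, spacing = NULL) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("data must be a 3D array (z, y, x)")
  if (!is.integer(data)) {
    if (anyNA(data) || any(data != round(data)))
      stop("grey values must be whole numbers; use convertToU16() for ",
           "floating-point or signed data")
    storage.mode(data) <- "integer"
  }
  new("IntensityVolume", data = data,
      spacing = if (is.null(spacing)) numeric(0) else as.numeric(spacing))
}

#' Construct a LabelVolume
#'
#' @param labels 3D array of non-negative integer segment labels
#'   (0 = background).
#' @return A [LabelVolume].
#' @examples
#' LabelVolume(array(0L, c(2, 2, 2)))
#' @export
LabelVolume <- function(labels) {
  if (is.null(dim(labels)) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array (z, y, x)")
  if (!is.integer(labels)) {
    if (anyNA(labels) || any(labels != round(labels)))
      stop("labels must be whole numbers")
    storage.mode(labels) <- "integer"
  }
  new("LabelVolume", labels = labels)
}

#' Construct the algorithm parameter set
#'
#' @param initialThreshold IT, the high grey value whose superlevel set
#'   yields disarticulated components (the seed).
#' @param targetThreshold TT, the low grey value with the desired bone
#'   definition; must not exceed \code{initialThreshold}.
#' @param numIterations NI, the number of threshold steps from IT down
#'   to TT.
#' @param numSegments NS, the number of largest seed components
#'   retained.
#' @param connectivity voxel neighbourhood: 6, 18 or 26 (default).
#' @param dilate expand each seed segment by one voxel before iterating
#'   (default \code{FALSE}).
#' @return A [BountiParams].
#' @examples
#' bountiParams(35000, 27000, 100, 28)
#' @export
bountiParams <- function(initialThreshold, targetThreshold, numIterations,
                         numSegments, connectivity = 26, dilate = FALSE) {
  new("BountiParams",
      initialThreshold = as.numeric(initialThreshold),
      targetThreshold = as.numeric(targetThreshold),
      numIterations = as.integer(numIterations),
      numSegments = as.integer(numSegments),
      connectivity = as.integer(connectivity),
      dilate = isTRUE(dilate))
}

#' Construct a phantom recipe
#'
#' Describes a synthetic volume with the structure the algorithm
#' assumes: bright spherical bodies joined by dimmer cylindrical
#' bridges over a dark background, degraded by blur then noise. The
#' defaults place grey values in the regime of a 16-bit infant-skull CT
#' (cores 40000, bridges 30000, background 5000), so that the canonical
#' parameters IT = 35000 / TT = 27000 separate the cores while keeping
#' the bridges above the target threshold.
#'
#' @param size integer(3) voxel grid (nz, ny, nx); default \code{c(48, 48, 48)}.
#' @param bodies list of \code{list(centre = c(z, y, x), radius,
#'   intensity)}; default two radius-6 bodies 20 voxels apart.
#' @param bridges list of \code{list(a, b, thickness, intensity)}
#'   joining bodies by index; thickness is the full cylinder width in
#'   voxels. Default one thickness-3 bridge at intensity 30000.
#' @param backgroundIntensity grey value of empty space (default 5000).
#' @param noiseSigma additive Gaussian noise SD in grey values, applied
#'   after blur (default 500, a mid-quality scan).
#' @param blurSigma Gaussian blur SD in voxels (default 0.5).
#' @param rngSeed integer RNG seed for the noise (default 1).
#' @return A [PhantomSpec].
#' @examples
#' spec <- phantomSpec(noiseSigma = 0, blurSigma = 0)
#' ph <- makePhantom(spec)
#' @export
phantomSpec <- function(size = c(48L, 48L, 48L),
                        bodies = list(
                          list(centre = c(24, 24, 14), radius = 6,
                               intensity = 40000),
                          list(centre = c(24, 24, 34), radius = 6,
                               intensity = 40000)),
                        bridges = list(
                          list(a = 1L, b = 2L, thickness = 3,
                               intensity = 30000)),
                        backgroundIntensity = 5000,
                        noiseSigma = 500, blurSigma = 0.5,
                        rngSeed = 1L) {
  new("PhantomSpec", size = as.integer(size), bodies = bodies,
      bridges = bridges,
      backgroundIntensity = as.numeric(backgroundIntensity),
      noiseSigma = as.numeric(noiseSigma),
      blurSigma = as.numeric(blurSigma), rngSeed = as.integer(rngSeed))
}

#' Construct a segmentation job configuration
#'
#' @param input path to the input grey-value TIFF stack.
#' @param output path for the output label TIFF stack.
#' @param params a [BountiParams].
#' @param seedPath optional path to a manual-seed label stack.
#' @param seedMode \code{"preserve"} (keep the manual label identities,
#'   even for touching segments) or \code{"largest"} (discard
#'   identities, relabel by connected components, keep the NS largest).
#' @param snapshots integer iterations at which intermediate labelings
#'   are exported.
#' @param logLevel \code{"quiet"}, \code{"info"} or \code{"debug"}.
#' @return A [RunConfig].
#' @export
runConfig <- function(input, output, params, seedPath = NULL,
                      seedMode = c("preserve", "largest"),
                      snapshots = NULL, logLevel = "info") {
  seedMode <- match.arg(seedMode)
  new("RunConfig", input = input, output = output, params = params,
      seedPath = if (is.null(seedPath)) character(0) else seedPath,
      seedMode = seedMode,
      snapshots = if (is.null(snapshots)) integer(0)
                  else as.integer(snapshots),
      logLevel = logLevel)
}
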