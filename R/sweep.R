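#' SweepSpec: a parameter-sensitivity sweep
#'
#' Describes one of the three sensitivity experiments: varying the
#' initial threshold (optionally holding the step size fixed by
#' adjusting the iteration count), varying the number of iterations,
#' or varying the volume size by downsampling.
#'
#' @slot mode \code{"initial_threshold"}, \code{"iterations"} or
#'   \code{"size"}.
#' @slot values sorted numeric values of the swept parameter
#'   (thresholds, iteration counts, or downsampling factors).
#' @slot keepStep optional fixed threshold step; only meaningful in
#'   initial-threshold mode, where NI is adjusted per value so the
#'   step stays constant and step size does not confound the
#'   comparison.
#'
#' @seealso [sweepSpec()], [runSweep()]
#' @exportClass SweepSpec
setClass("SweepSpec",
  representation(mode = "character", values = "numeric",
                 keepStep = "numeric"),
  prototype(keepStep = numeric(0)))

setValidity("SweepSpec", function(object) {
  if (!(object@mode %in% c("initial_threshold", "iterations", "size")))
    return("mode must be initial_threshold, iterations or size")
  if (length(object@values) == 0L)
    return("values must be non-empty")
  if (is.unsorted(object@values))
    return("values must be sorted")
  if (length(object@keepStep) && object@mode != "initial_threshold")
    return("keepStep is only valid in initial_threshold mode")
  TRUE
})

#' Construct a sweep specification
#'
#' @param mode \code{"initial_threshold"}, \code{"iterations"} or
#'   \code{"size"}.
#' @param values the swept values, sorted ascending.
#' @param keepStep optional fixed threshold step (initial-threshold
#'   mode only).
#' @return A [SweepSpec].
#' @examples
#' sweepSpec("initial_threshold", seq(30000, 40000, 1000), keepStep = 50)
#' @export
sweepSpec <- function(mode, values, keepStep = NULL) {
  new("SweepSpec", mode = mode, values = as.numeric(values),
      keepStep = if (is.null(keepStep)) numeric(0)
                 else as.numeric(keepStep))
}

#' Run a parameter-sensitivity sweep
#'
#' Reruns the segmentation across the swept values, holding every
#' other parameter at its value in \code{params}.
#' \itemize{
#'   \item \code{initial_threshold}: each value replaces IT; with
#'     \code{keepStep} s, the iteration count becomes
#'     \code{(IT - TT) / s} (exact division enforced) so the step size
#'     does not confound the comparison.
#'   \item \code{iterations}: each value replaces NI.
#'   \item \code{size}: the volume is downsampled by each factor; wall
#'     time is recorded in the summary for the user's information
#'     (hardware-dependent, reported, never asserted).
#' }
#'
#' @param volume an [IntensityVolume].
#' @param spec a [SweepSpec].
#' @param params baseline [BountiParams] for the unswept fields.
#' @return A list with \code{results} (one [SegmentationResult] per
#'   value, named) and \code{summary} (a data.frame with the full
#'   parameter provenance, per-run segment counts and voxel totals,
#'   and elapsed seconds).
#' @export
runSweep <- function(volume, spec, params) {
  stopifnot(is(volume, "IntensityVolume"), is(spec, "SweepSpec"),
            is(params, "BountiParams"))
  results <- list()
  rows <- list()
  for (v in spec@values) {
    p <- params
    vol <- volume
    factor <- NA_integer_
    if (spec@mode == "initial_threshold") {
      ni <- if (length(spec@keepStep))
        iterationsForStep(v, params@targetThreshold, spec@keepStep)
      else params@numIterations
      p <- bountiParams(v, params@targetThreshold, ni,
                        params@numSegments, params@connectivity,
                        params@dilate)
    } else if (spec@mode == "iterations") {
      p <- bountiParams(params@initialThreshold, params@targetThreshold,
                        v, params@numSegments, params@connectivity,
                        params@dilate)
    } else {
      factor <- as.integer(v)
      vol <- downsampleVolume(volume, factor)
    }
    elapsed <- system.time(res <- bounti(vol, p))[["elapsed"]]
    key <- as.character(v)
    results[[key]] <- res
    rows[[key]] <- data.frame(
      mode = spec@mode, value = v,
      initialThreshold = p@initialThreshold,
      targetThreshold = p@targetThreshold,
      numIterations = p@numIterations,
      numSegments = p@numSegments,
      connectivity = p@connectivity,
      dilate = p@dilate,
      downsampleFactor = factor,
      voxels = prod(dim(vol)),
      segmentsFound = nSegments(res),
      labeledVoxels = sum(segmentSizes(res)),
      elapsedSeconds = unname(elapsed))
  }
  list(results = results, summary = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
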