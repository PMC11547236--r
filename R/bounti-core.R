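#' Build the descending threshold schedule
#'
#' The per-iteration step is \code{TS = (IT - TT) / NI}; iteration CI
#' (counted from 0) is thresholded at \code{CIT = IT - TS * CI},
#' rounded half-up to the nearest grey value, with the final entry
#' forced to TT exactly so the run always ends at the target
#' threshold. The step shown to users ([thresholdStep()]) is
#' \code{floor(TS)}.
#'
#' @param params a [BountiParams].
#' @return A [ThresholdSchedule] of length \code{NI + 1}.
#' @examples
#' s <- buildSchedule(bountiParams(35000, 27000, 10, 28))
#' thresholds(s)     # 35000, 34200, ..., 27000
#' thresholdStep(s)  # 800
#' @export
buildSchedule <- function(params) {
  stopifnot(is(params, "BountiParams"))
  it <- params@initialThreshold
  tt <- params@targetThreshold
  ni <- params@numIterations
  ts <- (it - tt) / ni
  th <- floor(it - ts * (0:ni) + 0.5)
  th[ni + 1L] <- tt
  th <- cummin(th)  # guard against round-up ever breaking monotonicity
  new("ThresholdSchedule", step = ts, thresholds = as.integer(th),
      currentIteration = 0L)
}

#' Iterations needed for a fixed threshold step
#'
#' For parameter sweeps that vary the initial threshold while holding
#' the step size constant, the iteration count must be adjusted:
#' \code{NI = (IT - TT) / step}. The division must be exact; a
#' non-integral count is an error naming the offending threshold.
#'
#' @param initialThreshold IT (may be a vector).
#' @param targetThreshold TT.
#' @param step the fixed per-iteration step.
#' @return Integer iteration counts.
#' @examples
#' iterationsForStep(seq(30000, 40000, 1000), 27000, 50)  # 60 .. 260
#' @export
iterationsForStep <- function(initialThreshold, targetThreshold, step) {
  if (step <= 0) stop("step must be positive")
  ni <- (initialThreshold - targetThreshold) / step
  bad <- ni != round(ni) | ni < 1
  if (any(bad))
    stop("initial threshold ", initialThreshold[which(bad)[1L]],
         " does not give a whole number of iterations at step ", step)
  as.integer(round(ni))
}

#' One boundary-preserving growth pass
#'
#' Adds to the existing segments every voxel whose grey value is at or
#' above \code{cit} and which is connected, through such voxels, to a
#' segment. Growth is a single simultaneous multi-source breadth-first
#' expansion: all segments advance one voxel layer per wavefront step,
#' each voxel is claimed by the first wavefront to reach it, and
#' equidistant ties go to the smaller label. Existing labels are never
#' reassigned, so boundaries established earlier (at higher
#' thresholds) are preserved; mask components touching no segment stay
#' background.
#'
#' @param labels a [LabelVolume] of current segments.
#' @param volume the [IntensityVolume] being segmented.
#' @param cit the current iteration threshold (grey value).
#' @param connectivity 6, 18 or 26.
#' @return The grown [LabelVolume].
#' @export
growOnce <- function(labels, volume, cit, connectivity = 26) {
  stopifnot(is(labels, "LabelVolume"), is(volume, "IntensityVolume"))
  if (!identical(dim(labels@labels), dim(volume@data)))
    stop("labels and volume shapes differ")
  if (!(connectivity %in% c(6, 18, 26)))
    stop("connectivity must be 6, 18 or 26")
  out <- cpp_grow_once(labels@labels, volume@data, as.integer(cit),
                       dim(volume@data), as.integer(connectivity))
  LabelVolume(out)
}

#' Boundary-preserving threshold iteration
#'
#' Segments a grey-value volume into its anatomically separate
#' high-intensity parts. A seed of disarticulated components is taken
#' at the high initial threshold (the NS largest connected components
#' of its superlevel set), then grown through \code{NI} descending
#' thresholds down to the target threshold, adding surrounding
#' connected voxels to every segment at each step. The result keeps
#' the separation achievable at the high threshold together with the
#' tissue definition of the low threshold: the union of the final
#' segments is exactly the union of those target-threshold components
#' that contain at least one seed voxel, so the output can never
#' select anything a direct target-threshold segmentation would not.
#'
#' @param volume an [IntensityVolume].
#' @param params a [BountiParams].
#' @param seed optional manual [Seed] (see [manualSeed()]); when
#'   absent the seed is built from the initial threshold. When
#'   \code{params@dilate} is set, a freshly built automatic seed is
#'   dilated; a supplied seed is used as given.
#' @param snapshotAt optional integer iterations (0 = the seed state)
#'   at which the intermediate labeling is recorded.
#' @return A [SegmentationResult].
#' @examples
#' ph <- makePhantom(phantomSpec(noiseSigma = 0, blurSigma = 0))
#' res <- bounti(ph$volume, bountiParams(35000, 27000, 10, 2))
#' segmentSizes(res)
#' @export
bounti <- function(volume, params, seed = NULL, snapshotAt = NULL) {
  stopifnot(is(volume, "IntensityVolume"), is(params, "BountiParams"))
  if (is.null(seed)) {
    seed <- .autoSeed(volume, params)
  } else {
    stopifnot(is(seed, "Seed"))
    if (!identical(dim(seed@labels@labels), dim(volume@data)))
      stop("manual seed shape must match the volume")
  }
  sched <- buildSchedule(params)
  snapshotAt <- as.integer(snapshotAt)
  snaps <- list()
  lab <- seed@labels
  if (0L %in% snapshotAt) snaps[["0"]] <- lab
  ni <- params@numIterations
  for (ci in seq_len(ni)) {
    lab <- growOnce(lab, volume, sched@thresholds[ci + 1L],
                    connectivity = params@connectivity)
    if (ci %in% snapshotAt) snaps[[as.character(ci)]] <- lab
  }
  sizes <- tabulate(lab@labels, nbins = length(seed@segmentSizes))
  new("SegmentationResult", labels = lab, seed = seed, params = params,
      schedule = sched, snapshots = snaps,
      segmentSizes = as.integer(sizes))
}

#' Extract the seed a run would grow from, without iterating
#'
#' Useful for choosing the initial threshold: the seed (optionally
#' dilated, per \code{params@dilate}) can be inspected directly. If
#' segments that should be separate are connected here, raise the
#' initial threshold; if expected segments are missing, lower it.
#'
#' @inheritParams bounti
#' @return A [Seed], identical to the one [bounti()] would construct.
#' @export
seedPreview <- function(volume, params) {
  stopifnot(is(volume, "IntensityVolume"), is(params, "BountiParams"))
  .autoSeed(volume, params)
}
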