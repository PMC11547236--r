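#' Threshold a volume (superlevel set)
#'
#' Returns the mask of voxels whose grey value is at or above \code{t}.
#' The comparison is inclusive (\code{>= t}) so that a schedule with
#' equal initial and target thresholds degenerates cleanly to a plain
#' threshold segmentation.
#'
#' @param volume an [IntensityVolume].
#' @param t grey value in \code{[0, 65535]}.
#' @return A [BinaryMask].
#' @export
thresholdMask <- function(volume, t) {
  stopifnot(is(volume, "IntensityVolume"))
  if (length(t) != 1L || is.na(t) || t < 0 || t > 65535)
    stop("threshold must be a grey value in [0, 65535]")
  m <- volume@data >= t
  new("BinaryMask", mask = m, thresholdUsed = as.numeric(t))
}

#' Label the connected components of a mask
#'
#' Each maximal connected true-region receives a distinct label.
#' Labels are assigned in decreasing component-size order (label 1 is
#' the largest); equal sizes break by the scan order (z, then y, then
#' x) of each component's first voxel, making the labeling
#' deterministic.
#'
#' @param mask a [BinaryMask] or logical 3D array.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (default,
#'   faces+edges+corners).
#' @return A list with \code{labels} (a [LabelVolume]) and \code{sizes}
#'   (integer voxel counts, \code{sizes[i]} for label \code{i}).
#' @export
labelComponents <- function(mask, connectivity = 26) {
  m <- if (is(mask, "BinaryMask")) mask@mask else mask
  if (is.null(dim(m)) || length(dim(m)) != 3L || !is.logical(m))
    stop("mask must be a logical 3D array")
  if (!(connectivity %in% c(6, 18, 26)))
    stop("connectivity must be 6, 18 or 26")
  res <- cpp_label_components(m, dim(m), as.integer(connectivity))
  list(labels = LabelVolume(res$labels), sizes = res$sizes)
}

#' Retain the largest components as the seed
#'
#' Keeps the \code{ns} largest components of a size-ordered labeling,
#' relabeled 1..ns by descending size; all other components become
#' background. If fewer than \code{ns} components exist, all are kept
#' and a warning is raised (anatomy expected by the operator may be
#' missing from the seed).
#'
#' @param labeled a [LabelVolume] from [labelComponents()] (labels in
#'   decreasing size order).
#' @param sizes integer voxel counts per label.
#' @param ns number of segments to retain (NS), \code{>= 1}.
#' @param provenance provenance tag recorded on the seed.
#' @return A [Seed].
#' @export
selectLargest <- function(labeled, sizes, ns, provenance = "auto") {
  stopifnot(is(labeled, "LabelVolume"))
  if (length(ns) != 1L || is.na(ns) || ns < 1)
    stop("ns must be >= 1")
  ns <- as.integer(ns)
  k <- length(sizes)
  if (k < ns)
    warning("only ", k, " component(s) exist but ", ns,
            " segment(s) were requested; keeping all ", k)
  keep <- min(k, ns)
  lab <- labeled@labels
  lab[lab > keep] <- 0L
  new("Seed", labels = LabelVolume(lab),
      segmentSizes = as.integer(sizes[seq_len(keep)]),
      provenance = provenance, dilated = FALSE)
}

#' Dilate every seed segment by one voxel
#'
#' Each segment gains its one-voxel 26-neighbourhood shell. A voxel
#' claimed by the shells of two or more segments is contested and stays
#' background, so dilation never connects segments; original labels are
#' never overwritten. Optionally the dilation is restricted to the true
#' voxels of a limit mask.
#'
#' @param seed a [Seed].
#' @param maskLimit optional [BinaryMask] (or logical array) aligned
#'   with the seed; only its true voxels may be claimed.
#' @return The dilated [Seed] (\code{dilated = TRUE}); per-segment
#'   sizes are recomputed.
#' @export
dilateSeed <- function(seed, maskLimit = NULL) {
  stopifnot(is(seed, "Seed"))
  lab <- seed@labels@labels
  lim <- if (is.null(maskLimit)) logical(0)
         else if (is(maskLimit, "BinaryMask")) maskLimit@mask
         else maskLimit
  if (length(lim) && !identical(dim(lim), dim(lab)))
    stop("maskLimit shape must match the seed")
  out <- cpp_dilate_labels(lab, dim(lab), as.vector(lim))
  k <- length(seed@segmentSizes)
  sizes <- tabulate(out, nbins = k)
  new("Seed", labels = LabelVolume(out), segmentSizes = as.integer(sizes),
      provenance = seed@provenance, dilated = TRUE)
}

#' Build a seed from a manual label volume
#'
#' For scans whose quality does not yield a usable automatic seed, a
#' manually prepared label volume can replace it. In \code{"preserve"}
#' mode the segment assignments are retained exactly as given, so
#' touching segments keep their distinct identities. In
#' \code{"largest"} mode the identities are discarded: the non-zero
#' support is relabeled by connected components and the \code{ns}
#' largest are retained (touching manual segments merge).
#'
#' @param labels a [LabelVolume] (or integer 3D array) aligned with the
#'   working volume.
#' @param mode \code{"preserve"} or \code{"largest"}.
#' @param ns number of segments retained in \code{"largest"} mode.
#' @param connectivity neighbourhood used in \code{"largest"} mode.
#' @return A [Seed] with provenance \code{"manual_preserve"} or
#'   \code{"manual_largest"}.
#' @export
manualSeed <- function(labels, mode = c("preserve", "largest"), ns = NULL,
                       connectivity = 26) {
  mode <- match.arg(mode)
  lab <- if (is(labels, "LabelVolume")) labels else LabelVolume(labels)
  if (all(lab@labels == 0L))
    stop("manual seed is empty (all background)")
  if (mode == "preserve") {
    k <- max(lab@labels)
    present <- sort(unique(as.vector(lab@labels)))
    present <- present[present > 0L]
    if (!identical(present, seq_len(k)))
      stop("manual seed labels must be contiguous 1..K in preserve mode")
    sizes <- tabulate(lab@labels, nbins = k)
    return(new("Seed", labels = lab, segmentSizes = as.integer(sizes),
               provenance = "manual_preserve", dilated = FALSE))
  }
  if (is.null(ns) || length(ns) != 1L || ns < 1)
    stop("ns >= 1 is required in largest mode")
  comp <- labelComponents(lab@labels > 0L, connectivity = connectivity)
  seed <- selectLargest(comp$labels, comp$sizes, ns,
                        provenance = "manual_largest")
  seed
}

# internal: auto seed from the initial threshold, as used by bounti()
.autoSeed <- function(volume, params) {
  m <- thresholdMask(volume, params@initialThreshold)
  comp <- labelComponents(m, connectivity = params@connectivity)
  if (length(comp$sizes) == 0L)
    stop("the seed is empty: no voxel reaches the initial threshold ",
         params@initialThreshold,
         "; lower the initial threshold so that the structures of ",
         "interest appear in the seed")
  seed <- selectLargest(comp$labels, comp$sizes, params@numSegments)
  if (params@dilate) seed <- dilateSeed(seed) else seed
}
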