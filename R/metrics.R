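#' Dice similarity coefficient of two voxel sets
#'
#' \code{2 |A intersect B| / (|A| + |B|)}: 1 for identical non-empty
#' sets, 0 for disjoint ones. Two empty sets have no defined
#' similarity and raise an error rather than silently scoring 0.
#'
#' @param a,b logical arrays (aligned) or integer voxel-index vectors.
#' @return Numeric in \code{[0, 1]}.
#' @examples
#' diceCoefficient(c(1L, 2L), c(2L, 3L))  # 0.5
#' @export
diceCoefficient <- function(a, b) {
  if (is.logical(a) && is.logical(b)) {
    if (!identical(dim(a), dim(b)))
      stop("masks must be aligned (same shape)")
    na <- sum(a); nb <- sum(b)
    if (na + nb == 0L)
      stop("Dice is undefined for two empty sets")
    return(2 * sum(a & b) / (na + nb))
  }
  na <- length(a); nb <- length(b)
  if (na + nb == 0L)
    stop("Dice is undefined for two empty sets")
  2 * length(intersect(a, b)) / (na + nb)
}

#' Per-segment Dice report against a reference segmentation
#'
#' Segments are matched by maximal voxel overlap: all
#' (reference, result) overlap pairs are ranked by decreasing overlap
#' (ties by reference then result label) and assigned greedily, each
#' reference and each result segment matched at most once. Matched
#' pairs are scored by [diceCoefficient()]; reference segments with no
#' match (missing from the result) score 0 in the
#' missing-counted mean and are omitted from the matched-only mean.
#' Matching is by overlap, not by label value, so a label permutation
#' of a perfect segmentation still scores 1.
#'
#' @param result a [LabelVolume] or [SegmentationResult].
#' @param reference a [LabelVolume] with at least one segment.
#' @return A [DiceReport].
#' @export
diceReport <- function(result, reference) {
  res <- if (is(result, "SegmentationResult")) result@labels@labels
         else if (is(result, "LabelVolume")) result@labels
         else result
  ref <- if (is(reference, "LabelVolume")) reference@labels else reference
  if (!identical(dim(res), dim(ref)))
    stop("result and reference must be aligned (same shape)")
  kref <- max(ref)
  if (kref < 1L)
    stop("reference has no segments")
  kres <- max(res)
  refSizes <- tabulate(ref, nbins = kref)
  resSizes <- tabulate(res, nbins = max(kres, 1L))

  both <- ref > 0L & res > 0L
  matched <- rep(NA_integer_, kref)
  per <- numeric(kref)
  names(per) <- as.character(seq_len(kref))
  names(matched) <- names(per)
  if (any(both)) {
    ov <- table(ref[both], res[both])
    pairs <- as.data.frame(ov, stringsAsFactors = FALSE)
    names(pairs) <- c("ref", "res", "overlap")
    pairs$ref <- as.integer(pairs$ref)
    pairs$res <- as.integer(pairs$res)
    pairs <- pairs[pairs$overlap > 0L, , drop = FALSE]
    pairs <- pairs[order(-pairs$overlap, pairs$ref, pairs$res), ,
                   drop = FALSE]
    usedRes <- logical(max(kres, 1L))
    for (i in seq_len(nrow(pairs))) {
      rf <- pairs$ref[i]; rs <- pairs$res[i]
      if (!is.na(matched[rf]) || usedRes[rs]) next
      matched[rf] <- rs
      usedRes[rs] <- TRUE
      per[rf] <- 2 * pairs$overlap[i] / (refSizes[rf] + resSizes[rs])
    }
  }
  got <- !is.na(matched)
  new("DiceReport", perSegment = per, matched = matched,
      meanWithMissing = mean(per),
      meanWithoutMissing = if (any(got)) mean(per[got]) else 0)
}
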