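#' Read a 3D TIFF stack as an intensity volume
#'
#' Reads a multi-page grayscale TIFF into an [IntensityVolume], one
#' z-slice per page, in page order. Unsigned 16-bit data is taken
#' verbatim. 8-bit data is widened without rescaling, so the output
#' occupies 0--255 of the 16-bit range. Signed 16-bit and 32-bit float
#' data are clipped to \code{inputRange} and affinely mapped onto
#' \code{[0, 65535]} (see [convertToU16()]); an \code{inputRange} is
#' required for these formats because no automatic rule recovers the
#' grey values of interest.
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param inputRange numeric(2) \code{(low, high)}; required for signed
#'   16-bit and float input, ignored otherwise.
#' @param spacing optional voxel spacing (dz, dy, dx) in micrometres,
#'   attached as metadata.
#' @return An [IntensityVolume] of shape (pages, height, width).
#' @seealso [writeTiffStack()], [convertToU16()]
#' @export
readTiffStack <- function(path, inputRange = NULL, spacing = NULL) {
  if (!file.exists(path))
    stop("cannot read TIFF stack: no such file: ", path)
  meta <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
  if (is.null(dim(meta))) meta <- as.data.frame(as.list(meta))
  if (any(meta$samples.per.pixel != 1L))
    stop("unsupported TIFF sample type: ", max(meta$samples.per.pixel),
         " samples per pixel (RGB/multi-channel); grayscale required")
  if (length(unique(meta$width)) != 1L ||
      length(unique(meta$length)) != 1L)
    stop("inconsistent page shapes across the TIFF stack")
  if (length(unique(meta$bits.per.sample)) != 1L)
    stop("inconsistent bit depths across the TIFF stack")
  fmt <- if ("sample.format" %in% names(meta)) meta$sample.format[1L]
         else "uint"
  if (is.na(fmt)) fmt <- "uint"
  bits <- meta$bits.per.sample[1L]

  source_format <-
    if (fmt == "float" && bits == 32L) "f32"
    else if (fmt == "int" && bits == 16L) "i16"
    else if (fmt == "uint" && bits == 16L) "u16"
    else if (fmt == "uint" && bits == 8L) "u8"
    else stop("unsupported TIFF sample type: ", bits, "-bit ", fmt)

  as_is <- source_format != "f32"
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop("inconsistent page shapes across the TIFF stack")

  nz <- length(pages); ny <- dims[[1L]][1L]; nx <- dims[[1L]][2L]
  arr <- array(if (as_is) 0L else 0, c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]

  if (source_format == "i16") {
    # libtiff hands signed 16-bit back wrapped to unsigned; un-wrap
    arr <- ifelse(arr > 32767L, arr - 65536L, arr)
  }
  convertToU16(arr, source_format, inputRange = inputRange,
               spacing = spacing)
}

#' Write a volume or label map as a 16-bit 3D TIFF stack
#'
#' Writes one page per z-slice, unsigned 16-bit samples.
#' \code{readTiffStack(writeTiffStack(v, path))} reproduces \code{v}
#' voxel for voxel.
#'
#' @param x an [IntensityVolume], [LabelVolume], [Seed],
#'   [SegmentationResult], or a 3D integer array in \code{[0, 65535]}.
#' @param path output file path.
#' @return The path, invisibly.
#' @seealso [readTiffStack()]
#' @export
writeTiffStack <- function(x, path) {
  arr <- if (is(x, "IntensityVolume")) x@data
         else if (is(x, "LabelVolume")) x@labels
         else if (is(x, "Seed")) x@labels@labels
         else if (is(x, "SegmentationResult")) x@labels@labels
         else x
  if (is.null(dim(arr)) || length(dim(arr)) != 3L)
    stop("input must be a 3D volume or label map")
  if (max(arr) > 65535L)
    stop("label/grey values exceed 65535 and cannot be stored in a ",
         "16-bit stack")
  if (min(arr) < 0L)
    stop("negative values cannot be stored in an unsigned 16-bit stack")
  d <- dim(arr)
  slices <- lapply(seq_len(d[1L]),
                   function(z) matrix(arr[z, , ] / 65535, d[2L], d[3L]))
  ok <- tryCatch(tiff::writeTIFF(slices, path, bits.per.sample = 16L),
                 error = function(e)
                   stop("cannot write TIFF stack to ", path, ": ",
                        conditionMessage(e)))
  invisible(path)
}

#' Convert grey-value data to unsigned 16-bit
#'
#' Applies the bit-depth rules the segmentation engine requires:
#' \itemize{
#'   \item \code{u16}: identity.
#'   \item \code{u8}: values copied unchanged into 16-bit storage, so
#'     the output occupies 0--255 (8-bit data is widened, not
#'     stretched).
#'   \item \code{i16}, \code{f32}: values clipped to \code{inputRange}
#'     and affinely mapped so that \code{low -> 0} and
#'     \code{high -> 65535}, rounded half-up to the nearest integer.
#'     The range must be supplied by the user: it controls how much of
#'     the 16-bit scale the grey values of interest (bone) occupy, and
#'     often needs adjustment to minimise information loss.
#' }
#'
#' @param data 3D numeric array.
#' @param sourceFormat one of \code{"u8"}, \code{"u16"}, \code{"i16"},
#'   \code{"f32"}.
#' @param inputRange numeric(2) \code{(low, high)}, \code{low < high};
#'   required for \code{"i16"} and \code{"f32"}.
#' @param spacing optional voxel spacing metadata.
#' @return An [IntensityVolume].
#' @examples
#' a <- array(c(-1, 0, 1, 3), c(1, 2, 2))
#' v <- convertToU16(a, "f32", inputRange = c(0, 2))
#' volData(v)  # clipped to [0,2], mapped 0 -> 0, 2 -> 65535
#' @export
convertToU16 <- function(data, sourceFormat = c("u16", "u8", "i16", "f32"),
                         inputRange = NULL, spacing = NULL) {
  sourceFormat <- match.arg(sourceFormat)
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("data must be a 3D array (z, y, x)")
  if (sourceFormat %in% c("u8", "u16")) {
    top <- if (sourceFormat == "u8") 255L else 65535L
    if (min(data) < 0L || max(data) > top)
      stop("values outside [0, ", top, "] are not valid ", sourceFormat,
           " data")
    return(IntensityVolume(data, spacing = spacing))
  }
  if (is.null(inputRange))
    stop("inputRange (low, high) is required when converting ",
         sourceFormat, " data")
  if (length(inputRange) != 2L || inputRange[1L] >= inputRange[2L])
    stop("inputRange must be (low, high) with low < high")
  low <- inputRange[1L]; high <- inputRange[2L]
  x <- pmin(pmax(data, low), high)
  mapped <- floor((x - low) / (high - low) * 65535 + 0.5)
  dim(mapped) <- dim(data)
  IntensityVolume(mapped, spacing = spacing)
}

#' Downsample a volume by integer factors (block mean)
#'
#' Reduces each axis by an integer factor; every output voxel is the
#' rounded (half-up) mean of its source block. Blocks at the far edges
#' may be partial, so the output shape is \code{ceiling(dim / factor)}.
#' This is a plain block-mean reduction intended for cutting run time
#' on large scans, not an interpolating resampler.
#'
#' @param volume an [IntensityVolume].
#' @param factor integer \code{>= 1}, scalar or per-axis (z, y, x).
#' @return A downsampled [IntensityVolume]; voxel spacing, if present,
#'   is multiplied by the factor.
#' @export
downsampleVolume <- function(volume, factor) {
  stopifnot(is(volume, "IntensityVolume"))
  if (length(factor) == 1L) factor <- rep(factor, 3L)
  if (length(factor) != 3L || any(is.na(factor)) ||
      any(factor != round(factor)) || any(factor < 1))
    stop("factor must be one or three integers >= 1")
  factor <- as.integer(factor)
  d <- dim(volume@data)
  if (all(factor == 1L)) return(volume)
  od <- as.integer(ceiling(d / factor))
  gz <- (seq_len(d[1L]) - 1L) %/% factor[1L] + 1L
  gy <- (seq_len(d[2L]) - 1L) %/% factor[2L] + 1L
  gx <- (seq_len(d[3L]) - 1L) %/% factor[3L] + 1L
  gid <- array(gz, d) +
    od[1L] * (array(rep(gy, each = d[1L]), d) - 1L) +
    od[1L] * od[2L] * (array(rep(gx, each = d[1L] * d[2L]), d) - 1L)
  v <- as.vector(gid)
  sums <- rowsum(as.numeric(volume@data), v)
  counts <- rowsum(rep(1, length(v)), v)
  out <- as.integer(floor(sums / counts + 0.5))
  dim(out) <- od
  sp <- if (length(volume@spacing) == 3L) volume@spacing * factor else NULL
  IntensityVolume(out, spacing = sp)
}
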