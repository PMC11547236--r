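# Minimal raw TIFF writer for fixtures the `tiff` package cannot
# produce (genuine float32 / signed int16 sample formats). Classic
# little-endian TIFF, one uncompressed strip per page; independent of
# the package's read path.
write_raw_tiff <- function(path, pages, bits,
                           format = c("uint", "int", "float")) {
  format <- match.arg(format)
  fmtcode <- c(uint = 1L, int = 2L, float = 3L)[[format]]
  bytes_pp <- bits %/% 8L
  sizes <- vapply(pages, function(m) length(m) * bytes_pp, 0L)
  data_off <- 8L + c(0L, cumsum(sizes))[seq_along(pages)]
  ifd_bytes <- 2L + 12L * 10L + 4L
  ifd_off <- 8L + sum(sizes) + (seq_along(pages) - 1L) * ifd_bytes

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off[1L], con, size = 4, endian = "little")
  for (m in pages) {
    v <- as.vector(t(m))  # TIFF stores rows sequentially
    if (format == "float")
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    else
      writeBin(as.integer(v), con, size = bytes_pp, endian = "little")
  }
  entry <- function(tag, type, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT + pad
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    writeBin(10L, con, size = 2, endian = "little")
    entry(256L, 4L, ncol(m))            # width
    entry(257L, 4L, nrow(m))            # length
    entry(258L, 3L, bits)               # bits per sample
    entry(259L, 3L, 1L)                 # no compression
    entry(262L, 3L, 1L)                 # black is zero
    entry(273L, 4L, data_off[i])        # strip offset
    entry(277L, 3L, 1L)                 # samples per pixel
    entry(278L, 4L, nrow(m))            # rows per strip
    entry(279L, 4L, sizes[i])           # strip byte count
    entry(339L, 3L, fmtcode)            # sample format
    nxt <- if (i < length(pages)) ifd_off[i + 1L] else 0L
    writeBin(nxt, con, size = 4, endian = "little")
  }
  invisible(path)
}
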