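# Minimal multi-page 32-bit-float grayscale TIFF writer.
#
# CRAN `tiff` reads IEEE-float sample-format TIFFs exactly but can only WRITE
# integer sample formats (doubles are quantized into [0,1] scaled uint), which
# breaks the bit-exact round-trip contract for intensity volumes. Pipeline
# files are therefore written here: classic little-endian TIFF, one
# uncompressed strip per page, SampleFormat = IEEE float, 32 bits/sample.
# Values are stored at float32 precision (the package's canonical intensity
# precision); reading back goes through tiff::readTIFF.

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# One 12-byte IFD entry. type 3 = SHORT, 4 = LONG. Values fit in 4 bytes here.
ifd_entry <- function(tag, type, count, value) {
  val <- if (type == 3L) c(u16(value), u16(0L)) else u32(value)
  c(u16(tag), u16(type), u32(count), val)
}

# pages: list of numeric matrices (rows x cols), written in list order.
write_float_tiff <- function(pages, path) {
  stopifnot(is.list(pages), length(pages) >= 1)
  con <- file(path, "wb")
  on.exit(close(con))
  pg1 <- pages[[1]]
  first_ifd <- 8 + nrow(pg1) * ncol(pg1) * 4
  writeBin(c(charToRaw("II"), u16(42L), u32(first_ifd)), con)
  offset <- 8
  n <- length(pages)
  for (i in seq_len(n)) {
    pg <- pages[[i]]
    stopifnot(is.matrix(pg))
    h <- nrow(pg); w <- ncol(pg)
    nbytes <- w * h * 4
    data_off <- offset
    ifd_off <- data_off + nbytes
    ifd_len <- 2 + 10 * 12 + 4
    # the next IFD sits after the next page's pixel data
    next_off <- if (i < n) {
      ifd_off + ifd_len + nrow(pages[[i + 1]]) * ncol(pages[[i + 1]]) * 4
    } else 0
    # row-major pixel stream at float32
    writeBin(as.numeric(t(pg)), con, size = 4, endian = "little")
    entries <- c(
      ifd_entry(256L, 4L, 1L, w),        # ImageWidth
      ifd_entry(257L, 4L, 1L, h),        # ImageLength
      ifd_entry(258L, 3L, 1L, 32L),      # BitsPerSample
      ifd_entry(259L, 3L, 1L, 1L),       # Compression: none
      ifd_entry(262L, 3L, 1L, 1L),       # Photometric: min-is-black
      ifd_entry(273L, 4L, 1L, data_off), # StripOffsets
      ifd_entry(277L, 3L, 1L, 1L),       # SamplesPerPixel
      ifd_entry(278L, 4L, 1L, h),        # RowsPerStrip
      ifd_entry(279L, 4L, 1L, nbytes),   # StripByteCounts
      ifd_entry(339L, 3L, 1L, 3L)        # SampleFormat: IEEE float
    )
    writeBin(c(u16(10L), entries, u32(next_off)), con)
    offset <- ifd_off + 2 + 10 * 12 + 4
  }
  invisible(path)
}

# Coerce a numeric vector/array to the float32 grid (round-trip through
# 4-byte IEEE storage). Used so in-memory values equal their on-disk form.
as_float32 <- function(x) {
  v <- readBin(writeBin(as.numeric(x), raw(), size = 4), "numeric",
               n = length(x), size = 4)
  if (!is.null(dim(x))) dim(v) <- dim(x)
  v
}
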