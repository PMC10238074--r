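#' File formats
#'
#' Volumes and frame stacks are multi-page 32-bit-float grayscale TIFFs with a
#' JSON sidecar `<name>.meta.json` describing pitches, shape, axis order and
#' (for stacks) timestamps. Pages of a volume are one B-scan each, rows = depth
#' z, columns = fast axis x, ordered repeat-major (all B-scans of repeat 1,
#' then repeat 2, ...). Pages of an SLO stack are ordered frame-major, red
#' channel then green channel within each frame. Masks are PNG or single-page
#' TIFF; tables are headered CSV; models, transforms and plans are JSON.
#'
#' @name retlesion-io
NULL

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".meta.json")

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop(sprintf("missing JSON sidecar: expected '%s' next to '%s'", sc, path))
  }
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Write / read an OCT volume as multi-page float TIFF + JSON sidecar
#'
#' Intensities are stored at 32-bit float precision; a volume whose voxels are
#' already on the float32 grid round-trips bit-exactly.
#'
#' @param volume An [oct_volume()].
#' @param path Output `.tif` path; the sidecar is written next to it.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns an
#'   [oct_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  v <- volume$voxels
  if (!has_repeats(volume)) dim(v) <- c(1L, dim(v))
  d <- dim(v)  # (r, y, x, z)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (r in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      pages[[k]] <- t(matrix(v[r, y, , ], d[3], d[4]))  # (z, x)
      k <- k + 1L
    }
  }
  write_float_tiff(pages, path)
  meta <- list(
    kind = "oct_volume",
    axis_order = if (has_repeats(volume)) "r,y,x,z" else "y,x,z",
    repeats = if (has_repeats(volume)) d[1] else 1L,
    shape_yxz = d[2:4],
    page_order = "repeat-major, page = B-scan (rows z, cols x)",
    pitch_um = list(x = volume$pitch_x, y = volume$pitch_y, z = volume$pitch_z),
    meta = volume$meta
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- read_sidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  r <- as.integer(meta$repeats)
  shp <- as.integer(meta$shape_yxz)
  if (length(pages) != r * shp[1]) {
    stop(sprintf("sidecar/file mismatch: sidecar implies %d pages (repeats %d x %d B-scans) but file has %d",
                 r * shp[1], r, shp[1], length(pages)))
  }
  if (!all(dim(pages[[1]]) == c(shp[3], shp[2]))) {
    stop("sidecar/file mismatch: page shape does not match sidecar shape_yxz")
  }
  v <- array(NA_real_, c(r, shp[1], shp[2], shp[3]))
  k <- 1L
  for (ri in seq_len(r)) {
    for (y in seq_len(shp[1])) {
      v[ri, y, , ] <- t(pages[[k]])
      k <- k + 1L
    }
  }
  if (r == 1L && identical(meta$axis_order, "y,x,z")) dim(v) <- shp
  oct_volume(v, meta$pitch_um$x, meta$pitch_um$y, meta$pitch_um$z,
             meta = as.list(meta$meta))
}

#' Write / read a two-channel SLO frame stack
#'
#' @param seq An [slo_sequence()].
#' @param path Output `.tif` path.
#' @return `write_sequence` returns `path` invisibly; `read_sequence` an
#'   [slo_sequence()].
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "slo_sequence"))
  d <- dim(seq$frames)  # (t, 2, row, col)
  pages <- vector("list", d[1] * 2L)
  k <- 1L
  for (t in seq_len(d[1])) {
    for (c in 1:2) {
      pages[[k]] <- matrix(seq$frames[t, c, , ], d[3], d[4])
      k <- k + 1L
    }
  }
  write_float_tiff(pages, path)
  meta <- list(
    kind = "slo_sequence",
    channels = c("red", "green"),
    n_frames = d[1], shape_rc = d[3:4],
    page_order = "frame-major, red then green",
    pitch_um = seq$pitch, frame_rate_hz = seq$frame_rate,
    timestamps_s = seq$timestamps
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  meta <- read_sidecar(path)
  if (length(meta$channels) != 2L) {
    stop("sidecar must declare exactly two channels (red, green)")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  nt <- as.integer(meta$n_frames)
  if (length(pages) != 2L * nt) {
    stop(sprintf("sidecar/file mismatch: expected %d pages (2 channels x %d frames), found %d",
                 2L * nt, nt, length(pages)))
  }
  rc <- as.integer(meta$shape_rc)
  fr <- array(NA_real_, c(nt, 2L, rc[1], rc[2]))
  k <- 1L
  for (t in seq_len(nt)) {
    for (c in 1:2) {
      fr[t, c, , ] <- pages[[k]]
      k <- k + 1L
    }
  }
  slo_sequence(fr, pitch = meta$pitch_um, timestamps = meta$timestamps_s,
               frame_rate = meta$frame_rate_hz)
}

#' Write / read a binary mask image
#'
#' Masks are logical matrices `(y, x)`; on disk they are 8-bit PNG (or
#' single-page TIFF) with foreground = 1.
#'
#' @param mask Logical matrix.
#' @param path `.png` or `.tif` path.
#' @return `read_mask` returns a logical matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, path)
  } else {
    write_float_tiff(list(img), path)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' Write an en face image (single-page float TIFF or 8-bit PNG)
#'
#' PNG output is min-max scaled to display range; TIFF keeps raw values.
#' @param image Numeric matrix; `NA` allowed (written as 0 in PNG).
#' @param path Output path.
#' @export
write_enface <- function(image, path) {
  stopifnot(is.matrix(image))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    rng <- range(image, na.rm = TRUE)
    sc <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
    sc[is.na(sc)] <- 0
    png::writePNG(sc, path)
  } else {
    img <- image
    img[is.na(img)] <- 0
    write_float_tiff(list(img), path)
  }
  invisible(path)
}
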