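#' Construct an OCT intensity volume
#'
#' An `oct_volume` holds a reconstructed (linear-intensity) OCT volume with
#' axes ordered `(y slow, x fast, z depth)` or, when repeated B-scans are
#' retained, `(repeat, y, x, z)`. Depth `z` increases away from the vitreous:
#' the inner retina sits at low `z` and the RPE at high `z`. All indices are
#' 1-based; physical en face coordinates are pixel-centred,
#' `x_um = (ix - 0.5) * pitch_x`.
#'
#' @param voxels Numeric array, 3D `(y, x, z)` or 4D `(r, y, x, z)`, all
#'   intensities >= 0.
#' @param pitch_x,pitch_y,pitch_z Voxel pitch in micrometres (> 0).
#' @param meta Optional named list of acquisition metadata (line rate,
#'   as-acquired dimensions, ...).
#' @return An object of class `oct_volume`.
#' @examples
#' v <- oct_volume(array(1, c(4, 8, 16)), 3, 3, 2)
#' dim(v$voxels)
#' @export
oct_volume <- function(voxels, pitch_x, pitch_y, pitch_z, meta = list()) {
  if (!is.array(voxels) || !(length(dim(voxels)) %in% c(3L, 4L))) {
    stop("`voxels` must be a 3D (y,x,z) or 4D (r,y,x,z) array")
  }
  if (anyNA(voxels) || min(voxels) < 0) {
    stop("OCT intensities must be non-negative and non-missing")
  }
  for (p in c(pitch_x, pitch_y, pitch_z)) {
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0) {
      stop("all pitches must be single positive numbers (µm/voxel)")
    }
  }
  if (any(dim(voxels) < 1L)) stop("all axis lengths must be >= 1")
  structure(
    list(voxels = voxels,
         pitch_x = pitch_x, pitch_y = pitch_y, pitch_z = pitch_z,
         meta = meta),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  if (has_repeats(x)) {
    cat(sprintf("<oct_volume> %d repeats, y=%d x=%d z=%d voxels\n",
                d[1], d[2], d[3], d[4]))
  } else {
    cat(sprintf("<oct_volume> y=%d x=%d z=%d voxels\n", d[1], d[2], d[3]))
  }
  cat(sprintf("  pitch (µm): x=%.3g y=%.3g z=%.3g\n",
              x$pitch_x, x$pitch_y, x$pitch_z))
  invisible(x)
}

#' Does a volume carry a repeat axis?
#' @param volume An [oct_volume()].
#' @return `TRUE` if the voxel array is 4D `(r, y, x, z)`.
#' @export
has_repeats <- function(volume) length(dim(volume$voxels)) == 4L

#' Number of acquired B-scan frames in a volume
#'
#' One frame per (B-scan position, repeat) pair: with 500 positions and
#' 5 repeats an acquisition comprises 2500 frames.
#'
#' @param volume An [oct_volume()].
#' @return Integer frame count.
#' @export
n_frames <- function(volume) {
  d <- dim(volume$voxels)
  if (has_repeats(volume)) as.integer(d[1] * d[2]) else as.integer(d[1])
}

#' Construct a two-channel SLO frame sequence
#'
#' Frames are stored `(time, channel, row, col)` with channel 1 = red
#' (tdTomato emission band) and channel 2 = green (GFP / photoconverted
#' emission band). Timestamps must be strictly increasing.
#'
#' @param frames Non-negative 4D array `(t, c, row, col)` with exactly two
#'   channels.
#' @param pitch Pixel pitch, micrometres.
#' @param timestamps Seconds, strictly increasing, one per frame. Defaults to
#'   `(0:(t-1))/frame_rate`.
#' @param frame_rate Acquisition rate, Hz.
#' @return An object of class `slo_sequence`.
#' @export
slo_sequence <- function(frames, pitch, timestamps = NULL, frame_rate = 7.8) {
  if (!is.array(frames) || length(dim(frames)) != 4L) {
    stop("`frames` must be a 4D (t, channel, row, col) array")
  }
  if (dim(frames)[2] != 2L) stop("exactly two channels (red, green) required")
  if (anyNA(frames) || min(frames) < 0) stop("SLO intensities must be non-negative")
  if (!is.numeric(pitch) || pitch <= 0) stop("`pitch` must be positive (µm/pixel)")
  nt <- dim(frames)[1]
  if (is.null(timestamps)) timestamps <- (seq_len(nt) - 1) / frame_rate
  if (length(timestamps) != nt || any(diff(timestamps) <= 0)) {
    stop("`timestamps` must have one strictly increasing value per frame")
  }
  structure(
    list(frames = frames, pitch = pitch, timestamps = as.numeric(timestamps),
         frame_rate = frame_rate),
    class = "slo_sequence"
  )
}

#' @export
print.slo_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<slo_sequence> %d frames, 2 channels, %dx%d px @ %.3g Hz, pitch %.3g µm\n",
              d[1], d[3], d[4], x$frame_rate, x$pitch))
  invisible(x)
}

#' Photocoagulation laser pulse parameters
#'
#' @param power_mw Optical power at the pupil, mW (> 0).
#' @param duration_ms Pulse duration, ms (> 0).
#' @param repeats Number of repeat pulses at one site (integer >= 1).
#' @param interval_ms Delay between repeat pulses, ms (>= 0).
#' @return An object of class `laser_params`.
#' @examples
#' laser_params(6, 200)            # single low-severity pulse
#' laser_params(6, 200, repeats = 4, interval_ms = 50)
#' @export
laser_params <- function(power_mw, duration_ms, repeats = 1L, interval_ms = 0) {
  if (!is.numeric(power_mw) || power_mw <= 0) stop("`power_mw` must be > 0")
  if (!is.numeric(duration_ms) || duration_ms <= 0) stop("`duration_ms` must be > 0")
  if (repeats < 1 || repeats != round(repeats)) stop("`repeats` must be an integer >= 1")
  if (interval_ms < 0) stop("`interval_ms` must be >= 0")
  structure(
    list(power_mw = power_mw, duration_ms = duration_ms,
         repeats = as.integer(repeats), interval_ms = interval_ms),
    class = "laser_params"
  )
}

#' Total delivered pulse energy in millijoules
#' @param laser A [laser_params()].
#' @return Energy `power * duration * repeats` in mJ.
#' @export
pulse_energy_mj <- function(laser) {
  laser$power_mw * (laser$duration_ms / 1000) * laser$repeats
}

#' Retinal surface depth map
#'
#' Per-(y, x) axial position (1-based voxel index, possibly fractional) of a
#' named retinal surface. For a paired (OPL, RPE) set the OPL must sit
#' strictly inner to (less deep than) the RPE at every position.
#'
#' @param name `"RPE"` or `"OPL"`.
#' @param depth Numeric matrix `(y, x)` of depth indices in `[1, z]`.
#' @param z_extent Depth-axis length used for bounds validation (optional).
#' @return An object of class `surface_map`.
#' @export
surface_map <- function(name, depth, z_extent = NULL) {
  name <- match.arg(name, c("RPE", "OPL"))
  if (!is.matrix(depth) || anyNA(depth)) stop("`depth` must be a complete numeric matrix")
  if (min(depth) < 1) stop("surface depth indices must be >= 1")
  if (!is.null(z_extent) && max(depth) > z_extent) {
    stop("surface depth exceeds the volume depth extent")
  }
  structure(list(name = name, depth = depth), class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("<surface_map> %s, %dx%d, depth range [%.1f, %.1f] voxels\n",
              x$name, nrow(x$depth), ncol(x$depth), min(x$depth), max(x$depth)))
  invisible(x)
}

# Internal: check a paired OPL/RPE ordering (OPL strictly inner everywhere).
check_surface_order <- function(top, bottom) {
  if (!all(top$depth < bottom$depth)) {
    stop(sprintf("surface order violated: %s must be strictly inner to %s everywhere",
                 top$name, bottom$name))
  }
  invisible(TRUE)
}
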