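#' Average repeated B-scans
#'
#' Voxelwise arithmetic mean over the repeat axis; for `r` independent speckle
#' realizations this reduces noise standard deviation by \eqn{\sqrt{r}}.
#'
#' @param volume An [oct_volume()] with repeat axis (`r >= 1`).
#' @return An [oct_volume()] without repeat axis, shape `(y, x, z)`.
#' @export
average_repeats <- function(volume) {
  stopifnot(inherits(volume, "oct_volume"))
  if (!has_repeats(volume)) stop("volume has no repeat axis")
  d <- dim(volume$voxels)
  avg <- if (d[1] == 1L) {
    array(volume$voxels[1, , , ], d[2:4])
  } else {
    array(colMeans(matrix(volume$voxels, d[1], prod(d[2:4]))), d[2:4])
  }
  oct_volume(avg, volume$pitch_x, volume$pitch_y, volume$pitch_z,
             meta = c(volume$meta, list(repeats_averaged = d[1])))
}

#' Detect a retinal surface (RPE or OPL)
#'
#' Per A-scan the axial profile is median-filtered and its local maxima
#' collected. The RPE is taken as the deepest local maximum whose height
#' reaches `rel_peak` of the A-scan's peak (the RPE is the outermost bright
#' layer, which keeps the rule valid under vessel shadows); the map is then
#' regularized by a 2D median filter over `(y, x)` and isolated outliers are
#' replaced by their smoothed neighbourhood value. The OPL is the strongest
#' local maximum within a configurable band inner to the detected RPE.
#'
#' @param volume Averaged [oct_volume()] (no repeat axis).
#' @param name `"RPE"` or `"OPL"`.
#' @param smoothing_um 2D median window, µm (rounded to an odd pixel count).
#' @param axial_median_um Axial median-filter window, µm.
#' @param rel_peak Minimum local-max height relative to the A-scan peak.
#' @param opl_band_um For OPL: search band `(min, max)` µm inner to the RPE.
#' @param noise_quantile A-scans whose peak does not exceed this quantile of
#'   the volume by `peak_factor` count as featureless.
#' @param peak_factor Required peak-to-background ratio.
#' @param outlier_vox Deviation from the smoothed surface beyond which an
#'   A-scan's estimate is replaced by the smoothed value.
#' @return A [surface_map()].
#' @export
detect_surface <- function(volume, name = c("RPE", "OPL"), smoothing_um = 15,
                           axial_median_um = 8, rel_peak = 0.4,
                           opl_band_um = c(40, 110),
                           noise_quantile = 0.5, peak_factor = 3,
                           outlier_vox = 5) {
  name <- match.arg(name)
  stopifnot(inherits(volume, "oct_volume"))
  if (has_repeats(volume)) stop("average repeats before surface detection")
  v <- volume$voxels
  d <- dim(v)
  nyx <- d[1] * d[2]
  m <- matrix(v, nyx, d[3])
  k <- max(3L, round(axial_median_um / volume$pitch_z))
  if (k %% 2L == 0L) k <- k + 1L
  filt <- t(apply(m, 1, function(a) stats::runmed(a, k)))
  bg <- stats::quantile(m, noise_quantile)
  peaks <- apply(filt, 1, max)
  frac_flat <- mean(peaks < peak_factor * bg)
  if (frac_flat > 0.05) {
    stop(sprintf("no intensity peak above noise floor in %.1f%% of A-scans (> 5%%): featureless volume?",
                 100 * frac_flat))
  }
  nz <- d[3]
  # deepest qualifying local maximum per A-scan
  inner <- filt[, 2:(nz - 1), drop = FALSE]
  is_max <- inner >= filt[, 1:(nz - 2), drop = FALSE] &
    inner >= filt[, 3:nz, drop = FALSE] &
    inner >= rel_peak * peaks
  rpe_idx <- integer(nyx)
  for (i in seq_len(nyx)) {
    cand <- which(is_max[i, ])
    rpe_idx[i] <- if (length(cand)) max(cand) + 1L else which.max(filt[i, ])
  }
  win_px <- max(1L, round(smoothing_um / volume$pitch_x))
  if (win_px %% 2L == 0L) win_px <- win_px + 1L
  # robust smooth reference: iteratively reweighted quadratic surface, so
  # arbitrarily wide shadow regions (e.g. vessel crossings) are repaired
  smooth_reference <- function(raw) {
    if (length(raw) < 12L) return(median_filter2(raw, win_px))
    df <- data.frame(z = as.vector(raw),
                     y = rep(seq_len(d[1]), times = d[2]),
                     x = rep(seq_len(d[2]), each = d[1]))
    w <- rep(1, nrow(df))
    for (it in 1:3) {
      fit <- stats::lm(z ~ stats::poly(y, 2, raw = TRUE) +
                         stats::poly(x, 2, raw = TRUE) + y:x,
                       data = df, weights = w)
      res <- df$z - stats::fitted(fit)
      s <- stats::mad(res) + 1e-6
      w <- as.numeric(abs(res) < 3 * s)
    }
    matrix(stats::fitted(fit), d[1], d[2])
  }
  regularize <- function(idx_v) {
    raw <- matrix(idx_v, d[1], d[2])
    ref <- smooth_reference(raw)
    bad <- abs(raw - ref) > outlier_vox
    raw[bad] <- ref[bad]
    median_filter2(raw, win_px)
  }
  rpe_depth <- regularize(rpe_idx)
  if (name == "RPE") {
    return(surface_map("RPE", rpe_depth, z_extent = nz))
  }
  rpe_sm <- as.vector(rpe_depth)
  zmin <- pmax(1, ceiling(rpe_sm - opl_band_um[2] / volume$pitch_z))
  zmax <- pmax(1, floor(rpe_sm - opl_band_um[1] / volume$pitch_z))
  depth_v <- integer(nyx)
  for (i in seq_len(nyx)) {
    lo <- zmin[i]; hi <- max(zmax[i], lo)
    seg <- filt[i, lo:hi]
    depth_v[i] <- lo + which.max(seg) - 1L
  }
  sm <- surface_map("OPL", regularize(depth_v), z_extent = nz)
  if (!all(sm$depth < rpe_depth)) {
    stop("detected OPL is not strictly inner to the RPE everywhere")
  }
  sm
}

#' Digitally flatten a volume to a reference surface
#'
#' Each A-scan is shifted axially (integer voxels, zero-filled, never wrapped)
#' so the reference surface sits at its median depth. The integer shift map
#' and a validity mask of non-padded voxels are attached so flattening is
#' invertible and projections can ignore padding.
#'
#' @param volume Averaged [oct_volume()].
#' @param reference A [surface_map()] (typically the RPE).
#' @return List: `volume` (flattened), `shifts` (matrix, voxels; positive =
#'   moved deeper), `valid` (logical `(y, x, z)` array), `target_depth`.
#' @export
flatten <- function(volume, reference) {
  stopifnot(inherits(volume, "oct_volume"), inherits(reference, "surface_map"))
  if (has_repeats(volume)) stop("flatten expects an averaged volume")
  d <- dim(volume$voxels)
  target <- round(stats::median(reference$depth))
  shifts <- round(target - reference$depth)   # + = push A-scan deeper
  v <- matrix(volume$voxels, d[1] * d[2], d[3])
  out <- matrix(0, nrow(v), d[3])
  valid <- matrix(FALSE, nrow(v), d[3])
  sh <- as.vector(shifts)
  for (s in sort(unique(sh))) {
    rows <- which(sh == s)
    if (s == 0) {
      out[rows, ] <- v[rows, , drop = FALSE]
      valid[rows, ] <- TRUE
    } else if (s > 0) {
      out[rows, (1 + s):d[3]] <- v[rows, 1:(d[3] - s), drop = FALSE]
      valid[rows, (1 + s):d[3]] <- TRUE
    } else {
      out[rows, 1:(d[3] + s)] <- v[rows, (1 - s):d[3], drop = FALSE]
      valid[rows, 1:(d[3] + s)] <- TRUE
    }
  }
  fl <- oct_volume(array(out, d), volume$pitch_x, volume$pitch_y,
                   volume$pitch_z, meta = c(volume$meta, list(flattened = TRUE)))
  list(volume = fl, shifts = shifts, valid = array(valid, d),
       target_depth = target)
}

#' Undo a flattening using its shift map
#'
#' @param flat Flattened [oct_volume()].
#' @param shifts Shift matrix returned by [flatten()].
#' @return An [oct_volume()]; voxels lost to padding return as zeros.
#' @export
unflatten <- function(flat, shifts) {
  # shifting by -s undoes shifting by s (integer, zero-filled)
  d <- dim(flat$voxels)
  v <- matrix(flat$voxels, d[1] * d[2], d[3])
  out <- matrix(0, nrow(v), d[3])
  sh <- -as.vector(shifts)
  for (s in sort(unique(sh))) {
    rows <- which(sh == s)
    if (s == 0) {
      out[rows, ] <- v[rows, , drop = FALSE]
    } else if (s > 0) {
      out[rows, (1 + s):d[3]] <- v[rows, 1:(d[3] - s), drop = FALSE]
    } else {
      out[rows, 1:(d[3] + s)] <- v[rows, (1 - s):d[3], drop = FALSE]
    }
  }
  oct_volume(array(out, d), flat$pitch_x, flat$pitch_y, flat$pitch_z,
             meta = flat$meta)
}

#' Layer-bounded en face projection
#'
#' Reduces each A-scan over the half-open depth interval
#' `[top, bottom)` (so adjacent slabs partition the volume); the default
#' reducer is the mean, matching depth-averaged en face views between the OPL
#' and RPE.
#'
#' @param volume Averaged (typically flattened) [oct_volume()].
#' @param top,bottom [surface_map()]s with `top` strictly inner to `bottom`.
#' @param reducer `"mean"`, `"max"` or `"sum"`.
#' @param valid Optional validity array from [flatten()]; padded voxels are
#'   excluded from the reduction.
#' @return Numeric matrix `(y, x)` with pitch attributes.
#' @export
enface_projection <- function(volume, top, bottom,
                              reducer = c("mean", "max", "sum"),
                              valid = NULL) {
  reducer <- match.arg(reducer)
  stopifnot(inherits(volume, "oct_volume"))
  check_surface_order(top, bottom)
  d <- dim(volume$voxels)
  v <- matrix(volume$voxels, d[1] * d[2], d[3])
  tz <- pmax(1L, ceiling(as.vector(top$depth) - 1e-9))
  bz <- pmin(d[3] + 1L, ceiling(as.vector(bottom$depth) - 1e-9))
  vd <- if (!is.null(valid)) matrix(valid, d[1] * d[2], d[3]) else NULL
  fn <- switch(reducer, mean = mean, max = max, sum = sum)
  out <- numeric(nrow(v))
  for (i in seq_len(nrow(v))) {
    zs <- tz[i]:(bz[i] - 1L)
    if (bz[i] - 1L < tz[i]) { out[i] <- NA_real_; next }
    if (!is.null(vd)) zs <- zs[vd[i, zs]]
    out[i] <- if (length(zs)) fn(v[i, zs]) else NA_real_
  }
  img <- matrix(out, d[1], d[2])
  attr(img, "pitch_x") <- volume$pitch_x
  attr(img, "pitch_y") <- volume$pitch_y
  img
}

#' Standard inner/outer en face views of a processed volume
#'
#' Convenience wrapper: averages repeats, detects RPE and OPL, flattens to the
#' RPE, and returns the outer (OPL to RPE) and inner retinal mean
#' projections. The inner slab spans a fixed thickness ending at the OPL
#' rather than starting at the volume top, so the projection is not diluted
#' by a bow-dependent amount of dark vitreous (a volume-projection artifact
#' otherwise).
#'
#' @param volume An [oct_volume()] with or without repeats.
#' @param inner_slab_um Thickness of the inner-retina slab above the OPL.
#' @param ... Passed to [detect_surface()].
#' @return List: `outer`, `inner` (matrices), `flat` (volume), `rpe`, `opl`,
#'   `shifts`, `valid`.
#' @export
process_oct <- function(volume, inner_slab_um = 70, ...) {
  avg <- if (has_repeats(volume)) average_repeats(volume) else volume
  rpe <- detect_surface(avg, "RPE", ...)
  opl <- detect_surface(avg, "OPL", ...)
  fl <- flatten(avg, rpe)
  shift_surface <- function(s) {
    surface_map(s$name, pmax(s$depth + fl$shifts, 1),
                z_extent = dim(avg$voxels)[3])
  }
  rpe_f <- shift_surface(rpe)
  opl_f <- shift_surface(opl)
  outer_img <- enface_projection(fl$volume, opl_f, rpe_f, "mean", fl$valid)
  inner_top <- surface_map(
    "OPL", pmax(opl_f$depth - inner_slab_um / avg$pitch_z, 1))
  inner_img <- enface_projection(
    fl$volume, inner_top, surface_map("RPE", opl_f$depth), "mean", fl$valid)
  list(outer = outer_img, inner = inner_img, flat = fl$volume,
       rpe = rpe_f, opl = opl_f, shifts = fl$shifts, valid = fl$valid)
}
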