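# Standard synthetic segmentation benchmarks: small lesioned phantom volumes
# pushed through the same processing the real pipeline uses (repeat
# averaging, RPE detection, flattening), paired with the phantom's exact
# ground-truth masks flattened by the same shift map.

benchmark_params <- function(seed) {
  phantom_params(
    shape = c(y = 4L, x = 64L, z = 96L),
    pitch = c(x = 6, y = 3, z = 3),
    repeats = 3L,
    curvature_um = 20,
    vessels = tibble::tibble(orientation = "v", position_um = 64,
                             radius_um = 15),
    seed = seed
  )
}

# apply a flattening shift map to a logical (y, x, z) mask
flatten_mask <- function(mask, shifts) {
  d <- dim(mask)
  m <- matrix(mask, d[1] * d[2], d[3])
  out <- matrix(FALSE, nrow(m), d[3])
  sh <- as.vector(shifts)
  for (s in sort(unique(sh))) {
    rows <- which(sh == s)
    if (s == 0) out[rows, ] <- m[rows, , drop = FALSE]
    else if (s > 0) out[rows, (1 + s):d[3]] <- m[rows, 1:(d[3] - s), drop = FALSE]
    else out[rows, 1:(d[3] + s)] <- m[rows, (1 - s):d[3], drop = FALSE]
  }
  array(out, d)
}

# one processed phantom: flattened averaged volume + flattened truth mask
lesioned_example <- function(seed, energy_mj, site_um = NULL,
                             params = benchmark_params(seed)) {
  gen <- generate_retina_volume(params)
  fov <- c(params$shape[2] * params$pitch[["x"]],
           params$shape[1] * params$pitch[["y"]])
  if (is.null(site_um)) site_um <- fov / 2
  if (energy_mj > 0) {
    les <- apply_lesion(gen$volume, site_um, params = params,
                        truth = gen$truth, energy_mj = energy_mj)
    gen <- les
  }
  avg <- average_repeats(gen$volume)
  rpe <- detect_surface(avg, "RPE")
  fl <- flatten(avg, rpe)
  mask <- if (is.null(gen$truth$lesion_mask)) {
    array(FALSE, dim(avg$voxels))
  } else flatten_mask(gen$truth$lesion_mask, fl$shifts)
  list(volume = fl$volume, mask = mask, truth = gen$truth,
       energy_mj = energy_mj, params = params)
}

#' Standard synthetic segmentation benchmark
#'
#' `n` flattened single-B-scan volumes with exact lesion labels: each source
#' phantom receives one lesion of random dose (1.2 to 6 mJ, the span from a
#' single 6 mW 200 ms pulse to about four repeats of it) at a jittered
#' central site; the two central B-scans are kept. A configurable fraction of
#' lesion-free volumes provides negative examples.
#'
#' @param n Number of B-scan pairs (default 60).
#' @param seed RNG seed.
#' @param lesion_free_frac Fraction of items without a lesion (default 0.1).
#' @return A [segmentation_dataset()] of `n` single-B-scan volumes.
#' @export
make_segmentation_benchmark <- function(n = 60L, seed = 1L,
                                        lesion_free_frac = 0.1) {
  n_src <- ceiling(n / 2)
  draws <- with_seed(seed, function() {
    tibble::tibble(
      e = stats::runif(n_src, 1.2, 6),
      dx = stats::runif(n_src, -40, 40),
      free = stats::runif(n_src) < lesion_free_frac
    )
  })
  volumes <- list(); masks <- list()
  k <- 1L
  for (i in seq_len(n_src)) {
    p <- benchmark_params(seed + 37L * i)
    fov <- c(p$shape[2] * p$pitch[["x"]], p$shape[1] * p$pitch[["y"]])
    e <- if (draws$free[i]) 0 else draws$e[i]
    ex <- lesioned_example(seed + 37L * i, e,
                           site_um = c(fov[1] / 2 + draws$dx[i], fov[2] / 2),
                           params = p)
    for (y in 2:3) {
      if (k > n) break
      v <- ex$volume$voxels[y, , , drop = FALSE]
      dim(v) <- dim(ex$volume$voxels)[2:3]
      vol1 <- oct_volume(array(v, c(1L, dim(v))), ex$volume$pitch_x,
                         ex$volume$pitch_y, ex$volume$pitch_z)
      m <- ex$mask[y, , , drop = FALSE]
      dim(m) <- dim(ex$mask)[2:3]
      volumes[[k]] <- vol1
      masks[[k]] <- array(m, c(1L, dim(m)))
      k <- k + 1L
    }
    if (k > n) break
  }
  segmentation_dataset(volumes, masks)
}

#' Dose-titration phantom series
#'
#' One lesion per volume with 4 repeated 100 ms pulses at the given powers
#' (default 10 to 50 mW), emulating the severity-titration protocol; lesion
#' size grows with delivered energy.
#'
#' @param powers_mw Pulse powers, mW.
#' @param seed RNG seed.
#' @return List of `lesioned_example` outputs (flattened volume, truth mask,
#'   `energy_mj`).
#' @export
make_titration_series <- function(powers_mw = c(10, 20, 30, 40, 50),
                                  seed = 1L) {
  lapply(seq_along(powers_mw), function(i) {
    p <- phantom_params(
      shape = c(y = 64L, x = 64L, z = 96L),
      pitch = c(x = 6, y = 6, z = 3),
      repeats = 3L, curvature_um = 20,
      vessels = tibble::tibble(orientation = character(),
                               position_um = numeric(),
                               radius_um = numeric()),
      seed = seed + 101L * i
    )
    laser <- laser_params(powers_mw[i], 100, repeats = 4L)
    fov <- c(p$shape[2] * p$pitch[["x"]], p$shape[1] * p$pitch[["y"]])
    ex <- lesioned_example(seed + 101L * i, pulse_energy_mj(laser),
                           site_um = fov / 2, params = p)
    ex$power_mw <- powers_mw[i]
    ex
  })
}
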