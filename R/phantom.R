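#' Parameters of the synthetic murine-retina phantom
#'
#' The phantom emulates the statistical structure the pipeline assumes: a
#' layered axial reflectivity profile with retinal curvature, vessel shadows,
#' multiplicative speckle with independent realizations per repeated B-scan,
#' an RPE-anchored scattering lesion response with saturating dose dependence,
#' tdTomato red-to-green photoconversion on SLO, and transient respiratory
#' motion events corrupting a Poisson-timed subset of SLO frames.
#'
#' Defaults follow the emulated acquisition: 500 x 500 A-scan sampling with
#' 5 repeated B-scans per position, 200-frame two-channel SLO stacks at
#' 7.8 Hz, respiratory events at ~1.5 Hz with sub-50 µm lateral and sub-200 µm
#' axial excursions lasting tens of milliseconds.
#'
#' @param shape Integer vector `(y, x, z)` voxels.
#' @param pitch Named numeric `(x, y, z)` µm/voxel.
#' @param repeats Repeated B-scans per position.
#' @param layers Data frame `name, depth_um, thickness_um, reflectivity`,
#'   ordered inner to outer; must contain OPL and RPE with OPL inner to RPE.
#' @param curvature_um Peak axial bow of the retina over the field, µm.
#' @param vessels Data frame `orientation` ("h"/"v"), `position_um`,
#'   `radius_um`; vessels cast shadows on everything below them.
#' @param vessel_attenuation Multiplicative shadow factor in (0, 1].
#' @param speckle_contrast Multiplicative speckle ratio sd/mean per voxel.
#' @param noise_floor Additive noise-floor scale.
#' @param lesion List: `e0_mj` (saturation energy), `delta_max` (max gain -1),
#'   `axial_growth_um_per_mj`, `lateral_sigma_um`, `sigma_growth` (relative
#'   lateral growth per `e0_mj` of dose; 0 recovers a fixed footprint),
#'   `gain_threshold` (ground-truth mask cut, fixed 1.2).
#' @param photoconversion List: `kappa_per_mj` (conversion rate),
#'   `leak_gain` (green-channel detection gain of converted fluorophore),
#'   `recovery_fraction` (fraction of tdTomato returning by day 7).
#' @param slo List: `size` px, `n_frames`, `frame_rate` Hz, `tdtomato_level`,
#'   `gfp_baseline`, `texture_amp`, `texture_scale_um`, `noise_sd`.
#' @param motion List: `rate_hz`, `lateral_amplitude_um`,
#'   `axial_amplitude_um`, `event_duration_ms`.
#' @param seed Integer RNG seed; identical params give bit-identical phantoms.
#' @return A validated `phantom_params` list.
#' @export
phantom_params <- function(
    shape = c(y = 500L, x = 500L, z = 256L),
    pitch = c(x = 3, y = 3, z = 2),
    repeats = 5L,
    layers = default_layers(),
    curvature_um = 40,
    vessels = NULL,
    vessel_attenuation = 0.35,
    speckle_contrast = 0.35,
    noise_floor = 0.02,
    lesion = list(e0_mj = 2.5, delta_max = 1.5, axial_growth_um_per_mj = 15,
                  lateral_sigma_um = 20, sigma_growth = 0.25,
                  gain_threshold = 1.2),
    photoconversion = list(kappa_per_mj = 0.45, leak_gain = 0.9,
                           recovery_fraction = 0.35),
    slo = list(size = 1024L, n_frames = 200L, frame_rate = 7.8,
               tdtomato_level = 0.6, gfp_baseline = 0.12,
               texture_amp = 0.15, texture_scale_um = 100, noise_sd = 0.02),
    motion = list(rate_hz = 1.5, lateral_amplitude_um = 40,
                  axial_amplitude_um = 150, event_duration_ms = 60),
    seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1), all(pitch > 0))
  if (is.null(vessels)) {
    fov <- c(shape[2] * pitch[["x"]], shape[1] * pitch[["y"]])
    vessels <- tibble::tibble(
      orientation = c("h", "v"),
      position_um = c(fov[2] / 2, fov[1] / 2),
      radius_um = 22
    )
  }
  if (!all(c("OPL", "RPE") %in% layers$name)) stop("layers must include OPL and RPE")
  if (any(diff(layers$depth_um) <= 0)) stop("layers must be ordered inner to outer")
  opl <- layers$depth_um[layers$name == "OPL"]
  rpe <- layers$depth_um[layers$name == "RPE"]
  if (opl >= rpe) stop("layer overlap: OPL must be inner to (above) the RPE")
  if (any(layers$reflectivity <= 0)) stop("reflectivities must be > 0")
  stopifnot(curvature_um >= 0, speckle_contrast >= 0, noise_floor >= 0,
            motion$lateral_amplitude_um >= 0, motion$axial_amplitude_um >= 0)
  structure(
    list(shape = shape, pitch = pitch, repeats = as.integer(repeats),
         layers = layers, curvature_um = curvature_um, vessels = vessels,
         vessel_attenuation = vessel_attenuation,
         speckle_contrast = speckle_contrast, noise_floor = noise_floor,
         lesion = lesion, photoconversion = photoconversion,
         slo = slo, motion = motion, seed = as.integer(seed)),
    class = "phantom_params"
  )
}

#' Default retinal layer model
#'
#' Depths are layer-centre distances from the volume top (µm) before the
#' curvature bow is added; reflectivities are relative linear-intensity
#' weights with the RPE as the dominant scatterer.
#' @return A tibble of layers, inner to outer.
#' @export
default_layers <- function() {
  tibble::tibble(
    name = c("NFL", "IPL", "INL", "OPL", "ONL", "ISOS", "RPE"),
    depth_um = c(60, 85, 115, 135, 165, 195, 215),
    thickness_um = c(14, 28, 22, 14, 40, 10, 14),
    reflectivity = c(0.7, 0.45, 0.3, 0.55, 0.18, 0.5, 1.0)
  )
}

# Run fn with a private, restored RNG state seeded from `seed`.
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Axial bow (µm added to layer depth) over the field; 0 at centre, peak at
# the field corners.
phantom_bow <- function(params) {
  y <- params$shape[1]; x <- params$shape[2]
  yn <- (2 * (seq_len(y) - 0.5) / y - 1)
  xn <- (2 * (seq_len(x) - 0.5) / x - 1)
  params$curvature_um * (outer(yn^2, xn^2, `+`)) / 2
}

# En face vessel mask (TRUE under a vessel) on the OCT grid.
phantom_vessel_mask <- function(params) {
  y <- params$shape[1]; x <- params$shape[2]
  ycoord <- (seq_len(y) - 0.5) * params$pitch[["y"]]
  xcoord <- (seq_len(x) - 0.5) * params$pitch[["x"]]
  m <- matrix(FALSE, y, x)
  for (i in seq_len(nrow(params$vessels))) {
    v <- params$vessels[i, ]
    if (v$orientation == "h") {
      hit <- abs(ycoord - v$position_um) <= v$radius_um
      m[hit, ] <- TRUE
    } else {
      hit <- abs(xcoord - v$position_um) <= v$radius_um
      m[, hit] <- TRUE
    }
  }
  m
}

# Deterministic (noise-free) volume plus ground-truth surfaces.
phantom_structure <- function(params) {
  shp <- params$shape
  bow <- phantom_bow(params)              # (y, x) µm
  z_um <- (seq_len(shp[3]) - 0.5) * params$pitch[["z"]]
  nyx <- shp[1] * shp[2]
  M <- matrix(0, nyx, shp[3])
  bow_v <- as.vector(bow)
  for (l in seq_len(nrow(params$layers))) {
    lay <- params$layers[l, ]
    s <- lay$thickness_um / 2
    M <- M + lay$reflectivity *
      exp(-0.5 * (outer(-bow_v - lay$depth_um, z_um, `+`) / s)^2)
  }
  vmask <- phantom_vessel_mask(params)
  if (any(vmask)) {
    vdepth_um <- 90 + bow_v  # vessels ride in the inner retina
    shadow_rows <- which(as.vector(vmask))
    for (r in shadow_rows) {
      below <- z_um > vdepth_um[r]
      M[r, below] <- M[r, below] * params$vessel_attenuation
    }
  }
  opl_um <- params$layers$depth_um[params$layers$name == "OPL"] + bow
  rpe_um <- params$layers$depth_um[params$layers$name == "RPE"] + bow
  pz <- params$pitch[["z"]]
  list(M = M, bow = bow,
       opl = surface_map("OPL", opl_um / pz + 0.5, z_extent = shp[3]),
       rpe = surface_map("RPE", rpe_um / pz + 0.5, z_extent = shp[3]),
       opl_um = opl_um, rpe_um = rpe_um, vessel_mask = vmask)
}

#' Generate a synthetic retina OCT volume with ground truth
#'
#' Produces a repeat-axis volume in which repeats share the deterministic
#' layered structure and differ only by independent speckle / noise-floor
#' realizations, plus exact ground-truth OPL/RPE surfaces and the vessel mask.
#'
#' @param params A [phantom_params()].
#' @return List: `volume` (an [oct_volume()] with repeat axis) and `truth`
#'   (surfaces, vessel mask, empty lesion site table, lesion mask `NULL`).
#' @export
generate_retina_volume <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  shp <- params$shape
  st <- phantom_structure(params)
  r <- params$repeats
  s <- params$speckle_contrast
  v <- array(0, c(r, shp[1], shp[2], shp[3]))
  nvox <- length(st$M)
  with_seed(params$seed, function() {
    for (ri in seq_len(r)) {
      plane <- st$M
      if (s > 0) {
        plane <- plane * matrix(rgamma(nvox, shape = 1 / s^2, rate = 1 / s^2),
                                nrow(st$M), ncol(st$M))
      }
      if (params$noise_floor > 0) {
        plane <- plane + params$noise_floor * abs(rnorm(nvox))
      }
      v[ri, , , ] <<- array(plane, c(shp[1], shp[2], shp[3]))
    }
  })
  vol <- oct_volume(v, params$pitch[["x"]], params$pitch[["y"]],
                    params$pitch[["z"]],
                    meta = list(phantom_seed = params$seed,
                                repeats = r, kind = "phantom"))
  truth <- structure(
    list(opl = st$opl, rpe = st$rpe, opl_um = st$opl_um, rpe_um = st$rpe_um,
         vessel_mask = st$vessel_mask,
         sites = tibble::tibble(x_um = numeric(), y_um = numeric(),
                                energy_mj = numeric()),
         lesion_mask = NULL),
    class = "phantom_truth"
  )
  list(volume = vol, truth = truth)
}

# Scattering-gain field of one lesion site at cumulative energy E (mJ),
# evaluated over the whole volume grid. Returns the (y*x, z) gain matrix.
lesion_gain_field <- function(params, truth, site_um, energy_mj, shp) {
  les <- params$lesion
  if (energy_mj <= 0) return(NULL)
  amp <- les$delta_max * (1 - exp(-energy_mj / les$e0_mj))
  sig <- les$lateral_sigma_um * (1 + les$sigma_growth * energy_mj / les$e0_mj)
  ycoord <- (seq_len(shp[1]) - 0.5) * params$pitch[["y"]]
  xcoord <- (seq_len(shp[2]) - 0.5) * params$pitch[["x"]]
  d2 <- outer((ycoord - site_um[2])^2, (xcoord - site_um[1])^2, `+`)
  glat <- amp * exp(-d2 / (2 * sig^2))           # (y, x)
  extent_um <- les$axial_growth_um_per_mj * energy_mj
  z_um <- (seq_len(shp[3]) - 0.5) * params$pitch[["z"]]
  z_top <- pmax(truth$rpe_um - extent_um, truth$opl_um)   # (y, x) µm
  nyx <- shp[1] * shp[2]
  A <- outer(as.vector(z_top), z_um, `<=`) &
    outer(as.vector(truth$rpe_um), z_um, `>=`)
  G <- matrix(1, nyx, shp[3])
  G <- G + as.vector(glat) * A
  G
}

#' Apply a laser lesion to a phantom volume
#'
#' Multiplies the volume by the scattering-gain field
#' \eqn{g = 1 + \Delta_{max}(1 - e^{-E/E_0}) G_{lat}(x, y) A(z)} where the
#' axial support `A` anchors at the RPE surface and extends inward by
#' `axial_growth_um_per_mj * E`, clipped at the OPL. Repeated calls at the
#' same site accumulate energy before evaluating the (saturating) response,
#' reproducing pulse-wise injury accumulation. The ground-truth mask collects
#' voxels with gain above the fixed threshold.
#'
#' @param volume Phantom [oct_volume()] (with or without repeat axis).
#' @param site_um Length-2 `(x_um, y_um)` retinal position.
#' @param laser A [laser_params()]; delivered energy is
#'   `power * duration * repeats` (mJ).
#' @param params The [phantom_params()] used to build the volume.
#' @param truth The `phantom_truth` from [generate_retina_volume()].
#' @param energy_mj Optional explicit energy override (mJ).
#' @return List `volume`, `truth` with updated site table and lesion mask.
#' @export
apply_lesion <- function(volume, site_um, laser = NULL, params, truth,
                         energy_mj = NULL) {
  shp <- params$shape
  fov <- c(shp[2] * params$pitch[["x"]], shp[1] * params$pitch[["y"]])
  if (site_um[1] < 0 || site_um[1] > fov[1] ||
      site_um[2] < 0 || site_um[2] > fov[2]) {
    stop(sprintf("lesion site (%.1f, %.1f) µm outside the field of view (%g x %g µm)",
                 site_um[1], site_um[2], fov[1], fov[2]))
  }
  if (is.null(energy_mj)) {
    stopifnot(inherits(laser, "laser_params"))
    energy_mj <- pulse_energy_mj(laser)
  }
  sites <- truth$sites
  prev_i <- if (nrow(sites)) {
    which(abs(sites$x_um - site_um[1]) < 1 & abs(sites$y_um - site_um[2]) < 1)
  } else integer(0)
  e_prev <- if (length(prev_i)) sites$energy_mj[prev_i[1]] else 0
  e_tot <- e_prev + energy_mj
  if (energy_mj > 0) {
    g_new <- lesion_gain_field(params, truth, site_um, e_tot, shp)
    ratio <- g_new
    if (e_prev > 0) {
      g_old <- lesion_gain_field(params, truth, site_um, e_prev, shp)
      ratio <- g_new / g_old
    }
    v <- volume$voxels
    if (has_repeats(volume)) {
      r <- dim(v)[1]
      for (ri in seq_len(r)) {
        v[ri, , , ] <- array(matrix(v[ri, , , ], shp[1] * shp[2], shp[3]) * ratio,
                             shp)
      }
    } else {
      v <- array(matrix(v, shp[1] * shp[2], shp[3]) * ratio, shp)
    }
    volume$voxels <- v
    if (length(prev_i)) {
      sites$energy_mj[prev_i[1]] <- e_tot
    } else {
      sites <- rbind(sites, tibble::tibble(x_um = site_um[1],
                                           y_um = site_um[2],
                                           energy_mj = e_tot))
    }
    truth$sites <- sites
    # energies only accumulate, so per-site masks only grow: OR-ing the
    # updated site's mask into the union is exact and avoids recomputing
    # every other site
    site_mask <- array(g_new > params$lesion$gain_threshold, shp)
    truth$lesion_mask <- if (is.null(truth$lesion_mask)) site_mask
    else truth$lesion_mask | site_mask
  }
  list(volume = volume, truth = truth)
}

# Ground-truth lesion mask: union over sites of gain > threshold, (y, x, z).
lesion_truth_mask <- function(params, truth) {
  shp <- params$shape
  mask <- array(FALSE, shp)
  if (!nrow(truth$sites)) return(mask)
  thr <- params$lesion$gain_threshold
  for (i in seq_len(nrow(truth$sites))) {
    g <- lesion_gain_field(params, truth,
                           c(truth$sites$x_um[i], truth$sites$y_um[i]),
                           truth$sites$energy_mj[i], shp)
    mask <- mask | array(g > thr, shp)
  }
  mask
}

# Closed-form axial extent (µm) of the lesion mask, used as oracle target.
lesion_axial_extent_um <- function(params, energy_mj) {
  les <- params$lesion
  opl <- params$layers$depth_um[params$layers$name == "OPL"]
  rpe <- params$layers$depth_um[params$layers$name == "RPE"]
  min(les$axial_growth_um_per_mj * energy_mj, rpe - opl)
}

# Smooth positive texture field on an n x n grid.
phantom_texture <- function(n, scale_px, amp) {
  raw <- matrix(rnorm(n * n), n, n)
  sm <- gauss_smooth(raw, scale_px)
  sm <- sm / max(stats::sd(sm), 1e-12)
  1 + amp * sm
}

#' Generate a two-channel SLO sequence with photoconversion and motion
#'
#' The red channel carries the tdTomato map scaled by the unconverted
#' fraction, the green channel a GFP baseline plus the converted tdTomato
#' signal; the per-site converted fraction follows
#' \eqn{\phi = 1 - e^{-\kappa E}} with a Gaussian lateral footprint. A
#' Poisson-timed subset of frames is laterally displaced by the respiratory
#' motion model and flagged in ground truth. Vessels appear dark in both
#' channels, co-located with the OCT vessel layout.
#'
#' @param params A [phantom_params()].
#' @param sites Tibble `x_um`, `y_um`, `energy_mj` of delivered lesions (may
#'   be empty or `NULL`).
#' @param day7 If `TRUE`, applies the single recovery fraction to model
#'   partial return of tdTomato contrast at 7 days.
#' @param seed_offset Added to `params$seed` so repeated acquisitions of one
#'   phantom differ.
#' @return List `sequence` (an [slo_sequence()]) and `truth` (list with
#'   `corrupted_frames`, `phi_map`, `site_px` table, `pitch`).
#' @export
generate_slo_sequence <- function(params, sites = NULL, day7 = FALSE,
                                  seed_offset = 1000L) {
  stopifnot(inherits(params, "phantom_params"))
  sl <- params$slo
  n <- as.integer(sl$size)
  fov_um <- params$shape[2] * params$pitch[["x"]]
  pitch <- fov_um / n
  if (is.null(sites)) {
    sites <- tibble::tibble(x_um = numeric(), y_um = numeric(),
                            energy_mj = numeric())
  }
  pc <- params$photoconversion
  with_seed(params$seed + seed_offset, function() {
    tex_t <- phantom_texture(n, sl$texture_scale_um / pitch, sl$texture_amp)
    tex_g <- phantom_texture(n, sl$texture_scale_um / pitch, sl$texture_amp)
    Tmap <- sl$tdtomato_level * tex_t
    Gmap <- sl$gfp_baseline * tex_g
    # vessels dark in both channels
    ycoord <- (seq_len(n) - 0.5) * pitch
    xcoord <- ycoord
    ves <- matrix(1, n, n)
    for (i in seq_len(nrow(params$vessels))) {
      v <- params$vessels[i, ]
      if (v$orientation == "h") {
        ves[abs(ycoord - v$position_um) <= v$radius_um, ] <-
          params$vessel_attenuation
      } else {
        ves[, abs(xcoord - v$position_um) <= v$radius_um] <-
          params$vessel_attenuation
      }
    }
    Tmap <- Tmap * ves
    Gmap <- Gmap * ves
    # converted fraction map
    phi <- matrix(0, n, n)
    if (nrow(sites) && pc$kappa_per_mj > 0) {
      keep_unconv <- matrix(1, n, n)
      for (i in seq_len(nrow(sites))) {
        e <- sites$energy_mj[i]
        phi_i <- 1 - exp(-pc$kappa_per_mj * e)
        sig <- params$lesion$lateral_sigma_um *
          (1 + params$lesion$sigma_growth * e / params$lesion$e0_mj)
        d2 <- outer((ycoord - sites$y_um[i])^2, (xcoord - sites$x_um[i])^2, `+`)
        keep_unconv <- keep_unconv * (1 - phi_i * exp(-d2 / (2 * sig^2)))
      }
      phi <- 1 - keep_unconv
    }
    if (day7) phi <- phi * (1 - pc$recovery_fraction)
    red0 <- Tmap * (1 - phi)
    green0 <- Gmap + Tmap * phi * pc$leak_gain
    nt <- as.integer(sl$n_frames)
    fr <- array(0, c(nt, 2L, n, n))
    # respiratory events: Poisson process over the acquisition
    total_s <- nt / sl$frame_rate
    n_ev <- rpois(1, params$motion$rate_hz * total_s)
    ev_t <- sort(runif(n_ev, 0, total_s))
    corrupted <- unique(pmin(floor(ev_t * sl$frame_rate) + 1L, nt))
    amp_px <- params$motion$lateral_amplitude_um / pitch
    for (t in seq_len(nt)) {
      r_t <- red0; g_t <- green0
      if (t %in% corrupted) {
        th <- runif(1, 0, 2 * pi)
        dy <- amp_px * sin(th); dx <- amp_px * cos(th)
        # axial excursion defocuses: global intensity drop
        dim_f <- 1 - 0.25 * params$motion$axial_amplitude_um / 200
        r_t <- shift_image(r_t, dy, dx, fill = 0) * dim_f
        g_t <- shift_image(g_t, dy, dx, fill = 0) * dim_f
      }
      if (sl$noise_sd > 0) {
        r_t <- r_t + matrix(rnorm(n * n, sd = sl$noise_sd), n, n)
        g_t <- g_t + matrix(rnorm(n * n, sd = sl$noise_sd), n, n)
      }
      fr[t, 1, , ] <- pmax(r_t, 0)
      fr[t, 2, , ] <- pmax(g_t, 0)
    }
    seq <- slo_sequence(fr, pitch = pitch, frame_rate = sl$frame_rate)
    truth <- list(corrupted_frames = sort(corrupted), phi_map = phi,
                  sites = sites, pitch = pitch)
    list(sequence = seq, truth = truth)
  })
}

#' Generate a grid calibration target with distorted observations
#'
#' Emits the commanded grid (voltages and nominal positions), the distorted
#' "observed" lesion positions (the configured polynomial evaluated at the
#' commanded voltages), and rendered OCT / SLO images of the observed grid
#' with a configurable inter-modality warp, all with ground truth.
#'
#' @param spacing_um Grid spacing on the target, µm.
#' @param n_grid Nodes per side (default 7).
#' @param distortion `NULL` for the ideal linear map, or a list
#'   `coeffs_x, coeffs_y` of natural-basis grids mapping volts to µm.
#' @param rotation_deg Rotation of the physical grid target.
#' @param scale_um_per_v Nominal linear galvo scale (µm/V).
#' @param warp `NULL` for an axis-aligned similarity, or list
#'   `coeffs_x, coeffs_y` mapping OCT µm to SLO px.
#' @param image_px Rendered image size (both modalities).
#' @param spot_sigma_px Rendered spot width.
#' @param noise_sd Additive image noise (SNR ~ 1/noise_sd).
#' @param seed RNG seed.
#' @return List: `landmarks` tibble (`vx, vy, x_cmd_um, y_cmd_um, x_obs_um,
#'   y_obs_um, x_slo_px, y_slo_px, rotation_deg`), `oct_image` + `oct_pitch`,
#'   `slo_image`, `warp` (truth), `scale_um_per_v`.
#' @export
generate_grid_target <- function(spacing_um = 150, n_grid = 7L,
                                 distortion = NULL, rotation_deg = 0,
                                 scale_um_per_v = 750,
                                 warp = NULL, image_px = 256L,
                                 spot_sigma_px = 2, noise_sd = 0.05,
                                 seed = 1L) {
  stopifnot(spacing_um > 0)
  half <- (n_grid - 1) / 2
  g <- (seq_len(n_grid) - 1 - half) * spacing_um
  pts <- cbind(x = rep(g, times = n_grid), y = rep(g, each = n_grid))
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cmd_um <- pts %*% t(R)                     # commanded positions, µm
  volts <- cmd_um / scale_um_per_v
  if (is.null(distortion)) {
    obs_um <- volts * scale_um_per_v
  } else {
    m <- list(degree = nrow(distortion$coeffs_x) - 1L,
              cx = distortion$coeffs_x, cy = distortion$coeffs_y)
    obs_um <- poly2d_map(m, volts)
  }
  # render: image centre = optical axis; OCT pitch chosen to contain the grid
  extent <- max(abs(obs_um)) * 2.6 + 6 * spot_sigma_px
  oct_pitch <- extent / image_px
  um_to_px <- function(p_um) p_um / oct_pitch + image_px / 2 + 0.5
  if (is.null(warp)) {
    # default inter-modality map: scale + offset (SLO px per OCT µm);
    # coeff grids: C[i+1, j+1] * x^i y^j
    s <- image_px / extent
    warp <- list()
    warp$coeffs_x <- matrix(0, 2, 2)
    warp$coeffs_x[1, 1] <- image_px / 2 + 0.5
    warp$coeffs_x[2, 1] <- s
    warp$coeffs_y <- matrix(0, 2, 2)
    warp$coeffs_y[1, 1] <- image_px / 2 + 0.5
    warp$coeffs_y[1, 2] <- s
  }
  wm <- list(degree = nrow(warp$coeffs_x) - 1L,
             cx = warp$coeffs_x, cy = warp$coeffs_y)
  slo_px <- poly2d_map(wm, obs_um)
  render <- function(px_xy, n, sigma, seed_add) {
    with_seed(seed + seed_add, function() {
      img <- matrix(0, n, n)
      rr <- matrix(seq_len(n), n, n)
      cc <- matrix(rep(seq_len(n), each = n), n, n)
      for (i in seq_len(nrow(px_xy))) {
        img <- img + exp(-((rr - px_xy[i, 2])^2 + (cc - px_xy[i, 1])^2) /
                           (2 * sigma^2))
      }
      img + matrix(abs(rnorm(n * n, sd = noise_sd)), n, n)
    })
  }
  oct_px <- cbind(um_to_px(obs_um[, 1]), um_to_px(obs_um[, 2]))
  oct_img <- render(oct_px, image_px, spot_sigma_px, 7L)
  slo_img <- render(slo_px, image_px, spot_sigma_px, 11L)
  list(
    landmarks = tibble::tibble(
      vx = volts[, 1], vy = volts[, 2],
      x_cmd_um = cmd_um[, 1], y_cmd_um = cmd_um[, 2],
      x_obs_um = obs_um[, 1], y_obs_um = obs_um[, 2],
      x_slo_px = slo_px[, 1], y_slo_px = slo_px[, 2],
      rotation_deg = rotation_deg
    ),
    oct_image = oct_img, oct_pitch = oct_pitch,
    oct_center_px = image_px / 2 + 0.5,
    slo_image = slo_img, warp = warp, scale_um_per_v = scale_um_per_v
  )
}
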