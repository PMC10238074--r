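test_that("phantom params validate layer ordering and amplitudes", {
  bad <- default_layers()
  bad$depth_um[bad$name == "OPL"] <- 300  # below RPE
  expect_error(small_phantom() |> (\(p) p)(), NA)
  expect_error(phantom_params(shape = c(8, 8, 96),
                              pitch = c(x = 6, y = 6, z = 3),
                              layers = bad), "ordered|overlap")
})

test_that("noise-free phantom is deterministic with identical repeats", {
  p <- small_phantom(y = 8, x = 8, speckle_contrast = 0, noise_floor = 0)
  g <- generate_retina_volume(p)
  expect_identical(g$volume$voxels[1, , , ], g$volume$voxels[3, , , ])
  # deterministic layer model: A-scan peak at the RPE position
  a <- g$volume$voxels[1, 4, 4, ]
  expect_equal(which.max(a), round(g$truth$rpe$depth[4, 4]), tolerance = 1)
  # same params -> bit-identical phantom
  g2 <- generate_retina_volume(small_phantom(y = 8, x = 8,
                                             speckle_contrast = 0,
                                             noise_floor = 0))
  expect_identical(g$volume$voxels, g2$volume$voxels)
})

test_that("zero curvature gives flat ground-truth surfaces", {
  p <- small_phantom(y = 8, x = 8, curvature_um = 0)
  g <- generate_retina_volume(p)
  expect_equal(stats::sd(g$truth$rpe$depth), 0)
  expect_true(all(g$truth$opl$depth < g$truth$rpe$depth))
})

test_that("per-voxel repeat variability matches the sampled speckle model", {
  # oracle: draw the stated multiplicative gamma noise directly
  s <- 0.35
  p <- small_phantom(y = 6, x = 6, repeats = 200, seed = 8,
                     speckle_contrast = s, noise_floor = 0,
                     vessels = no_vessels())
  g <- generate_retina_volume(p)
  d <- dim(g$volume$voxels)
  m <- matrix(g$volume$voxels, d[1], prod(d[2:4]))
  emp_sd <- apply(m, 2, stats::sd)
  mean_v <- colMeans(m)
  set.seed(1)
  oracle_ratio <- stats::sd(rgamma(2e5, shape = 1 / s^2, rate = 1 / s^2))
  keep <- mean_v > 0.2  # well-resolved voxels
  expect_equal(mean(emp_sd[keep] / mean_v[keep]), oracle_ratio,
               tolerance = 0.05)
})

test_that("vessels shadow everything beneath them", {
  p <- small_phantom(y = 16, x = 16, repeats = 1, speckle_contrast = 0,
                     noise_floor = 0)
  g <- generate_retina_volume(p)
  vm <- g$truth$vessel_mask
  expect_true(any(vm) && !all(vm))
  # column 3 crosses only the horizontal vessel, so both shadowed and clear
  # A-scans exist along it
  zrpe <- round(g$truth$rpe$depth[1, 3])
  under <- g$volume$voxels[1, vm[, 3], 3, zrpe]
  clear <- g$volume$voxels[1, !vm[, 3], 3, zrpe]
  expect_true(length(under) > 0 && length(clear) > 0)
  expect_lt(max(under), min(clear))
})

test_that("lesion response is monotone, accumulates energy, and has the
           closed-form axial extent", {
  p <- small_phantom(vessels = no_vessels(), seed = 3)
  g <- generate_retina_volume(p)
  fov <- c(32 * 6, 24 * 6) / 2
  # E = 0: untouched
  r0 <- apply_lesion(g$volume, fov, params = p, truth = g$truth,
                     energy_mj = 0)
  expect_identical(r0$volume$voxels, g$volume$voxels)
  expect_true(is.null(r0$truth$lesion_mask) || !any(r0$truth$lesion_mask))
  # pulse-wise accumulation: 4 successive pulses == one 4-repeat delivery
  l1 <- laser_params(6, 200)
  acc <- list(volume = g$volume, truth = g$truth)
  for (i in 1:4) acc <- apply_lesion(acc$volume, fov, l1, p, acc$truth)
  once <- apply_lesion(g$volume, fov, laser_params(6, 200, repeats = 4), p,
                       g$truth)
  expect_equal(acc$volume$voxels, once$volume$voxels, tolerance = 1e-12)
  expect_equal(acc$truth$sites$energy_mj, 4.8)
  # mean gain grows from 1 to 4 pulses (Fig 6A-style monotonicity)
  one <- apply_lesion(g$volume, fov, l1, p, g$truth)
  gain_in_mask <- function(res) {
    rep4d <- array(rep(res$truth$lesion_mask, each = dim(g$volume$voxels)[1]),
                   dim(g$volume$voxels))
    mean(res$volume$voxels[rep4d] / g$volume$voxels[rep4d])
  }
  expect_gt(gain_in_mask(one), 1)
  expect_gt(gain_in_mask(acc), gain_in_mask(one))
  # closed-form axial-extent oracle at E0 vs 2*E0 (below the OPL clip)
  ext <- function(E) {
    gg <- generate_retina_volume(p)
    rr <- apply_lesion(gg$volume, fov, params = p, truth = gg$truth,
                       energy_mj = E)
    zs <- which(apply(rr$truth$lesion_mask, 3, any))
    (max(zs) - min(zs) + 1) * p$pitch[["z"]]
  }
  e0 <- p$lesion$e0_mj
  expect_equal(ext(2 * e0) / ext(e0),
               lesion_axial_extent_um(p, 2 * e0) / lesion_axial_extent_um(p, e0),
               tolerance = 0.15)  # voxel discretization
  # mask volume monotone in energy, empty at 0
  vols <- sapply(c(0, 1, 2, 4, 8), function(E) {
    gg <- generate_retina_volume(p)
    rr <- apply_lesion(gg$volume, fov, params = p, truth = gg$truth,
                       energy_mj = E)
    if (is.null(rr$truth$lesion_mask)) 0 else sum(rr$truth$lesion_mask)
  })
  expect_equal(vols[1], 0)
  expect_true(all(diff(vols) > 0))
  # site outside the field errors
  expect_error(apply_lesion(g$volume, c(1e5, 1e5), l1, p, g$truth),
               "outside the field")
})

test_that("photoconversion fraction is bounded, increasing, and saturates", {
  p <- small_phantom(y = 64, x = 64, slo = small_slo(64L, 6L),
                     vessels = no_vessels())
  fov <- 64 * 6
  phis <- sapply(c(0.5, 1.2, 4.8, 1e4), function(E) {
    s <- generate_slo_sequence(
      p, sites = tibble::tibble(x_um = fov / 2, y_um = fov / 2, energy_mj = E))
    max(s$truth$phi_map)
  })
  expect_true(all(phis >= 0 & phis <= 1))
  expect_true(all(diff(phis) > 0))
  expect_equal(phis[4], 1, tolerance = 1e-6)  # complete conversion at E -> Inf
  # kappa = 0: no lesion signal above the green baseline
  p0 <- small_phantom(y = 64, x = 64, slo = small_slo(64L, 6L),
                      vessels = no_vessels(),
                      photoconversion = list(kappa_per_mj = 0, leak_gain = 0.9,
                                             recovery_fraction = 0.35))
  s_les <- generate_slo_sequence(
    p0, sites = tibble::tibble(x_um = fov / 2, y_um = fov / 2, energy_mj = 10))
  s_none <- generate_slo_sequence(p0, sites = NULL)
  expect_equal(max(s_les$truth$phi_map), 0)
  expect_equal(mean(s_les$sequence$frames[, 2, , ]),
               mean(s_none$sequence$frames[, 2, , ]), tolerance = 0.01)
})

test_that("respiratory events corrupt the Poisson-expected number of frames", {
  p <- small_phantom(y = 32, x = 32, slo = small_slo(32L, 40L))
  rate <- p$motion$rate_hz; fr <- p$slo$frame_rate; n <- 40
  counts <- sapply(1:60, function(s) {
    p2 <- small_phantom(y = 32, x = 32, slo = small_slo(32L, 40L), seed = s)
    length(generate_slo_sequence(p2)$truth$corrupted_frames)
  })
  # oracle: distinct-frame expectation of the Poisson event model
  expected <- n * (1 - exp(-rate / fr))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se + 0.5)
  # and it is close to the raw rate ratio n * rate / frame_rate
  expect_equal(mean(counts), n * rate / fr, tolerance = 0.15)
})

test_that("grid targets honour distortion, rotation, and warp ground truth", {
  # zero distortion: observed == commanded
  gt <- generate_grid_target(spacing_um = 150, seed = 2)
  expect_equal(gt$landmarks$x_obs_um, gt$landmarks$x_cmd_um, tolerance = 1e-9)
  # 90 degree rotation preserves the landmark multiset
  gt90 <- generate_grid_target(spacing_um = 150, rotation_deg = 90, seed = 2)
  d0 <- sort(round(gt$landmarks$x_cmd_um^2 + gt$landmarks$y_cmd_um^2, 6))
  d90 <- sort(round(gt90$landmarks$x_cmd_um^2 + gt90$landmarks$y_cmd_um^2, 6))
  expect_equal(d0, d90)
  # quadratic distortion: observed equals direct polynomial evaluation
  cx <- matrix(0, 3, 3); cx[2, 1] <- 95 * 7.5; cx[3, 1] <- 30; cx[2, 2] <- 11
  cy <- matrix(0, 3, 3); cy[1, 2] <- 98 * 7.5; cy[1, 3] <- 22; cy[2, 2] <- 15
  gtq <- generate_grid_target(distortion = list(coeffs_x = cx, coeffs_y = cy),
                              seed = 3)
  v <- cbind(gtq$landmarks$vx, gtq$landmarks$vy)
  oracle <- retlesion:::poly2d_map(list(degree = 2L, cx = cx, cy = cy), v)
  expect_equal(gtq$landmarks$x_obs_um, oracle[, 1], tolerance = 1e-9)
  expect_equal(gtq$landmarks$y_obs_um, oracle[, 2], tolerance = 1e-9)
})
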