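test_that("motion QC keeps identical frames and rejects labeled events", {
  fr <- array(0.5, c(10, 2, 16, 16))
  qc0 <- reject_motion_frames(slo_sequence(fr, 2))
  expect_length(qc0$rejected, 0)
  expect_error(reject_motion_frames(slo_sequence(array(0.5, c(4, 2, 8, 8)), 2)),
               "at least 5")
  # phantom stacks with ground-truth corrupted frames, several seeds
  sens <- fr_rej <- c()
  for (s in 1:5) {
    p <- small_phantom(y = 64, x = 64, slo = small_slo(128L, 24L), seed = 40 + s)
    sl <- generate_slo_sequence(p)
    truth <- sl$truth$corrupted_frames
    if (!length(truth)) next
    qc <- reject_motion_frames(sl$sequence, max_disp_px = 5)
    sens <- c(sens, mean(truth %in% qc$rejected))
    clean <- setdiff(seq_len(24), truth)
    fr_rej <- c(fr_rej, mean(clean %in% qc$rejected))
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fr_rej), 0.05)
  # all-rejected pathological case errors
  expect_error(reject_motion_frames(slo_sequence(array(0.5, c(6, 2, 8, 8)), 2),
                                    max_disp_px = -1), "all frames")
})

test_that("registration recovers constructed integer shifts exactly", {
  set.seed(8)
  scene <- retlesion:::gauss_smooth(matrix(runif(96 * 96), 96, 96), 2)
  shifts <- rbind(c(0, 0), c(2, -3), c(-4, 1), c(5, 5), c(0, -2))
  fr <- array(0, c(5, 2, 96, 96))
  for (i in 1:5) {
    sh <- retlesion:::shift_image(scene, shifts[i, 1], shifts[i, 2], fill = 0)
    fr[i, 1, , ] <- sh; fr[i, 2, , ] <- sh * 0.5
  }
  ra <- register_and_average(slo_sequence(fr, 2))
  expect_equal(ra$shifts$dy_px, -shifts[, 1])
  expect_equal(ra$shifts$dx_px, -shifts[, 2])
  ctr <- 20:76
  expect_lt(max(abs(ra$red[ctr, ctr] - scene[ctr, ctr])), 1e-6)
  # green channel gets the red-channel shifts
  expect_lt(max(abs(ra$green[ctr, ctr] - 0.5 * scene[ctr, ctr])), 1e-6)
  # single kept frame is the identity
  one <- register_and_average(slo_sequence(fr, 2), kept = 3)
  expect_identical(one$red, fr[3, 1, , ])
})

test_that("averaging N aligned noisy frames reduces noise by sqrt(N)", {
  set.seed(9)
  scene0 <- retlesion:::gauss_smooth(matrix(runif(96 * 96), 96, 96), 2)
  scene <- (scene0 - mean(scene0)) / stats::sd(scene0) * 0.25 + 0.6
  s48 <- scene[1:48, 1:48]
  N <- 16
  ratios <- replicate(30, {
    fr <- array(0, c(N, 2, 48, 48))
    for (i in 1:N) {
      fr[i, 1, , ] <- pmax(s48 + matrix(rnorm(48 * 48, sd = 0.1), 48, 48), 0)
      fr[i, 2, , ] <- fr[i, 1, , ]
    }
    ra <- register_and_average(slo_sequence(fr, 2))
    stats::sd(ra$red[10:38, 10:38] - s48[10:38, 10:38]) / 0.1
  })
  expect_equal(mean(ratios), 1 / sqrt(N), tolerance = 0.1)
})

test_that("shift estimation is antisymmetric", {
  set.seed(10)
  scene <- retlesion:::gauss_smooth(matrix(runif(80 * 80), 80, 80), 2)
  for (sh in list(c(1.6, -2.3), c(-0.8, 0.4), c(3, 2))) {
    b <- retlesion:::shift_image(scene, sh[1], sh[2], fill = 0)
    p1 <- retlesion:::phase_correlate(scene, b)
    p2 <- retlesion:::phase_correlate(b, scene)
    expect_lt(abs(p1$dy + p2$dy), 0.1)
    expect_lt(abs(p1$dx + p2$dx), 0.1)
  }
})

test_that("photoconversion index is bounded, ratio-invariant, and sentinelled", {
  pre <- list(red = matrix(1, 8, 8), green = matrix(0.1, 8, 8))
  post <- list(red = matrix(0.4, 8, 8), green = matrix(0.7, 8, 8))
  pm <- photoconversion_map(pre, post)
  expect_equal(pm$p[1, 1], 0.6 / (0.6 + 0.4))
  # invariance to a common channel gain (exact ratio property)
  pm2 <- photoconversion_map(lapply(pre, \(m) m * 3.7),
                             lapply(post, \(m) m * 3.7))
  expect_equal(pm$p, pm2$p)
  # post == pre: p is 0 or undefined, never positive
  pm0 <- photoconversion_map(pre, pre)
  expect_true(all(pm0$p[!is.na(pm0$p)] == 0))
  # below the noise floor the index is the NA sentinel
  dim_pre <- list(red = matrix(0.01, 4, 4), green = matrix(0.01, 4, 4))
  pm3 <- photoconversion_map(dim_pre, dim_pre, noise_floor = 0.05)
  expect_true(all(is.na(pm3$p)))
  # p in [0, 1] wherever defined, for random inputs
  set.seed(4)
  for (i in 1:5) {
    a <- list(red = matrix(runif(64), 8, 8), green = matrix(runif(64), 8, 8))
    b <- list(red = matrix(runif(64), 8, 8), green = matrix(runif(64), 8, 8))
    pp <- photoconversion_map(a, b)$p
    expect_true(all(pp[!is.na(pp)] >= 0 & pp[!is.na(pp)] <= 1))
  }
})

test_that("complete conversion yields p near 1 inside the lesion", {
  p <- small_phantom(y = 64, x = 64, slo = small_slo(96L, 8L),
                     vessels = no_vessels(),
                     photoconversion = list(kappa_per_mj = 0.45, leak_gain = 1,
                                            recovery_fraction = 0.35))
  fov <- 64 * 6
  site <- tibble::tibble(x_um = fov / 2, y_um = fov / 2, energy_mj = 30)
  pre <- generate_slo_sequence(p, NULL)
  post <- generate_slo_sequence(p, site)
  pa <- process_slo(pre$sequence, max_disp_px = 4)
  po <- process_slo(post$sequence, max_disp_px = 4)
  pm <- photoconversion_map(pa, po)
  core <- post$truth$phi_map > 0.9
  expect_gt(conversion_in_mask(pm, core), 0.9)
})

test_that("p increases strictly with pulse count (1 to 4 pulses)", {
  p <- small_phantom(y = 96, x = 96, slo = small_slo(96L, 8L),
                     vessels = no_vessels())
  fov <- 96 * 6
  pre <- generate_slo_sequence(p, NULL)
  pa <- process_slo(pre$sequence, max_disp_px = 4)
  ps <- sapply(1:4, function(k) {
    site <- tibble::tibble(x_um = fov / 2, y_um = fov / 2, energy_mj = 1.2 * k)
    post <- generate_slo_sequence(p, site)
    po <- process_slo(post$sequence, max_disp_px = 4)
    conversion_in_mask(photoconversion_map(pa, po),
                       post$truth$phi_map > 0.15)
  })
  expect_true(all(diff(ps) > 0))
})

test_that("lesions are localized at their planned sites", {
  p <- small_phantom(y = 128, x = 128, slo = small_slo(128L, 8L), seed = 4)
  fov <- 128 * 6
  sites <- quadrant_sites(c(fov, fov))
  sites$energy_mj <- 1.2
  pre <- generate_slo_sequence(p, NULL)
  post <- generate_slo_sequence(p, sites)
  pa <- process_slo(pre$sequence, max_disp_px = 4)
  po <- process_slo(post$sequence, max_disp_px = 4)
  pm <- photoconversion_map(pa, po)
  loc <- lesion_localize_slo(pm, pitch = post$truth$pitch,
                             p_threshold = 0.25, min_area_px = 9)
  expect_equal(nrow(loc), 12)
  dists <- sapply(seq_len(nrow(sites)), function(i) {
    min(sqrt((loc$x_um - sites$x_um[i])^2 + (loc$y_um - sites$y_um[i])^2))
  })
  expect_lt(max(dists), 25)  # within one spot radius
  # empty map gives an empty table
  empty <- photoconversion_map(pa, pa)
  expect_equal(nrow(lesion_localize_slo(empty, 6)), 0)
})

test_that("QC + registration never degrades noise versus naive averaging", {
  p <- small_phantom(y = 64, x = 64, slo = small_slo(96L, 16L), seed = 9,
                     vessels = no_vessels())
  sl <- generate_slo_sequence(p)
  naive_red <- apply(sl$sequence$frames[, 1, , ], c(2, 3), mean)
  pr <- process_slo(sl$sequence, max_disp_px = 4)
  # compare high-frequency residual (noise proxy) against a smooth reference
  hf <- function(img) {
    ok <- !is.na(img)
    sm <- retlesion:::gauss_smooth(ifelse(ok, img, mean(img, na.rm = TRUE)), 3)
    stats::sd((img - sm)[ok])
  }
  expect_lte(hf(pr$red), hf(naive_red) * 1.05)
})
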