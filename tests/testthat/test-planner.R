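test_that("patch plans have the overlap-defined pitch and match the oracle", {
  pitch <- 2
  tr <- matrix(FALSE, 150, 250)
  tr[26:125, 26:225] <- TRUE  # 200 x 400 µm rectangle
  laser <- laser_params(6, 200)
  plan <- plan_patch(tr, NULL, pitch, spot_diameter_um = 50, overlap = 0.5,
                     laser = laser)
  xs <- sort(unique(plan$x_um))
  expect_equal(unique(round(diff(xs), 9)), 25)    # (1 - 0.5) * 50
  expect_equal((50 - unique(round(diff(xs), 9))) / 50, 0.5)
  ora <- oracle_patch_sites(tr, NULL, pitch, 50, 0.5)
  expect_equal(nrow(plan), nrow(ora))
  expect_equal(cbind(plan$x_um, plan$y_um), unname(ora), tolerance = 1e-9)
  # overlap 0: pitch equals the spot diameter
  p0 <- plan_patch(tr, NULL, pitch, 50, 0, laser)
  expect_equal(unique(round(diff(sort(unique(p0$x_um))), 9)), 50)
  # exclusion == treatment kills every site
  expect_equal(nrow(plan_patch(tr, tr, pitch, 50, 0.5, laser)), 0)
  # spot larger than the mask: empty plan with warning
  tiny <- matrix(FALSE, 30, 30); tiny[14:16, 14:16] <- TRUE
  expect_warning(pt <- plan_patch(tiny, NULL, 2, 50, 0.5, laser),
                 "larger|empty")
  expect_equal(nrow(pt), 0)
})

test_that("random masks: oracle agreement and exclusion safety (property)", {
  set.seed(14)
  laser <- laser_params(6, 200)
  for (i in 1:20) {
    tr <- retlesion:::gauss_smooth(matrix(runif(60 * 60), 60, 60), 6) > 0.5
    ex <- retlesion:::gauss_smooth(matrix(runif(60 * 60), 60, 60), 4) > 0.62
    pl <- suppressWarnings(plan_patch(tr, ex, 4, 40, 0.5, laser))
    ora <- oracle_patch_sites(tr, ex, 4, 40, 0.5)
    expect_equal(nrow(pl), nrow(ora))
    if (nrow(pl)) {
      expect_equal(cbind(pl$x_um, pl$y_um), unname(ora), tolerance = 1e-9)
      cy <- (seq_len(60) - 0.5) * 4; cx <- cy
      for (j in seq_len(nrow(pl))) {
        ins <- outer((cy - pl$y_um[j])^2, (cx - pl$x_um[j])^2, `+`) <= 20^2
        expect_false(any(ex[ins]))
        expect_true(all(tr[ins]))
      }
    }
  }
})

test_that("site count shrinks with spot size and exclusion area (property)", {
  set.seed(15)
  laser <- laser_params(6, 200)
  tr <- retlesion:::gauss_smooth(matrix(runif(60 * 60), 60, 60), 8) > 0.45
  n_by_spot <- sapply(c(24, 40, 56, 72), function(s) {
    nrow(suppressWarnings(plan_patch(tr, NULL, 4, s, 0.5, laser)))
  })
  expect_true(all(diff(n_by_spot) <= 0))
  ex_small <- retlesion:::gauss_smooth(matrix(runif(3600), 60, 60), 4) > 0.75
  ex_big <- ex_small | (retlesion:::gauss_smooth(matrix(runif(3600), 60, 60), 4) > 0.7)
  n_small <- nrow(suppressWarnings(plan_patch(tr, ex_small, 4, 40, 0.5, laser)))
  n_big <- nrow(suppressWarnings(plan_patch(tr, ex_big, 4, 40, 0.5, laser)))
  expect_lte(n_big, n_small)
})

test_that("focal plans validate sites and the quadrant preset gives 3 per quadrant", {
  laser <- laser_params(6, 200)
  fov <- c(768, 768)
  sites <- quadrant_sites(fov)
  expect_equal(nrow(sites), 12)
  expect_equal(as.integer(table(sites$quadrant)), rep(3L, 4))
  # vessel-free mask: all 12 admissible
  tr <- matrix(TRUE, 128, 128)
  plan <- plan_focal(sites, laser, treatment = tr, pitch_um = 6)
  expect_equal(nrow(plan), 12)
  # a site on a vessel (exclusion) pixel errors, naming the site
  ex <- matrix(FALSE, 128, 128)
  px <- ceiling(sites$y_um[5] / 6); py <- ceiling(sites$x_um[5] / 6)
  ex[px, py] <- TRUE
  expect_error(plan_focal(sites, laser, treatment = tr, exclusion = ex,
                          pitch_um = 6), "site 5")
  # empty site list is a valid empty plan
  empty <- plan_focal(tibble::tibble(x_um = numeric(), y_um = numeric()),
                      laser, pitch_um = 6)
  expect_equal(nrow(empty), 0)
})

test_that("schedules expand repeats with exact timing and energy bookkeeping", {
  g <- grid7()
  cal <- fit_voltage_map(data.frame(g, x_um = 300 * g$vx + 300,
                                    y_um = 300 * g$vy + 300), 1)
  plan <- plan_focal(tibble::tibble(x_um = c(100, 200), y_um = c(100, 200)),
                     laser_params(6, 200, repeats = 4, interval_ms = 50),
                     pitch_um = 2)
  sch <- compile_schedule(plan, cal)
  expect_equal(nrow(sch), 8)
  within1 <- sch$onset_ms[sch$site == 1]
  expect_equal(unique(diff(within1)), 250)     # duration + interval
  expect_equal(sum(sch$duration_ms), 1600)     # total on-time
  expect_equal(sum(sch$power_mw * sch$duration_ms),
               2 * 4 * 6 * 200)                # exact energy bookkeeping
  expect_true(all(diff(sch$onset_ms) > 0))
  # voltages land back on the sites through the calibration
  back <- map_voltage(cal, cbind(sch$vx, sch$vy))
  expect_equal(unname(back[, 1]), rep(c(100, 200), each = 4),
               tolerance = 1e-6, ignore_attr = TRUE)
  # repeats 1: one row per site
  p1 <- plan_focal(tibble::tibble(x_um = 100, y_um = 100),
                   laser_params(6, 200), pitch_um = 2)
  expect_equal(nrow(compile_schedule(p1, cal)), 1)
  # identity calibration: voltages equal positions numerically
  cal_id <- fit_voltage_map(data.frame(g2 <- grid7() * 200,
                                       x_um = g2$vx, y_um = g2$vy), 1)
  sch_id <- compile_schedule(p1, cal_id)
  expect_equal(c(sch_id$vx, sch_id$vy), c(100, 100), tolerance = 1e-6,
               ignore_attr = TRUE)
  # sites beyond the calibration image error
  pl_out <- plan_focal(tibble::tibble(x_um = 5000, y_um = 5000),
                       laser_params(6, 200), pitch_um = 2)
  expect_error(compile_schedule(pl_out, cal), "outside")
})

test_that("coverage reports match disc-union geometry", {
  pitch <- 2
  tr <- matrix(FALSE, 150, 250); tr[26:125, 26:225] <- TRUE
  laser <- laser_params(6, 200)
  plan <- plan_patch(tr, NULL, pitch, 50, 0.5, laser)
  cov <- coverage_report(plan)
  # interior (eroded by one spot radius) is completely covered
  idx <- which(tr, arr.ind = TRUE)
  cy <- (idx[, 1] - 0.5) * pitch; cx <- (idx[, 2] - 0.5) * pitch
  interior <- cy >= 26 * 2 - 2 + 25 & cy <= 125 * 2 - 25 &
    cx >= 25 * 2 + 25 & cx <= 225 * 2 - 25
  gaps <- cov$gap_map[tr]
  expect_true(all(!gaps[interior]))
  expect_gt(cov$coverage, 0.95)
  # empty plan covers nothing
  em <- plan_patch(tr, tr, pitch, 50, 0.5, laser)
  expect_equal(coverage_report(em, tr, pitch)$coverage, 0)
  # single site covers one disc area within discretization
  single <- plan_focal(tibble::tibble(x_um = 250, y_um = 150), laser,
                       treatment = tr, pitch_um = pitch)
  cs <- coverage_report(single, tr, pitch)
  expect_equal(cs$coverage, pi * 25^2 / (200 * 400), tolerance = 0.02)
})

test_that("plans round-trip through JSON", {
  laser <- laser_params(6, 200, 4, 50)
  plan <- plan_focal(tibble::tibble(x_um = c(10, 20), y_um = c(30, 40)),
                     laser, pitch_um = 2, spot_diameter_um = 50)
  f <- tempfile(fileext = ".json")
  write_plan(plan, f)
  p2 <- read_plan(f)
  expect_equal(p2$x_um, plan$x_um)
  expect_equal(p2$repeats, plan$repeats)
  expect_equal(attr(p2, "spot_diameter_um"), 50)
  unlink(f)
})
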