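test_that("an exact linear scan map is recovered with negligible residual", {
  g <- grid7()
  pairs <- data.frame(g, x_um = 100 * g$vx, y_um = 100 * g$vy)
  m <- fit_voltage_map(pairs, degree = 1)
  expect_lt(m$rms_residual, 1e-9)
  expect_equal(m$coeffs_x[1, 1], 0, tolerance = 1e-9)
  expect_equal(m$coeffs_x[2, 1], 100, tolerance = 1e-9)
  expect_equal(m$coeffs_y[1, 2], 100, tolerance = 1e-9)
  # identity-like evaluation
  m_id <- fit_voltage_map(data.frame(g, x_um = g$vx, y_um = g$vy), 1)
  expect_equal(as.vector(map_voltage(m_id, c(0.3, -0.2))), c(0.3, -0.2),
               tolerance = 1e-9)
  # domain corner evaluates finitely without warning
  expect_warning(map_voltage(m, c(1, 1)), NA)
  expect_warning(map_voltage(m, c(1.5, 0)), "extrapolating")
})

test_that("quadratic distortion coefficients are recovered against a
           normal-equations oracle", {
  pairs <- quad_pairs()
  m <- fit_voltage_map(pairs, degree = 2)
  expect_lt(max(abs(m$coeffs_x - quad_truth_cx())), 1e-6)
  expect_lt(max(abs(m$coeffs_y - quad_truth_cy())), 1e-6)
  # independent oracle: explicit normal-equations solve on the raw monomials
  X <- with(pairs, cbind(1, vx, vy, vx^2, vx * vy, vy^2,
                         vx^2 * vy, vx * vy^2, vx^2 * vy^2))
  beta <- solve(t(X) %*% X, t(X) %*% pairs$x_um)
  expect_equal(m$coeffs_x[2, 1], beta[2], tolerance = 1e-6)
  expect_equal(m$coeffs_x[3, 1], beta[4], tolerance = 1e-6)
  expect_equal(m$coeffs_x[2, 2], beta[5], tolerance = 1e-6)
  # forward map matches the generating formula at a grid node
  mv <- map_voltage(m, c(0.5, -1 / 3))
  expect_equal(mv[1], 95 * 0.5 + 4 * 0.25 + 1.5 * 0.5 * (-1 / 3),
               tolerance = 1e-6)
})

test_that("fit errors: underdetermined, collinear, empty report", {
  pairs <- quad_pairs()
  expect_error(fit_voltage_map(pairs[1:3, ], 2), "underdetermined")
  line <- data.frame(vx = seq(-1, 1, 0.2), vy = seq(-1, 1, 0.2))
  line <- data.frame(line, x_um = line$vx, y_um = line$vy)
  expect_error(fit_voltage_map(line, 1), "collinear|degenerate")
  m <- fit_voltage_map(pairs, 2)
  expect_error(targeting_report(m, pairs[0, ]), "empty")
})

test_that("inversion round-trips and rejects unreachable targets", {
  m <- fit_voltage_map(quad_pairs(), 2)
  v0 <- c(0.25, 0.4)
  tgt <- map_voltage(m, v0)
  expect_lt(max(abs(invert_map(m, tgt) - v0)), 1e-4)
  # linear model inverts to the closed-form solution
  g <- grid7()
  ml <- fit_voltage_map(data.frame(g, x_um = 80 * g$vx + 5 * g$vy,
                                   y_um = -4 * g$vx + 90 * g$vy), 1)
  A <- matrix(c(80, -4, 5, 90), 2, 2)
  tgt2 <- c(33, -21)
  expect_lt(max(abs(invert_map(ml, tgt2) - solve(A, tgt2))), 1e-9)
  expect_error(invert_map(m, c(2000, 2000)), "outside")
})

test_that("random polynomial maps of degree <= 3 are recovered exactly and
           invert within tolerance (property)", {
  set.seed(11)
  for (i in 1:25) {
    d <- sample(1:3, 1)
    cx <- matrix(0, d + 1, d + 1); cy <- matrix(0, d + 1, d + 1)
    cx[2, 1] <- runif(1, 600, 900); cy[1, 2] <- runif(1, 600, 900)
    high <- (row(cx) + col(cx)) > 2.5
    cx[high] <- cx[high] + runif(sum(high), -15, 15)
    cy[high] <- cy[high] + runif(sum(high), -15, 15)
    cx[1, 1] <- runif(1, -20, 20); cy[1, 1] <- runif(1, -20, 20)
    g <- grid7()
    pos <- retlesion:::poly2d_map(list(degree = d, cx = cx, cy = cy),
                                  as.matrix(g))
    fit <- fit_voltage_map(data.frame(g, x_um = pos[, 1], y_um = pos[, 2]), d)
    expect_lt(max(abs(fit$coeffs_x - cx)), 1e-6)
    expect_lt(max(abs(fit$coeffs_y - cy)), 1e-6)
    expect_lt(fit$rms_residual, 1e-6)
    dense <- as.matrix(expand.grid(vx = seq(-0.95, 0.95, length.out = 6),
                                   vy = seq(-0.95, 0.95, length.out = 6)))
    tg <- map_voltage(fit, dense)
    vv <- invert_map(fit, tg)
    expect_lt(max(sqrt(rowSums((map_voltage(fit, vv) - tg)^2))), 0.1)
  }
})

test_that("residual rms under i.i.d. position noise follows sigma*sqrt(1-p/n)", {
  set.seed(9)
  g <- grid7()
  rmss <- replicate(200, {
    pn <- data.frame(g, x_um = 100 * g$vx + rnorm(49),
                     y_um = 100 * g$vy + rnorm(49))
    fit_voltage_map(pn, 1)$rms_residual
  })
  expect_equal(mean(rmss), sqrt(1 - 4 / 49), tolerance = 0.1)
})

test_that("rotated-grid union recovers the same model as a single dense grid", {
  set.seed(7)
  cx <- quad_truth_cx() * 7.5; cy <- quad_truth_cy() * 7.5
  mdl <- list(degree = 2L, cx = cx, cy = cy)
  mk_pairs <- function(rot_deg) {
    gt <- generate_grid_target(spacing_um = 150, distortion = list(
      coeffs_x = cx, coeffs_y = cy), rotation_deg = rot_deg, seed = rot_deg + 1)
    data.frame(vx = gt$landmarks$vx, vy = gt$landmarks$vy,
               x_um = gt$landmarks$x_obs_um + rnorm(49, sd = 0.5),
               y_um = gt$landmarks$y_obs_um + rnorm(49, sd = 0.5))
  }
  rot_union <- do.call(rbind, lapply(c(0, 15, 30, 45), mk_pairs))
  m_rot <- fit_voltage_map(rot_union, 2)
  m_single <- fit_voltage_map(mk_pairs(0), 2)
  # compare the fitted mappings (coefficients are correlated; the map is the
  # meaningful object): both agree with the generator and each other to a
  # few times the fit's prediction noise (~ sigma * sqrt(p/n) = 0.21 µm)
  # stay inside the domain shared by every rotation (no extrapolation)
  dense <- as.matrix(expand.grid(vx = seq(-0.55, 0.55, length.out = 8),
                                 vy = seq(-0.55, 0.55, length.out = 8)))
  truth_pos <- retlesion:::poly2d_map(mdl, dense)
  pred_rot <- suppressWarnings(map_voltage(m_rot, dense))
  pred_single <- suppressWarnings(map_voltage(m_single, dense))
  expect_lt(sqrt(mean((pred_rot - truth_pos)^2)), 1)
  expect_lt(sqrt(mean((pred_rot - pred_single)^2)), 1)
})

test_that("targeting report flags outliers and tidiers summarize the model", {
  m <- fit_voltage_map(quad_pairs(), 2)
  held <- quad_pairs()[seq(1, 49, 7), ]
  rep0 <- targeting_report(m, held)
  expect_lt(attr(rep0, "rms_um"), 1e-6)
  held$x_um[3] <- held$x_um[3] + 100
  rep1 <- targeting_report(m, held)
  expect_equal(attr(rep1, "max_um"), 100, tolerance = 1e-6)
  expect_equal(which.max(rep1$residual_um), 3L)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2 * 9)
  expect_equal(td$estimate[td$axis == "x" & td$power_vx == 1 &
                             td$power_vy == 0], 95, tolerance = 1e-6)
  gl <- glance(m)
  expect_named(gl, c("degree", "n_pairs", "rms_residual_um"))
  # JSON round trip
  f <- tempfile(fileext = ".json")
  write_calibration(m, f)
  m2 <- read_calibration(f)
  expect_equal(m2$coeffs_x, m$coeffs_x, tolerance = 1e-12)
  expect_equal(m2$degree, m$degree)
  unlink(f)
})
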