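#' Plan focal lesions at explicit sites
#'
#' Validates each requested site against the treatment and exclusion masks
#' and attaches per-site laser parameters. Masks are logical `(y, x)` matrices
#' on the en face OCT grid with pixel pitch `pitch_um`.
#'
#' @param sites Tibble/data frame with `x_um`, `y_um` (may be empty).
#' @param laser A [laser_params()] applied to every site.
#' @param treatment Logical matrix: allowed area (`NULL` = everywhere).
#' @param exclusion Logical matrix: forbidden pixels (`NULL` = none).
#' @param pitch_um µm per mask pixel.
#' @return A `lesion_plan`: tibble of sites (`site`, `x_um`, `y_um`,
#'   `power_mw`, `duration_ms`, `repeats`, `interval_ms`) with plan metadata
#'   attributes (`spot_diameter_um`, `overlap`, masks).
#' @export
plan_focal <- function(sites, laser, treatment = NULL, exclusion = NULL,
                       pitch_um = 3, spot_diameter_um = 50) {
  stopifnot(inherits(laser, "laser_params"))
  sites <- tibble::as_tibble(sites)
  if (nrow(sites)) {
    for (i in seq_len(nrow(sites))) {
      px <- mask_index(sites$x_um[i], sites$y_um[i], treatment %||% exclusion,
                       pitch_um)
      if (!is.null(exclusion) && isTRUE(exclusion[px[1], px[2]])) {
        stop(sprintf("site %d at (%.1f, %.1f) µm lies inside the exclusion mask",
                     i, sites$x_um[i], sites$y_um[i]))
      }
      if (!is.null(treatment) && !isTRUE(treatment[px[1], px[2]])) {
        stop(sprintf("site %d at (%.1f, %.1f) µm lies outside the treatment mask",
                     i, sites$x_um[i], sites$y_um[i]))
      }
    }
  }
  new_lesion_plan(sites, laser, spot_diameter_um, overlap = NA_real_,
                  pitch_um = pitch_um)
}

`%||%` <- function(a, b) if (!is.null(a)) a else b

mask_index <- function(x_um, y_um, mask, pitch_um) {
  if (is.null(mask)) return(c(1L, 1L))
  r <- pmin(pmax(ceiling(y_um / pitch_um), 1L), nrow(mask))
  c <- pmin(pmax(ceiling(x_um / pitch_um), 1L), ncol(mask))
  c(r, c)
}

new_lesion_plan <- function(sites, laser, spot_diameter_um, overlap,
                            pitch_um, treatment = NULL, exclusion = NULL) {
  plan <- tibble::tibble(
    site = seq_len(nrow(sites)),
    x_um = sites$x_um, y_um = sites$y_um,
    power_mw = laser$power_mw, duration_ms = laser$duration_ms,
    repeats = laser$repeats, interval_ms = laser$interval_ms
  )
  structure(plan,
            class = c("lesion_plan", class(plan)),
            spot_diameter_um = spot_diameter_um, overlap = overlap,
            pitch_um = pitch_um, treatment = treatment, exclusion = exclusion)
}

#' Quadrant preset of focal sites
#'
#' Twelve sites, three per retinal quadrant, aligned along the quadrant
#' diagonals between the default crossing vessels, at configurable
#' eccentricities from the field centre.
#'
#' @param fov_um Field of view `(x, y)` µm.
#' @param eccentricities_um Radial distances of the 3 lesions per quadrant.
#' @return Tibble `x_um`, `y_um`, `quadrant` with 12 rows.
#' @export
quadrant_sites <- function(fov_um, eccentricities_um = c(0.25, 0.35, 0.45) *
                             min(fov_um)) {
  ctr <- fov_um / 2
  dirs <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)) / sqrt(2)
  quads <- c("temporal-superior", "nasal-superior", "nasal-inferior",
             "temporal-inferior")
  rows <- list()
  k <- 1L
  for (q in 1:4) {
    for (e in eccentricities_um) {
      rows[[k]] <- tibble::tibble(x_um = ctr[1] + dirs[q, 1] * e,
                                  y_um = ctr[2] + dirs[q, 2] * e,
                                  quadrant = quads[q])
      k <- k + 1L
    }
  }
  dplyr::bind_rows(rows)
}

#' Plan an extended-area lesion patch by raster fill
#'
#' Lays a row-major raster grid with centre pitch
#' `(1 - overlap) * spot_diameter_um` anchored at the treatment-mask bounding
#' box (offset by one spot radius), and keeps a site iff its full spot disc
#' lies inside the treatment mask and intersects no exclusion pixel. The
#' default 50% overlap halves the pitch relative to the spot diameter.
#'
#' @param treatment,exclusion Logical `(y, x)` masks sharing geometry
#'   (`exclusion` may be `NULL`).
#' @param pitch_um µm per mask pixel.
#' @param spot_diameter_um Lesioning spot diameter on the retina, µm.
#' @param overlap Fractional spot overlap in `[0, 1)` (default 0.5).
#' @param laser A [laser_params()].
#' @param allow_partial If `TRUE`, a site is kept when its centre (not the
#'   full disc) is inside the treatment mask; exclusion is always enforced on
#'   the full disc.
#' @return A `lesion_plan` (possibly with zero sites, with a warning when the
#'   spot cannot fit).
#' @export
plan_patch <- function(treatment, exclusion = NULL, pitch_um,
                       spot_diameter_um = 50, overlap = 0.5, laser,
                       allow_partial = FALSE) {
  stopifnot(is.matrix(treatment), inherits(laser, "laser_params"),
            overlap >= 0, overlap < 1)
  if (!is.null(exclusion)) stopifnot(all(dim(exclusion) == dim(treatment)))
  pitch_s <- (1 - overlap) * spot_diameter_um
  radius <- spot_diameter_um / 2
  if (!any(treatment)) {
    warning("treatment mask is empty; empty plan")
    return(new_lesion_plan(tibble::tibble(x_um = numeric(), y_um = numeric()),
                           laser, spot_diameter_um, overlap, pitch_um,
                           treatment, exclusion))
  }
  idx <- which(treatment, arr.ind = TRUE)
  # bounding box in µm (pixel extents, not centres)
  x0 <- (min(idx[, 2]) - 1) * pitch_um; x1 <- max(idx[, 2]) * pitch_um
  y0 <- (min(idx[, 1]) - 1) * pitch_um; y1 <- max(idx[, 1]) * pitch_um
  if (x1 - x0 < spot_diameter_um || y1 - y0 < spot_diameter_um) {
    warning("spot larger than the treatment area; empty plan")
    xs <- ys <- numeric(0)
  } else {
    xs <- seq(x0 + radius, x1 - radius + 1e-9, by = pitch_s)
    ys <- seq(y0 + radius, y1 - radius + 1e-9, by = pitch_s)
  }
  keep <- list(); k <- 1L
  for (y in ys) {           # row-major: y outer, x inner
    for (x in xs) {
      if (site_admissible(x, y, radius, treatment, exclusion, pitch_um,
                          allow_partial)) {
        keep[[k]] <- c(x, y); k <- k + 1L
      }
    }
  }
  sites <- if (length(keep)) {
    m <- do.call(rbind, keep)
    tibble::tibble(x_um = m[, 1], y_um = m[, 2])
  } else tibble::tibble(x_um = numeric(), y_um = numeric())
  new_lesion_plan(sites, laser, spot_diameter_um, overlap, pitch_um,
                  treatment, exclusion)
}

# Full-disc admissibility on the pixel grid: every treatment pixel whose
# centre is within `radius` of the site must be TRUE, and no exclusion pixel
# centre within `radius` may be TRUE.
site_admissible <- function(x_um, y_um, radius, treatment, exclusion,
                            pitch_um, allow_partial = FALSE) {
  nr <- nrow(treatment); nc <- ncol(treatment)
  r0 <- max(1L, floor((y_um - radius) / pitch_um))
  r1 <- min(nr, ceiling((y_um + radius) / pitch_um) + 1L)
  c0 <- max(1L, floor((x_um - radius) / pitch_um))
  c1 <- min(nc, ceiling((x_um + radius) / pitch_um) + 1L)
  rr <- r0:r1; cc <- c0:c1
  yc <- (rr - 0.5) * pitch_um; xc <- (cc - 0.5) * pitch_um
  d2 <- outer((yc - y_um)^2, (xc - x_um)^2, `+`)
  inside <- d2 <= radius^2
  if (!any(inside)) return(FALSE)
  tr_sub <- treatment[rr, cc, drop = FALSE]
  if (allow_partial) {
    ctr <- mask_index(x_um, y_um, treatment, pitch_um)
    if (!isTRUE(treatment[ctr[1], ctr[2]])) return(FALSE)
  } else {
    # disc must not poke beyond the mask array either
    if ((y_um - radius) < 0 || (x_um - radius) < 0 ||
        (y_um + radius) > nr * pitch_um || (x_um + radius) > nc * pitch_um) {
      return(FALSE)
    }
    if (!all(tr_sub[inside])) return(FALSE)
  }
  if (!is.null(exclusion)) {
    ex_sub <- exclusion[rr, cc, drop = FALSE]
    if (any(ex_sub[inside])) return(FALSE)
  }
  TRUE
}

#' @export
print.lesion_plan <- function(x, ...) {
  cat(sprintf("<lesion_plan> %d sites, spot %.3g µm, overlap %s\n",
              nrow(x), attr(x, "spot_diameter_um"),
              ifelse(is.na(attr(x, "overlap")), "-",
                     sprintf("%.0f%%", 100 * attr(x, "overlap")))))
  NextMethod()
}

#' Compile a lesion plan into a calibrated firing schedule
#'
#' Each site is inverted through the calibration to command voltages; each of
#' its repeat pulses becomes one row, with onsets spaced
#' `duration + interval` within a site and a configurable settle delay
#' between sites.
#'
#' @param plan A `lesion_plan`.
#' @param model A `calibration_model`.
#' @param settle_ms Inter-site settle delay (default 1 ms).
#' @return Tibble `site`, `vx`, `vy`, `pulse`, `onset_ms`, `duration_ms`,
#'   `power_mw`.
#' @export
compile_schedule <- function(plan, model, settle_ms = 1) {
  stopifnot(inherits(plan, "lesion_plan"), inherits(model, "calibration_model"))
  if (nrow(plan) == 0L) {
    return(tibble::tibble(site = integer(), vx = numeric(), vy = numeric(),
                          pulse = integer(), onset_ms = numeric(),
                          duration_ms = numeric(), power_mw = numeric()))
  }
  volts <- tryCatch(
    invert_map(model, cbind(plan$x_um, plan$y_um)),
    error = function(e) stop(sprintf("site(s) outside the calibration image: %s",
                                     conditionMessage(e))))
  rows <- list()
  t0 <- 0
  k <- 1L
  for (i in seq_len(nrow(plan))) {
    for (p in seq_len(plan$repeats[i])) {
      rows[[k]] <- tibble::tibble(
        site = plan$site[i], vx = volts[i, 1], vy = volts[i, 2],
        pulse = p, onset_ms = t0,
        duration_ms = plan$duration_ms[i], power_mw = plan$power_mw[i])
      t0 <- t0 + plan$duration_ms[i] +
        if (p < plan$repeats[i]) plan$interval_ms[i] else settle_ms
      k <- k + 1L
    }
  }
  dplyr::bind_rows(rows)
}

#' Patch coverage report
#'
#' Fraction of treatment-mask pixels whose centre lies within one spot radius
#' of at least one planned site, plus the gap map of uncovered pixels.
#'
#' @param plan A `lesion_plan`.
#' @param treatment Logical mask (default: the plan's stored mask).
#' @param pitch_um µm per mask pixel (default: the plan's).
#' @return List: `coverage` (fraction), `gap_map` (logical matrix; TRUE =
#'   treatment pixel not covered).
#' @export
coverage_report <- function(plan, treatment = NULL, pitch_um = NULL) {
  treatment <- treatment %||% attr(plan, "treatment")
  pitch_um <- pitch_um %||% attr(plan, "pitch_um")
  stopifnot(is.matrix(treatment))
  radius <- attr(plan, "spot_diameter_um") / 2
  covered <- matrix(FALSE, nrow(treatment), ncol(treatment))
  if (nrow(plan)) {
    for (i in seq_len(nrow(plan))) {
      r0 <- max(1L, floor((plan$y_um[i] - radius) / pitch_um))
      r1 <- min(nrow(treatment), ceiling((plan$y_um[i] + radius) / pitch_um) + 1L)
      c0 <- max(1L, floor((plan$x_um[i] - radius) / pitch_um))
      c1 <- min(ncol(treatment), ceiling((plan$x_um[i] + radius) / pitch_um) + 1L)
      rr <- r0:r1; cc <- c0:c1
      d2 <- outer(((rr - 0.5) * pitch_um - plan$y_um[i])^2,
                  ((cc - 0.5) * pitch_um - plan$x_um[i])^2, `+`)
      covered[rr, cc] <- covered[rr, cc] | (d2 <= radius^2)
    }
  }
  gap <- treatment & !covered
  list(coverage = if (any(treatment)) sum(covered & treatment) / sum(treatment)
       else NA_real_,
       gap_map = gap)
}

#' Serialize / load a lesion plan as JSON
#' @param plan A `lesion_plan`.
#' @param path JSON path.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(
    list(kind = "lesion_plan",
         spot_diameter_um = attr(plan, "spot_diameter_um"),
         overlap = attr(plan, "overlap"),
         pitch_um = attr(plan, "pitch_um"),
         sites = as.data.frame(plan)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sites <- tibble::as_tibble(j$sites)
  if (nrow(sites) == 0) {
    sites <- tibble::tibble(x_um = numeric(), y_um = numeric())
  }
  laser <- if (nrow(sites)) {
    laser_params(sites$power_mw[1], sites$duration_ms[1],
                 sites$repeats[1], sites$interval_ms[1])
  } else laser_params(6, 200)
  plan <- new_lesion_plan(sites, laser, j$spot_diameter_um,
                          j$overlap %||% NA_real_, j$pitch_um)
  if (nrow(sites)) {
    plan$power_mw <- sites$power_mw
    plan$duration_ms <- sites$duration_ms
    plan$repeats <- sites$repeats
    plan$interval_ms <- sites$interval_ms
  }
  plan
}
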