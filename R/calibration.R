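#' Fit the galvanometer voltage-to-position calibration
#'
#' Lesion aiming is calibrated by firing at a paper grid target and measuring
#' the offsets between commanded and observed lesion positions on OCT; a 2D
#' polynomial mapping from scan-mirror command voltages to retinal positions
#' (µm) is then fit per output axis by least squares. Internally the fit uses
#' a shifted/scaled basis on \eqn{[-1,1]^2} for conditioning; reported
#' coefficient grids are in the natural monomial basis
#' (`coeffs[i+1, j+1]` multiplies \eqn{v_x^i v_y^j}).
#'
#' @param pairs Data frame with columns `vx`, `vy` (commanded volts) and
#'   `x_um`, `y_um` (observed retinal position, µm).
#' @param degree Polynomial degree (default 3; full tensor-product terms).
#' @return A `calibration_model`: degree, `coeffs_x`, `coeffs_y`,
#'   `rms_residual` (µm), `domain` (voltage bounding box), `n_pairs`.
#' @examples
#' v <- expand.grid(vx = seq(-1, 1, length.out = 7), vy = seq(-1, 1, length.out = 7))
#' pairs <- data.frame(v, x_um = 100 * v$vx, y_um = 100 * v$vy)
#' m <- fit_voltage_map(pairs, degree = 1)
#' m$rms_residual
#' @export
fit_voltage_map <- function(pairs, degree = 3L) {
  need <- c("vx", "vy", "x_um", "y_um")
  if (!all(need %in% names(pairs))) {
    stop("`pairs` needs columns vx, vy, x_um, y_um")
  }
  fit <- poly2d_fit(cbind(pairs$vx, pairs$vy), cbind(pairs$x_um, pairs$y_um),
                    degree)
  structure(
    list(degree = fit$degree, coeffs_x = fit$cx, coeffs_y = fit$cy,
         rms_residual = fit$rms_residual, domain = fit$domain,
         n_pairs = nrow(pairs)),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> degree %d, %d pairs, rms residual %.4g µm\n",
              x$degree, x$n_pairs, x$rms_residual))
  cat(sprintf("  voltage domain: vx [%.3g, %.3g], vy [%.3g, %.3g]\n",
              x$domain[1], x$domain[2], x$domain[3], x$domain[4]))
  invisible(x)
}

as_poly2d <- function(model) {
  list(degree = model$degree, cx = model$coeffs_x, cy = model$coeffs_y,
       domain = model$domain)
}

#' Map command voltages to retinal positions
#'
#' Forward polynomial evaluation. Voltages outside the fitted domain are still
#' evaluated, with a warning (extrapolation).
#'
#' @param model A `calibration_model` (or `unwarp_transform`).
#' @param voltage Length-2 vector `(vx, vy)` or an n x 2 matrix.
#' @return n x 2 matrix of positions (µm), columns `x_um`, `y_um`.
#' @export
map_voltage <- function(model, voltage) {
  v <- rbind(voltage)
  dom <- model$domain
  eps <- 1e-9
  outside <- v[, 1] < dom[1] - eps | v[, 1] > dom[2] + eps |
    v[, 2] < dom[3] - eps | v[, 2] > dom[4] + eps
  if (any(outside)) {
    warning(sprintf("%d voltage(s) outside the calibrated domain; extrapolating",
                    sum(outside)))
  }
  out <- poly2d_map(as_poly2d(model), v)
  colnames(out) <- c("x_um", "y_um")
  out
}

#' Invert the calibration: retinal target to command voltage
#'
#' Damped Newton iteration with the analytic polynomial Jacobian, seeded from
#' the best point of a dense forward-sampled grid over the voltage domain.
#'
#' @param model A `calibration_model`.
#' @param target Length-2 `(x_um, y_um)` or n x 2 matrix of targets (µm).
#' @param tol Convergence tolerance on the mapped position, µm (default 0.1).
#' @return n x 2 matrix of voltages, columns `vx`, `vy`.
#' @export
invert_map <- function(model, target, tol = 0.1) {
  out <- poly2d_invert(as_poly2d(model), rbind(target), tol = tol)
  colnames(out) <- c("vx", "vy")
  out
}

#' Held-out targeting-quality report
#'
#' Evaluates a fitted calibration on held-out (voltage, position) pairs and
#' reports per-point and summary residuals.
#'
#' @param model A `calibration_model`.
#' @param pairs Held-out pairs, same columns as [fit_voltage_map()].
#' @return A tibble with one row per pair (`vx`, `vy`, `x_um`, `y_um`,
#'   `x_pred`, `y_pred`, `residual_um`) carrying `rms_um` and `max_um`
#'   attributes; also printed by `glance()`.
#' @export
targeting_report <- function(model, pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("held-out pair set is empty")
  }
  pred <- suppressWarnings(map_voltage(model, cbind(pairs$vx, pairs$vy)))
  res <- sqrt((pred[, 1] - pairs$x_um)^2 + (pred[, 2] - pairs$y_um)^2)
  out <- tibble::tibble(
    vx = pairs$vx, vy = pairs$vy,
    x_um = pairs$x_um, y_um = pairs$y_um,
    x_pred = pred[, 1], y_pred = pred[, 2],
    residual_um = res
  )
  attr(out, "rms_um") <- sqrt(mean(res^2))
  attr(out, "max_um") <- max(res)
  out
}

#' Serialize / load a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path JSON file path.
#' @return `read_calibration` returns a `calibration_model`.
#' @export
write_calibration <- function(model, path) {
  jsonlite::write_json(
    list(kind = "calibration_model", degree = model$degree,
         coeffs_x = model$coeffs_x, coeffs_y = model$coeffs_y,
         rms_residual = model$rms_residual, domain = as.list(model$domain),
         n_pairs = model$n_pairs),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- j$degree
  structure(
    list(degree = as.integer(d),
         coeffs_x = as.matrix(j$coeffs_x),
         coeffs_y = as.matrix(j$coeffs_y),
         rms_residual = j$rms_residual,
         domain = unlist(j$domain), n_pairs = j$n_pairs),
    class = "calibration_model"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration model into a coefficient table
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @return Tibble with `axis`, `power_vx`, `power_vy`, `estimate`.
#' @method tidy calibration_model
#' @export
tidy.calibration_model <- function(x, ...) {
  d <- x$degree
  grid <- expand.grid(power_vx = 0:d, power_vy = 0:d)
  tibble::tibble(
    axis = rep(c("x", "y"), each = nrow(grid)),
    power_vx = rep(grid$power_vx, 2),
    power_vy = rep(grid$power_vy, 2),
    estimate = c(x$coeffs_x[cbind(grid$power_vx + 1, grid$power_vy + 1)],
                 x$coeffs_y[cbind(grid$power_vx + 1, grid$power_vy + 1)])
  )
}

#' One-row model summary
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @method glance calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(degree = x$degree, n_pairs = x$n_pairs,
                 rms_residual_um = x$rms_residual)
}
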