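# Tensor-product bivariate polynomial mapping R^2 -> R^2, the shared engine of
# the voltage-to-position calibration and the SLO->OCT unwarp. Fitting uses a
# shifted/scaled basis on [-1,1]^2 for conditioning; coefficients are stored
# (and exported) in the natural monomial basis: coeff grid C[(i+1),(j+1)]
# multiplies u^i * v^j.

poly2d_vander <- function(u, degree) {
  outer(u, 0:degree, `^`)
}

poly2d_eval_axis <- function(C, u, v) {
  d <- nrow(C) - 1L
  rowSums((poly2d_vander(u, d) %*% C) * poly2d_vander(v, d))
}

# derivative of the coefficient grid along rows (d/du) or cols (d/dv)
poly2d_deriv <- function(C, axis = c("u", "v")) {
  axis <- match.arg(axis)
  d <- nrow(C) - 1L
  D <- matrix(0, d + 1, d + 1)
  if (d == 0L) return(D)
  if (axis == "u") {
    D[1:d, ] <- C[2:(d + 1), ] * (1:d)
  } else {
    D[, 1:d] <- sweep(C[, 2:(d + 1), drop = FALSE], 2, 1:d, `*`)
  }
  D
}

# coefficients of ((u - c)/h)^i expanded in u^k, as columns of a matrix
shift_basis_matrix <- function(degree, c0, h) {
  B <- matrix(0, degree + 1, degree + 1)
  p <- 1  # polynomial "1"
  B[1, 1] <- 1
  base <- c(-c0 / h, 1 / h)
  for (i in seq_len(degree)) {
    p <- c(0, p) * base[2] + c(p, 0) * base[1]  # multiply by (u - c)/h
    B[seq_along(p), i + 1] <- p
  }
  B
}

# Least-squares fit of a degree-d tensor-product polynomial per output axis.
# inputs, outputs: n x 2 matrices. Returns natural-basis grids and rms.
poly2d_fit <- function(inputs, outputs, degree) {
  stopifnot(is.matrix(inputs), is.matrix(outputs),
            ncol(inputs) == 2, ncol(outputs) == 2)
  n <- nrow(inputs)
  p <- (degree + 1L)^2
  if (n < p) {
    stop(sprintf("underdetermined fit: degree %d needs >= %d point pairs per axis, got %d",
                 degree, p, n))
  }
  rng1 <- range(inputs[, 1]); rng2 <- range(inputs[, 2])
  if (diff(rng1) <= 0 || diff(rng2) <= 0) {
    stop("degenerate (collinear) input geometry: inputs span a line, not a 2D domain")
  }
  c1 <- mean(rng1); h1 <- diff(rng1) / 2
  c2 <- mean(rng2); h2 <- diff(rng2) / 2
  s1 <- (inputs[, 1] - c1) / h1
  s2 <- (inputs[, 2] - c2) / h2
  V1 <- poly2d_vander(s1, degree)
  V2 <- poly2d_vander(s2, degree)
  X <- matrix(0, n, p)
  k <- 1L
  for (j in 0:degree) {
    for (i in 0:degree) {
      X[, k] <- V1[, i + 1] * V2[, j + 1]
      k <- k + 1L
    }
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    stop(sprintf("rank-deficient design (rank %d < %d): grid points are collinear or degenerate",
                 qrX$rank, p))
  }
  coefs <- qr.coef(qrX, outputs)
  fitted <- X %*% coefs
  res <- outputs - fitted
  rms <- sqrt(mean(res^2))  # pooled per-axis residual rms
  B1 <- shift_basis_matrix(degree, c1, h1)
  B2 <- shift_basis_matrix(degree, c2, h2)
  to_nat <- function(cs) B1 %*% matrix(cs, degree + 1, degree + 1) %*% t(B2)
  list(degree = as.integer(degree),
       cx = to_nat(coefs[, 1]), cy = to_nat(coefs[, 2]),
       rms_residual = rms,
       residuals = res,
       domain = c(u_min = rng1[1], u_max = rng1[2],
                  v_min = rng2[1], v_max = rng2[2]))
}

poly2d_map <- function(model, pts) {
  pts <- rbind(pts)
  cbind(poly2d_eval_axis(model$cx, pts[, 1], pts[, 2]),
        poly2d_eval_axis(model$cy, pts[, 1], pts[, 2]))
}

# Damped-Newton inversion of the forward map, vectorized over targets.
# Seeds from the best point of a dense forward-sampled grid over the domain.
poly2d_invert <- function(model, targets, tol = 0.1, max_iter = 100L,
                          grid_n = 50L, outside = c("error", "na")) {
  outside <- match.arg(outside)
  targets <- rbind(targets)
  dom <- model$domain
  gu <- seq(dom[1], dom[2], length.out = grid_n)
  gv <- seq(dom[3], dom[4], length.out = grid_n)
  grid <- cbind(rep(gu, times = grid_n), rep(gv, each = grid_n))
  fw <- poly2d_map(model, grid)
  # image scale for the outside-domain check
  span <- sqrt(diff(range(fw[, 1]))^2 + diff(range(fw[, 2]))^2)
  m <- nrow(targets)
  v <- matrix(0, m, 2)
  best_d <- numeric(m)
  for (i in seq_len(m)) {
    d2 <- (fw[, 1] - targets[i, 1])^2 + (fw[, 2] - targets[i, 2])^2
    j <- which.min(d2)
    v[i, ] <- grid[j, ]
    best_d[i] <- sqrt(d2[j])
  }
  bad <- best_d > 3 * span / grid_n + 1e-9
  if (any(bad)) {
    if (outside == "error") {
      stop(sprintf("%d target(s) outside the calibrated image (nearest mapped point %.3g away)",
                   sum(bad), min(best_d[bad])))
    }
    if (all(bad)) {
      v[] <- NA_real_
      return(v)
    }
    v_ok <- poly2d_invert(model, targets[!bad, , drop = FALSE], tol = tol,
                          max_iter = max_iter, grid_n = grid_n)
    v[] <- NA_real_
    v[!bad, ] <- v_ok
    return(v)
  }
  dxu <- poly2d_deriv(model$cx, "u"); dxv <- poly2d_deriv(model$cx, "v")
  dyu <- poly2d_deriv(model$cy, "u"); dyv <- poly2d_deriv(model$cy, "v")
  resid_of <- function(vv) poly2d_map(model, vv) - targets
  Fv <- resid_of(v)
  rn <- sqrt(rowSums(Fv^2))
  for (it in seq_len(max_iter)) {
    if (all(rn <= tol * 1e-3 + .Machine$double.eps) || all(rn <= tol & it > 1)) break
    j11 <- poly2d_eval_axis(dxu, v[, 1], v[, 2])
    j12 <- poly2d_eval_axis(dxv, v[, 1], v[, 2])
    j21 <- poly2d_eval_axis(dyu, v[, 1], v[, 2])
    j22 <- poly2d_eval_axis(dyv, v[, 1], v[, 2])
    det <- j11 * j22 - j12 * j21
    det[abs(det) < 1e-300] <- 1e-300
    step <- cbind((j22 * Fv[, 1] - j12 * Fv[, 2]) / det,
                  (-j21 * Fv[, 1] + j11 * Fv[, 2]) / det)
    lambda <- rep(1, m)
    for (damp in 1:6) {
      v_new <- v - step * lambda
      F_new <- resid_of(v_new)
      rn_new <- sqrt(rowSums(F_new^2))
      worse <- rn_new > rn & rn > tol * 1e-3
      if (!any(worse)) break
      lambda[worse] <- lambda[worse] / 2
    }
    v <- v - step * lambda
    Fv <- resid_of(v)
    rn <- sqrt(rowSums(Fv^2))
  }
  if (any(rn > tol)) {
    stop(sprintf("Newton inversion did not converge for %d target(s); worst residual %.3g (tol %.3g)",
                 sum(rn > tol), max(rn), tol))
  }
  v
}
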