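# Shared fixtures: small phantoms and polynomial grids used across tests.

no_vessels <- function() {
  tibble::tibble(orientation = character(), position_um = numeric(),
                 radius_um = numeric())
}

# compact retina phantom: 288 µm depth at 3 µm pitch holds the layer model
small_phantom <- function(y = 24, x = 32, z = 96, repeats = 3, seed = 1,
                          vessels = NULL, curvature_um = 20, ...) {
  phantom_params(shape = c(y = y, x = x, z = z),
                 pitch = c(x = 6, y = 6, z = 3),
                 repeats = repeats, curvature_um = curvature_um,
                 vessels = vessels, seed = seed, ...)
}

# independent brute-force patch-planning oracle shared by the planner and
# acceptance tests: rasters the candidate grid and tests each disc directly
oracle_patch_sites <- function(tr, ex, pitch, spot, ov) {
  rad <- spot / 2; step <- (1 - ov) * spot
  idx <- which(tr, arr.ind = TRUE)
  if (!nrow(idx)) return(matrix(numeric(0), 0, 2))
  x0 <- (min(idx[, 2]) - 1) * pitch; x1 <- max(idx[, 2]) * pitch
  y0 <- (min(idx[, 1]) - 1) * pitch; y1 <- max(idx[, 1]) * pitch
  if (x1 - x0 < spot || y1 - y0 < spot) return(matrix(numeric(0), 0, 2))
  xs <- seq(x0 + rad, x1 - rad + 1e-9, by = step)
  ys <- seq(y0 + rad, y1 - rad + 1e-9, by = step)
  cy <- (seq_len(nrow(tr)) - 0.5) * pitch
  cx <- (seq_len(ncol(tr)) - 0.5) * pitch
  keep <- NULL
  for (y in ys) for (x in xs) {
    if (y - rad < 0 || x - rad < 0 ||
        y + rad > nrow(tr) * pitch || x + rad > ncol(tr) * pitch) next
    ins <- outer((cy - y)^2, (cx - x)^2, `+`) <= rad^2
    if (!all(tr[ins])) next
    if (!is.null(ex) && any(ex[ins])) next
    keep <- rbind(keep, c(x, y))
  }
  if (is.null(keep)) matrix(numeric(0), 0, 2) else keep
}

# small SLO settings (frames/geometry scaled down; rates as acquired)
small_slo <- function(size = 128L, n_frames = 20L) {
  list(size = size, n_frames = n_frames, frame_rate = 7.8,
       tdtomato_level = 0.6, gfp_baseline = 0.12,
       texture_amp = 0.15, texture_scale_um = 100, noise_sd = 0.02)
}

grid7 <- function() {
  expand.grid(vx = seq(-1, 1, length.out = 7),
              vy = seq(-1, 1, length.out = 7))
}

# deterministic quadratic scan distortion used in several tests
quad_pairs <- function() {
  g <- grid7()
  data.frame(g,
             x_um = 95 * g$vx + 4 * g$vx^2 + 1.5 * g$vx * g$vy,
             y_um = 98 * g$vy + 3 * g$vy^2 + 2 * g$vx * g$vy)
}

quad_truth_cx <- function() {
  m <- matrix(0, 3, 3); m[2, 1] <- 95; m[3, 1] <- 4; m[2, 2] <- 1.5; m
}
quad_truth_cy <- function() {
  m <- matrix(0, 3, 3); m[1, 2] <- 98; m[1, 3] <- 3; m[2, 2] <- 2; m
}

rand_f32_array <- function(dim, scale = 10) {
  retlesion:::as_float32(array(runif(prod(dim)) * scale, dim))
}
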