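# Shared raster helpers. Image matrices are (row = y, col = x); pixel centres
# sit at (i - 0.5) * pitch in micrometres; indices are 1-based.

# Vectorized bilinear sampling at fractional (row, col) positions.
# Out-of-domain queries return `fill`.
bilinear_sample <- function(img, row, col, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  ok <- r0 >= 1 & c0 >= 1 & (r0 + 1) <= nr & (c0 + 1) <= nc
  ok[is.na(ok)] <- FALSE
  # exact border pixels (no neighbour needed)
  edge <- !ok & row >= 1 & row <= nr & col >= 1 & col <= nc & fr == 0 & fc == 0
  edge[is.na(edge)] <- FALSE
  out <- rep(fill, length(row))
  if (any(ok)) {
    i00 <- (c0[ok] - 1) * nr + r0[ok]
    v00 <- img[i00]; v10 <- img[i00 + 1L]
    v01 <- img[i00 + nr]; v11 <- img[i00 + nr + 1L]
    out[ok] <- v00 * (1 - fr[ok]) * (1 - fc[ok]) + v10 * fr[ok] * (1 - fc[ok]) +
      v01 * (1 - fr[ok]) * fc[ok] + v11 * fr[ok] * fc[ok]
  }
  if (any(edge)) out[edge] <- img[cbind(row[edge], col[edge])]
  out
}

# Rigid translation of an image by (dy, dx) pixels (content moves by +dy rows,
# +dx cols); bilinear, `fill` outside.
shift_image <- function(img, dy, dx, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  grid_r <- matrix(seq_len(nr), nr, nc) - dy
  grid_c <- matrix(rep(seq_len(nc), each = nr), nr, nc) - dx
  matrix(bilinear_sample(img, as.vector(grid_r), as.vector(grid_c), fill = fill),
         nr, nc)
}

# Separable Gaussian smoothing (reflecting borders) used for phantom textures
# and landmark detection.
gauss_smooth <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - rev(seq_len(half)))
    idx <- pmin(pmax(idx, 1L), n)
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[j:(j + n - 1), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

# Phase correlation between equally sized images: returns the translation
# (dy, dx) that maps `b` onto `a` (i.e. shift_image(b, dy, dx) ~ a), with
# sub-pixel parabolic peak refinement, plus the correlation peak height.
# Images are mean-subtracted and Hann-windowed, and the spectral whitening is
# regularized, so border zero-fill does not destabilize the peak.
phase_correlate <- function(a, b, whiten_reg = 0.1) {
  stopifnot(all(dim(a) == dim(b)))
  nr <- nrow(a); nc <- ncol(a)
  w <- outer(0.5 - 0.5 * cos(2 * pi * (0:(nr - 1)) / (nr - 1)),
             0.5 - 0.5 * cos(2 * pi * (0:(nc - 1)) / (nc - 1)))
  fa <- stats::fft((a - mean(a)) * w)
  fb <- stats::fft((b - mean(b)) * w)
  cross <- fa * Conj(fb)
  mag <- Mod(cross)
  r <- Re(stats::fft(cross / (mag + whiten_reg * mean(mag) + 1e-300),
                     inverse = TRUE)) / (nr * nc)
  pk <- which.max(r)
  pr <- ((pk - 1) %% nr) + 1
  pc <- ((pk - 1) %/% nr) + 1
  # parabolic refinement on the circular grid
  refine <- function(vm1, v0, vp1) {
    den <- vm1 - 2 * v0 + vp1
    if (abs(den) < 1e-12) 0 else 0.5 * (vm1 - vp1) / den
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  dr <- refine(r[wrap(pr - 1, nr), pc], r[pr, pc], r[wrap(pr + 1, nr), pc])
  dc <- refine(r[pr, wrap(pc - 1, nc)], r[pr, pc], r[pr, wrap(pc + 1, nc)])
  dy <- (pr - 1) + dr; if (dy > nr / 2) dy <- dy - nr
  dx <- (pc - 1) + dc; if (dx > nc / 2) dx <- dx - nc
  # the peak height is high for a clean translation and degrades with noise
  # or structural change; used directly as the frame-quality score
  list(dy = dy, dx = dx, peak = r[pr, pc])
}

# Translation estimate with exact-integer snapping: when the rounded shift
# explains `b` essentially as well (overlap SSD within a small margin, since
# sub-pixel interpolation spuriously lowers noise-dominated SSD), prefer it,
# so constructed integer displacements are recovered exactly and aligned
# noisy frames are not micro-shifted. `presmooth` (px) regularizes the
# estimation on noisy frames without affecting the data being averaged.
estimate_shift <- function(a, b, presmooth = 1.5, snap_margin = 1.05) {
  if (presmooth > 0) {
    pc <- phase_correlate(gauss_smooth(a, presmooth),
                          gauss_smooth(b, presmooth))
  } else {
    pc <- phase_correlate(a, b)
  }
  est <- c(pc$dy, pc$dx)
  snap <- round(est)
  if (any(est != snap)) {
    ssd_of <- function(s) {
      bs <- shift_image(b, s[1], s[2], fill = NA_real_)
      ok <- !is.na(bs)
      mean((bs[ok] - a[ok])^2)
    }
    if (ssd_of(snap) <= snap_margin * ssd_of(est)) est <- snap
  }
  list(dy = est[1], dx = est[2], peak = pc$peak)
}

# 2D median filter with an odd square window (edge-replicated). Used to
# regularize detected surfaces.
median_filter2 <- function(m, window = 3L) {
  if (window <= 1L) return(m)
  stopifnot(window %% 2L == 1L)
  half <- (window - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ridx <- pmin(pmax(seq(1L - half, nr + half), 1L), nr)
  cidx <- pmin(pmax(seq(1L - half, nc + half), 1L), nc)
  mp <- m[ridx, cidx, drop = FALSE]
  stack <- matrix(0, nr * nc, window * window)
  k <- 1L
  for (dc in 0:(window - 1L)) {
    for (dr in 0:(window - 1L)) {
      stack[, k] <- as.vector(mp[(1 + dr):(nr + dr), (1 + dc):(nc + dc)])
      k <- k + 1L
    }
  }
  matrix(apply(stack, 1, stats::median), nr, nc)
}

# Connected components of a logical array (2D: 8-connectivity,
# 3D: 26-connectivity) via an offset edge list + igraph. Returns an integer
# label array (0 = background).
label_components <- function(mask) {
  stopifnot(is.logical(mask))
  d <- dim(mask)
  if (is.null(d)) stop("mask must be a matrix or 3D array")
  nd <- length(d)
  idx <- which(mask)
  if (length(idx) == 0L) return(array(0L, d))
  pos <- arrayInd(idx, d)
  key <- function(p) {
    k <- p[, 1]
    mult <- d[1]
    for (j in 2:nd) { k <- k + (p[, j] - 1) * mult; mult <- mult * d[j] }
    k
  }
  inside <- rep(TRUE, length(idx))
  lookup <- integer(prod(d))
  lookup[idx] <- seq_along(idx)
  offsets <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  # half the offsets suffice (undirected edges)
  keep <- apply(offsets, 1, function(o) {
    nz <- which(o != 0)[1]
    o[nz] > 0
  })
  offsets <- offsets[keep, , drop = FALSE]
  edges <- NULL
  for (k in seq_len(nrow(offsets))) {
    q <- sweep(pos, 2, offsets[k, ], "+")
    ok <- rep(TRUE, nrow(q))
    for (j in seq_len(nd)) ok <- ok & q[, j] >= 1 & q[, j] <= d[j]
    if (!any(ok)) next
    qk <- key(q[ok, , drop = FALSE])
    nb <- lookup[qk]
    hit <- nb > 0L
    if (any(hit)) {
      edges <- rbind(edges, cbind(which(ok)[hit], nb[hit]))
    }
  }
  g <- igraph::graph_from_edgelist(
    rbind(matrix(rep(seq_along(idx), 2), ncol = 2), edges), directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(idx)]
  out <- array(0L, d)
  out[idx] <- as.integer(comp)
  # relabel 1..k in first-appearance order for determinism
  u <- unique(out[idx])
  relab <- integer(max(u)); relab[u] <- seq_along(u)
  out[idx] <- relab[out[idx]]
  out
}
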