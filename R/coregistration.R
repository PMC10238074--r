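#' Detect grid-target landmarks with sub-pixel centroids
#'
#' Finds blob-like grid nodes as local maxima of a lightly smoothed image that
#' stand at least `min_prominence` above the background (median) level, then
#' refines each to an intensity-weighted centroid within a window of one
#' expected spacing. Points are returned row-major (sorted by spacing-rounded
#' row, then column).
#'
#' @param image Numeric matrix.
#' @param expected_spacing_px Approximate node spacing in pixels.
#' @param min_prominence Required peak height above background, as a fraction
#'   of the image's peak-to-background range (default 0.3).
#' @return Tibble `x_px`, `y_px` (sub-pixel, pixel-centre convention where
#'   pixel (1,1) is at 1.0), one row per landmark. Errors with fewer than 6.
#' @export
detect_grid_landmarks <- function(image, expected_spacing_px,
                                  min_prominence = 0.3) {
  stopifnot(is.matrix(image), expected_spacing_px > 1)
  sm <- gauss_smooth(image, 1)
  bg <- stats::median(sm)
  thr <- bg + min_prominence * (max(sm) - bg)
  half <- max(2L, round(expected_spacing_px / 2) - 1L)
  nr <- nrow(sm); nc <- ncol(sm)
  cand <- which(sm > thr)
  peaks <- NULL
  for (i in cand) {
    r <- ((i - 1) %% nr) + 1
    c <- ((i - 1) %/% nr) + 1
    r0 <- max(1, r - half); r1 <- min(nr, r + half)
    c0 <- max(1, c - half); c1 <- min(nc, c + half)
    if (sm[r, c] >= max(sm[r0:r1, c0:c1])) peaks <- rbind(peaks, c(r, c))
  }
  if (is.null(peaks) || nrow(peaks) < 6L) {
    stop(sprintf("found %d grid landmarks; at least 6 required",
                 if (is.null(peaks)) 0L else nrow(peaks)))
  }
  # deduplicate plateau peaks closer than half a spacing
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    d <- sqrt((peaks[, 1] - peaks[i, 1])^2 + (peaks[, 2] - peaks[i, 2])^2)
    dup <- which(d < expected_spacing_px / 2 & seq_len(nrow(peaks)) > i)
    keep[dup] <- FALSE
  }
  peaks <- peaks[keep, , drop = FALSE]
  # centroid window: a quarter spacing captures the spot core while keeping
  # rectified-noise bias negligible; weights are thresholded at 10% of the
  # local peak above background
  win <- max(3L, round(expected_spacing_px / 4))
  cent <- t(apply(peaks, 1, function(p) {
    r0 <- max(1, p[1] - win); r1 <- min(nr, p[1] + win)
    c0 <- max(1, p[2] - win); c1 <- min(nc, p[2] + win)
    sub <- image[r0:r1, c0:c1]
    w <- pmax(sub - bg - 0.1 * (max(sub) - bg), 0)
    rr <- matrix(r0:r1, r1 - r0 + 1, c1 - c0 + 1)
    cc <- matrix(c0:c1, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
    c(sum(rr * w) / sum(w), sum(cc * w) / sum(w))
  }))
  ord <- order(round(cent[, 1] / expected_spacing_px), cent[, 2])
  tibble::tibble(x_px = cent[ord, 2], y_px = cent[ord, 1])
}

# Similarity (scale/rotation/translation) transform from >= 2 point pairs,
# least squares via complex regression.
fit_similarity <- function(a, b) {
  za <- complex(real = a[, 1], imaginary = a[, 2])
  zb <- complex(real = b[, 1], imaginary = b[, 2])
  za_c <- za - mean(za); zb_c <- zb - mean(zb)
  s <- sum(Conj(za_c) * zb_c) / sum(Mod(za_c)^2)
  t <- mean(zb) - s * mean(za)
  function(p) {
    z <- s * complex(real = p[, 1], imaginary = p[, 2]) + t
    cbind(Re(z), Im(z))
  }
}

# extreme corner points (min/max of x+y and x-y)
corner_points <- function(p) {
  s <- p[, 1] + p[, 2]; d <- p[, 1] - p[, 2]
  p[c(which.min(s), which.max(s), which.min(d), which.max(d)), , drop = FALSE]
}

#' Match two landmark sets
#'
#' A coarse similarity pre-alignment seeded from the 4 extreme corner points
#' of each set (with leave-one-out trials so a single spurious extreme point
#' cannot corrupt the seed, keeping the trial with the most inliers, then a
#' refit on those inliers) is followed by mutual-nearest-neighbour matching;
#' unmatched points are dropped with a reported count.
#'
#' @param points_a,points_b Tibbles with `x_px`/`y_px` (or `x_um`/`y_um`)
#'   columns, or 2-column matrices.
#' @param max_dist Optional gate on the post-alignment match distance
#'   (default: half the median nearest-neighbour spacing of set B).
#' @return Tibble `index_a`, `index_b`, `dist`; attribute `n_dropped`.
#' @export
match_landmarks <- function(points_a, points_b, max_dist = NULL) {
  as_mat <- function(p) {
    if (is.matrix(p)) return(p)
    cols <- intersect(c("x_px", "x_um"), names(p))
    cbind(p[[cols[1]]], p[[sub("x", "y", cols[1])]])
  }
  a <- as_mat(points_a); b <- as_mat(points_b)
  if (is.null(max_dist)) {
    spacing <- stats::median(sqrt(apply(
      outer(b[, 1], b[, 1], `-`)^2 + outer(b[, 2], b[, 2], `-`)^2 +
        diag(Inf, nrow(b)), 1, min)))
    max_dist <- spacing / 2
  }
  ca <- corner_points(a); cb <- corner_points(b)
  mutual_match <- function(tr) {
    a_al <- tr(a)
    dmat <- outer(a_al[, 1], b[, 1], `-`)^2 + outer(a_al[, 2], b[, 2], `-`)^2
    nn_ab <- apply(dmat, 1, which.min)
    nn_ba <- apply(dmat, 2, which.min)
    mutual <- which(nn_ba[nn_ab] == seq_len(nrow(a)))
    dist <- sqrt(dmat[cbind(mutual, nn_ab[mutual])])
    ok <- dist <= max_dist
    list(ia = mutual[ok], ib = nn_ab[mutual][ok], dist = dist[ok])
  }
  # corner-seed trials: all 4 corner roles, each leave-one-out triple, and
  # every corner pair (a similarity is already determined by 2 pairs), so up
  # to two spurious extreme points cannot corrupt every seed
  trials <- c(list(seq_len(4)),
              lapply(1:4, function(i) setdiff(1:4, i)),
              utils::combn(4, 2, simplify = FALSE))
  best <- NULL
  for (tri in trials) {
    m <- mutual_match(fit_similarity(ca[tri, , drop = FALSE],
                                     cb[tri, , drop = FALSE]))
    if (is.null(best) || length(m$ia) > length(best$ia)) best <- m
  }
  # refit the similarity on the inlier correspondences and re-match
  if (length(best$ia) >= 2) {
    m2 <- mutual_match(fit_similarity(a[best$ia, , drop = FALSE],
                                      b[best$ib, , drop = FALSE]))
    if (length(m2$ia) >= length(best$ia)) best <- m2
  }
  out <- tibble::tibble(index_a = best$ia, index_b = best$ib,
                        dist = best$dist)
  attr(out, "n_dropped") <- (nrow(a) - nrow(out))
  out
}

#' Fit the SLO-to-OCT polynomial unwarp
#'
#' Least-squares tensor-product polynomial mapping SLO pixel coordinates to
#' OCT en face coordinates (µm), the canonical frame in which lesion plans
#' live. Same structure, conditioning and error behaviour as
#' [fit_voltage_map()].
#'
#' @param correspondences Tibble with `x_slo_px`, `y_slo_px`, `x_oct_um`,
#'   `y_oct_um`.
#' @param degree Polynomial degree (default 3).
#' @return An `unwarp_transform` (also a valid input to [map_voltage()] /
#'   [invert_map()] style evaluation via [apply_unwarp()]).
#' @export
fit_unwarp <- function(correspondences, degree = 3L) {
  need <- c("x_slo_px", "y_slo_px", "x_oct_um", "y_oct_um")
  if (!all(need %in% names(correspondences))) {
    stop("`correspondences` needs columns x_slo_px, y_slo_px, x_oct_um, y_oct_um")
  }
  fit <- poly2d_fit(cbind(correspondences$x_slo_px, correspondences$y_slo_px),
                    cbind(correspondences$x_oct_um, correspondences$y_oct_um),
                    degree)
  structure(
    list(degree = fit$degree, coeffs_x = fit$cx, coeffs_y = fit$cy,
         rms_residual = fit$rms_residual, domain = fit$domain,
         source = "slo_px", target = "oct_um",
         n_pairs = nrow(correspondences)),
    class = c("unwarp_transform", "calibration_model")
  )
}

#' @export
print.unwarp_transform <- function(x, ...) {
  cat(sprintf("<unwarp_transform> SLO px -> OCT µm, degree %d, rms %.4g µm\n",
              x$degree, x$rms_residual))
  invisible(x)
}

#' Evaluate an unwarp transform at SLO pixel positions
#' @param transform An `unwarp_transform`.
#' @param pts n x 2 matrix / length-2 vector of `(x_slo_px, y_slo_px)`.
#' @return n x 2 matrix of OCT positions (µm).
#' @export
map_unwarp <- function(transform, pts) {
  out <- poly2d_map(as_poly2d(transform), rbind(pts))
  colnames(out) <- c("x_um", "y_um")
  out
}

#' Resample an SLO image onto the OCT en face grid
#'
#' Inverse-mapping resampling: every output (OCT-grid) pixel centre is mapped
#' back to SLO pixel coordinates by Newton inversion of the stored SLO-to-OCT
#' polynomial, then bilinearly interpolated. Pixels that land outside the SLO
#' frame are set to `NaN` and reported as `1 - coverage`.
#'
#' @param image SLO image matrix (pixel-centre coordinates, pixel (1,1) at 1).
#' @param transform An `unwarp_transform` (SLO px to OCT µm).
#' @param out_nx,out_ny Output grid size (pixels).
#' @param out_pitch Output pixel pitch, µm.
#' @param out_origin Length-2 µm position of the output pixel (1,1) centre.
#' @return Matrix `(out_ny, out_nx)` with attribute `coverage` (fraction of
#'   output pixels mapped inside the input frame).
#' @export
apply_unwarp <- function(image, transform, out_nx, out_ny, out_pitch,
                         out_origin = c(out_pitch / 2, out_pitch / 2)) {
  xs <- out_origin[1] + (seq_len(out_nx) - 1) * out_pitch
  ys <- out_origin[2] + (seq_len(out_ny) - 1) * out_pitch
  targets <- cbind(rep(xs, each = out_ny), rep(ys, times = out_nx))
  src <- poly2d_invert(as_poly2d(transform), targets, tol = 1e-3,
                       outside = "na")
  vals <- bilinear_sample(image, src[, 2], src[, 1], fill = NaN)
  vals[is.na(src[, 1])] <- NaN
  out <- matrix(vals, out_ny, out_nx)
  attr(out, "coverage") <- mean(!is.nan(vals))
  attr(out, "pitch") <- out_pitch
  out
}

#' End-to-end grid co-registration
#'
#' Detects landmarks in OCT and SLO grid images, matches them, and fits the
#' SLO-to-OCT unwarp.
#'
#' @param oct_image,slo_image Grid-target images.
#' @param oct_pitch µm per OCT pixel; OCT µm coordinates are taken about the
#'   image centre (`oct_center_px`).
#' @param oct_center_px Pixel position of the optical axis in the OCT image.
#' @param expected_spacing_px Approximate node spacing (pixels) in each image.
#' @param degree Unwarp polynomial degree.
#' @return List: `transform`, `correspondences`, `landmarks_oct`,
#'   `landmarks_slo`.
#' @export
coregister_grids <- function(oct_image, slo_image, oct_pitch, oct_center_px,
                             expected_spacing_px, degree = 3L) {
  lm_oct <- detect_grid_landmarks(oct_image, expected_spacing_px)
  lm_slo <- detect_grid_landmarks(slo_image, expected_spacing_px)
  m <- match_landmarks(lm_slo, lm_oct)
  corr <- tibble::tibble(
    x_slo_px = lm_slo$x_px[m$index_a],
    y_slo_px = lm_slo$y_px[m$index_a],
    x_oct_um = (lm_oct$x_px[m$index_b] - oct_center_px) * oct_pitch,
    y_oct_um = (lm_oct$y_px[m$index_b] - oct_center_px) * oct_pitch
  )
  tr <- fit_unwarp(corr, degree = degree)
  list(transform = tr, correspondences = corr,
       landmarks_oct = lm_oct, landmarks_slo = lm_slo)
}
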