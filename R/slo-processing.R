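#' Reject SLO frames with respiratory-motion artifacts
#'
#' Each frame is scored by the phase-correlation peak against the per-pixel
#' median frame (red channel); a frame is rejected when its score falls below
#' `median(scores) - 3 * MAD(scores)` or when its estimated displacement
#' exceeds `max_disp_px`. Both thresholds are configurable.
#'
#' @param seq An [slo_sequence()] with at least 5 frames.
#' @param mad_k Robust-gate width in MADs (default 3).
#' @param max_disp_px Maximum tolerated displacement, pixels (default 10).
#' @return List: `kept`, `rejected` (frame indices) and `scores` tibble
#'   (`frame`, `score`, `disp_px`, `kept`).
#' @export
reject_motion_frames <- function(seq, mad_k = 3, max_disp_px = 10) {
  stopifnot(inherits(seq, "slo_sequence"))
  nt <- dim(seq$frames)[1]
  if (nt < 5L) stop("need at least 5 frames for motion QC")
  red <- seq$frames[, 1, , ]
  ref <- apply(red, c(2, 3), stats::median)
  score <- disp <- numeric(nt)
  for (t in seq_len(nt)) {
    pc <- estimate_shift(ref, red[t, , ])
    score[t] <- pc$peak
    disp[t] <- sqrt(pc$dy^2 + pc$dx^2)
  }
  med <- stats::median(score)
  mad <- stats::mad(score)
  keep <- score >= med - mad_k * mad & disp <= max_disp_px
  if (!any(keep)) stop("all frames rejected by motion QC")
  tab <- tibble::tibble(frame = seq_len(nt), score = score, disp_px = disp,
                        kept = keep)
  list(kept = which(keep), rejected = which(!keep), scores = tab)
}

#' Register and average the kept SLO frames
#'
#' Rigid translation per frame is estimated on the red channel by phase
#' correlation with parabolic sub-pixel refinement against the first kept
#' frame; the same shift is applied to both channels (bilinear) and the
#' aligned frames are averaged with an NaN-aware masked mean at the borders.
#'
#' @param seq An [slo_sequence()].
#' @param kept Frame indices to use (default: all).
#' @return List: `red`, `green` (averaged matrices), `shifts` tibble
#'   (`frame`, `dy_px`, `dx_px`).
#' @export
register_and_average <- function(seq, kept = NULL) {
  stopifnot(inherits(seq, "slo_sequence"))
  nt <- dim(seq$frames)[1]
  if (is.null(kept)) kept <- seq_len(nt)
  stopifnot(length(kept) >= 1, all(kept >= 1 & kept <= nt))
  if (length(kept) == 1L) {
    return(list(red = seq$frames[kept, 1, , ],
                green = seq$frames[kept, 2, , ],
                shifts = tibble::tibble(frame = kept, dy_px = 0, dx_px = 0)))
  }
  ref <- seq$frames[kept[1], 1, , ]
  dys <- dxs <- numeric(length(kept))
  accum_r <- accum_g <- matrix(0, dim(seq$frames)[3], dim(seq$frames)[4])
  count <- matrix(0, dim(seq$frames)[3], dim(seq$frames)[4])
  for (i in seq_along(kept)) {
    fr_r <- seq$frames[kept[i], 1, , ]
    fr_g <- seq$frames[kept[i], 2, , ]
    pc <- estimate_shift(ref, fr_r)
    dys[i] <- pc$dy; dxs[i] <- pc$dx
    ar <- shift_image(fr_r, pc$dy, pc$dx, fill = NA_real_)
    ag <- shift_image(fr_g, pc$dy, pc$dx, fill = NA_real_)
    ok <- !is.na(ar)
    accum_r[ok] <- accum_r[ok] + ar[ok]
    accum_g[ok] <- accum_g[ok] + ag[ok]
    count[ok] <- count[ok] + 1
  }
  red_avg <- accum_r / count
  green_avg <- accum_g / count
  red_avg[count == 0] <- NA_real_
  green_avg[count == 0] <- NA_real_
  list(red = red_avg, green = green_avg,
       shifts = tibble::tibble(frame = kept, dy_px = dys, dx_px = dxs))
}

#' Quantify tdTomato photoconversion between two averaged acquisitions
#'
#' Computes the bounded conversion index \eqn{p = G' / (G' + R)} where
#' \eqn{G' = \max(green_{post} - green_{pre}, 0)} is the green signal above
#' the pre-lesion baseline and \eqn{R} the post-lesion red signal. The index
#' is 0 with no conversion and approaches 1 at complete conversion, and stays
#' stable where the red signal vanishes. Pixels with \eqn{G' + R} below the
#' noise floor are set to `NA` (undefined).
#'
#' @param pre,post Lists with `red`, `green` matrices ([register_and_average()]
#'   output), co-registered to the same geometry.
#' @param noise_floor Minimum `G' + R` for the index to be defined.
#' @return A `photoconversion_map`: list with `p` (matrix in `[0,1]` or `NA`),
#'   `g_excess`, `red_post`.
#' @export
photoconversion_map <- function(pre, post, noise_floor = 0.05) {
  stopifnot(all(dim(pre$green) == dim(post$green)),
            all(dim(pre$red) == dim(post$red)))
  g_excess <- pmax(post$green - pre$green, 0)
  denom <- g_excess + post$red
  p <- g_excess / denom
  p[!is.na(denom) & denom < noise_floor] <- NA_real_
  structure(list(p = p, g_excess = g_excess, red_post = post$red,
                 noise_floor = noise_floor),
            class = "photoconversion_map")
}

#' @export
print.photoconversion_map <- function(x, ...) {
  cat(sprintf("<photoconversion_map> %dx%d px, defined %.1f%%, mean p %.3f\n",
              nrow(x$p), ncol(x$p), 100 * mean(!is.na(x$p)),
              mean(x$p, na.rm = TRUE)))
  invisible(x)
}

#' Mean conversion index within a mask
#' @param map A `photoconversion_map`.
#' @param mask Logical matrix.
#' @return Scalar mean of defined `p` inside the mask.
#' @export
conversion_in_mask <- function(map, mask) {
  mean(map$p[mask], na.rm = TRUE)
}

#' Localize lesions on a photoconversion map
#'
#' Thresholds the conversion index, labels 8-connected components, discards
#' small ones, and returns intensity-weighted centroids in µm. Lesions whose
#' footprints touch merge into a single component (consequence of the
#' connectivity definition).
#'
#' @param map A `photoconversion_map`.
#' @param pitch µm per pixel.
#' @param p_threshold Conversion threshold (default 0.5).
#' @param min_area_px Minimum component area.
#' @return Tibble `lesion`, `x_um`, `y_um`, `area_px`, `mean_p`.
#' @export
lesion_localize_slo <- function(map, pitch, p_threshold = 0.5,
                                min_area_px = 9L) {
  bw <- !is.na(map$p) & map$p > p_threshold
  if (!any(bw)) {
    return(tibble::tibble(lesion = integer(), x_um = numeric(),
                          y_um = numeric(), area_px = integer(),
                          mean_p = numeric()))
  }
  lab <- label_components(bw)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rows <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_area_px) return(NULL)
    w <- map$p[lab == id]
    tibble::tibble(
      x_um = sum((idx[, 2] - 0.5) * w) / sum(w) * pitch,
      y_um = sum((idx[, 1] - 0.5) * w) / sum(w) * pitch,
      area_px = nrow(idx), mean_p = mean(w))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out <- dplyr::mutate(out, lesion = dplyr::row_number(),
                                      .before = 1)
  else out <- tibble::tibble(lesion = integer(), x_um = numeric(),
                             y_um = numeric(), area_px = integer(),
                             mean_p = numeric())
  out
}

#' Full SLO stack processing: QC, registration, averaging
#'
#' @param seq An [slo_sequence()].
#' @param ... Passed to [reject_motion_frames()].
#' @return List: `red`, `green`, `qc` (score tibble), `kept`, `shifts`.
#' @export
process_slo <- function(seq, ...) {
  qc <- reject_motion_frames(seq, ...)
  avg <- register_and_average(seq, qc$kept)
  list(red = avg$red, green = avg$green, qc = qc$scores, kept = qc$kept,
       shifts = avg$shifts)
}
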