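#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# long-format helper for image matrices
image_df <- function(img, pitch = 1) {
  tibble::tibble(
    y_um = rep((seq_len(nrow(img)) - 0.5) * pitch, times = ncol(img)),
    x_um = rep((seq_len(ncol(img)) - 0.5) * pitch, each = nrow(img)),
    value = as.vector(img)
  )
}

#' Plot an en face image
#'
#' @param img Numeric matrix (e.g. from [enface_projection()]).
#' @param pitch µm per pixel (defaults to the image's `pitch_x` attribute).
#' @param title Plot title.
#' @return A ggplot.
#' @export
plot_enface <- function(img, pitch = NULL, title = "en face projection") {
  pitch <- pitch %||% attr(img, "pitch_x") %||% 1
  ggplot2::ggplot(image_df(img, pitch),
                  ggplot2::aes(x = .data$x_um, y = .data$y_um,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 na.value = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = "x (µm)", y = "y (µm)",
                  fill = "intensity") +
    ggplot2::theme_minimal()
}

#' @rdname plot_enface
#' @param object A `photoconversion_map`.
#' @param ... Unused.
#' @method autoplot photoconversion_map
#' @export
autoplot.photoconversion_map <- function(object, ...) {
  p <- plot_enface(object$p, title = "photoconversion index p = G'/(G'+R)")
  p + ggplot2::scale_fill_viridis_c(na.value = "grey20", limits = c(0, 1))
}

#' Plot a lesion plan over its treatment mask
#'
#' @param object A `lesion_plan`.
#' @param ... Unused.
#' @return A ggplot of spot discs over the mask.
#' @method autoplot lesion_plan
#' @export
autoplot.lesion_plan <- function(object, ...) {
  r <- attr(object, "spot_diameter_um") / 2
  g <- ggplot2::ggplot()
  mask <- attr(object, "treatment")
  if (!is.null(mask)) {
    df <- image_df(mask * 1, attr(object, "pitch_um"))
    g <- g + ggplot2::geom_raster(
      data = df[df$value > 0, ],
      ggplot2::aes(x = .data$x_um, y = .data$y_um), fill = "grey80")
  }
  th <- seq(0, 2 * pi, length.out = 33)
  if (nrow(object)) {
    circ <- dplyr::bind_rows(lapply(seq_len(nrow(object)), function(i) {
      tibble::tibble(site = i,
                     x_um = object$x_um[i] + r * cos(th),
                     y_um = object$y_um[i] + r * sin(th))
    }))
    g <- g + ggplot2::geom_path(
      data = circ, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                group = .data$site),
      colour = "firebrick")
  }
  g + ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("lesion plan: %d sites", nrow(object)),
                  x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a segmenter training log
#' @param object A `lesion_segmenter`.
#' @param ... Unused.
#' @method autoplot lesion_segmenter
#' @export
autoplot.lesion_segmenter <- function(object, ...) {
  df <- object$log
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_loss, colour = "loss")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$val_dice, colour = "val Dice")) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "segmenter training") +
    ggplot2::theme_minimal()
}

#' Plot the scan-field distortion of a calibration
#'
#' Displacement between the fitted polynomial map and the best linear map,
#' over the voltage domain.
#' @param object A `calibration_model`.
#' @param n Grid resolution.
#' @param ... Unused.
#' @method autoplot calibration_model
#' @export
autoplot.calibration_model <- function(object, n = 15, ...) {
  dom <- object$domain
  g <- expand.grid(vx = seq(dom[1], dom[2], length.out = n),
                   vy = seq(dom[3], dom[4], length.out = n))
  pos <- suppressWarnings(map_voltage(object, as.matrix(g)))
  lin_x <- stats::lm(pos[, 1] ~ vx + vy, data = g)
  lin_y <- stats::lm(pos[, 2] ~ vx + vy, data = g)
  df <- tibble::tibble(vx = g$vx, vy = g$vy,
                       dx = stats::residuals(lin_x),
                       dy = stats::residuals(lin_y))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vx, y = .data$vy)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$vx + .data$dx / 1000,
                                       yend = .data$vy + .data$dy / 1000),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "pt"))) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "scan-field distortion (nonlinear part, mV-scaled)",
                  x = "vx (V)", y = "vy (V)") +
    ggplot2::theme_minimal()
}
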