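#' Plot an ion image
#'
#' Base-graphics heat map in physical micrometre coordinates; invalid pixels
#' are blank.
#'
#' @param x an `ion_image`
#' @param main title; defaults to the m/z window
#' @param col color ramp
#' @param ... passed to [graphics::image()]
#' @export
plot.ion_image <- function(x, main = NULL,
                           col = grDevices::hcl.colors(64, "viridis"), ...) {
  v <- x$values
  v[!x$valid] <- NA
  nx <- ncol(v); ny <- nrow(v)
  main <- main %||% sprintf("m/z %.4f +/- %.3g (%s)", x$mz_center, x$mz_tol,
                            x$normalization)
  graphics::image(x = (seq_len(nx) - 0.5) * x$pixel_size[1],
                  y = (seq_len(ny) - 0.5) * x$pixel_size[2],
                  z = t(v), col = col, xlab = "x (um)", ylab = "y (um)",
                  main = main, useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

#' Plot a tissue label map
#'
#' @param x a `tissue_label_map`
#' @param pixel_size micrometres per pixel for the axes
#' @param col one color per label, in `all_labels()` order
#' @param ... passed to [graphics::image()]
#' @export
plot.tissue_label_map <- function(x, pixel_size = c(50, 75),
                                  col = c("firebrick", "goldenrod",
                                          "slateblue", "grey90", "white"),
                                  ...) {
  z <- matrix(match(x$labels, all_labels()), x$ny, x$nx)
  graphics::image(x = (seq_len(x$nx) - 0.5) * pixel_size[1],
                  y = (seq_len(x$ny) - 0.5) * pixel_size[2],
                  z = t(z), col = col, zlim = c(1, length(all_labels())),
                  xlab = "x (um)", ylab = "y (um)", useRaster = TRUE,
                  asp = 1, ...)
  graphics::legend("topright", legend = all_labels(), fill = col, bty = "n",
                   cex = 0.8)
  invisible(x)
}
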