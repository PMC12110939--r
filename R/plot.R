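#' @include analyze.R
NULL

#' Render a signed interocular difference map
#'
#' Diverging blue-white-red colormap, symmetric about zero with limits at
#' the 99th percentile of the absolute differences (robust to outliers),
#' with the analysis zone circles overlaid. Blue marks regions where the
#' registered left eye sits below the right eye, red above.
#'
#' @param diff a [DifferenceMap-class].
#' @param zones zone diameters (mm) to outline (default \code{c(4, 6)}).
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return the symmetric color limit, invisibly (um).
#' @export
plotDifferenceMap <- function(diff, zones = c(4, 6),
                              main = "Interocular elevation difference", ...) {
  v <- diff@signed
  lim <- unname(stats::quantile(abs(v), 0.99, na.rm = TRUE))
  if (!is.finite(lim) || lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(
    c("#2166AC", "#67A9CF", "#F7F7F7", "#EF8A62", "#B2182B"))(255)
  n <- nrow(v)
  xs <- (seq_len(n) - diff@center[2]) * diff@spacing
  ys <- (seq_len(n) - diff@center[1]) * diff@spacing
  vc <- pmax(pmin(v, lim), -lim)
  graphics::image(xs, ys, t(vc), col = pal, zlim = c(-lim, lim),
                  xlab = "x (mm)", ylab = "y (mm)", main = main,
                  asp = 1, useRaster = TRUE, ...)
  tt <- seq(0, 2 * pi, length.out = 181)
  for (z in zones) {
    graphics::lines((z / 2) * cos(tt), (z / 2) * sin(tt), lty = 2)
  }
  graphics::mtext(sprintf("color limits: +/- %.1f um", lim), side = 3,
                  line = 0.2, cex = 0.8)
  invisible(lim)
}
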