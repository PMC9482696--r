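# Static SFP plot: orthographic view of the unit sphere with the axis tips
# in the standard colours (blue = FE/z, green = ABAD/y, red = LAR/x).

#' Plot a spherical frame projection
#'
#' Orthographic projection of the tip clouds (and optional region
#' boundaries) onto the viewing plane; back-facing points are dimmed.
#'
#' @param x An `sfp_trace`.
#' @param regions Optional named list of `spherical_region` objects
#'   (`x`, `y`, `z`) drawn as boundary polygons.
#' @param azimuth,elevation Viewing direction, degrees.
#' @param cex Point size.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, the 3x2 projection basis used.
#' @export
plot.sfp_trace <- function(x, regions = NULL, azimuth = 35, elevation = 25,
                           cex = 0.3, ...) {
  az <- deg2rad(azimuth); el <- deg2rad(elevation)
  eye <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  u <- normalize(cross3(c(0, 0, 1), eye))
  v <- cross3(eye, u)
  proj <- cbind(u, v)
  graphics::plot(NA, xlim = c(-1.05, 1.05), ylim = c(-1.05, 1.05), asp = 1,
                 xlab = "", ylab = "", axes = FALSE, ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th), col = "grey70")
  cols <- c(x = "red", y = "green3", z = "blue")
  for (ax in c("x", "y", "z")) {
    tips <- x[[paste0(ax, "_tips")]]
    front <- as.numeric(tips %*% eye) >= 0
    xy <- tips %*% proj
    graphics::points(xy[front, , drop = FALSE], col = cols[[ax]],
                     pch = 16, cex = cex)
    graphics::points(xy[!front, , drop = FALSE],
                     col = grDevices::adjustcolor(cols[[ax]], 0.15),
                     pch = 16, cex = cex)
  }
  if (!is.null(regions)) {
    for (ax in intersect(names(regions), c("x", "y", "z"))) {
      b <- regions[[ax]]$boundary
      xy <- b %*% proj
      graphics::polygon(xy, border = cols[[ax]], lwd = 1.5,
                        col = grDevices::adjustcolor(cols[[ax]], 0.08))
    }
  }
  invisible(proj)
}
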