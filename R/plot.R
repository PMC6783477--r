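# Circular plot of the group orientation result.

#' @describeIn fit_orientation Circular plot of the oriented animals'
#'   flow-frame bearings: points stacked in 5-degree bins on the unit circle
#'   (0 = upstream flow direction at the top), a mean arrow of length equal
#'   to the group resultant, and dashed radii marking the bootstrap CI.
#' @param bin_width Display bin width in degrees (must divide 360).
#' @export
plot.orient_fit <- function(x, bin_width = 5, ...) {
  or <- x$individuals[x$individuals$oriented, , drop = FALSE]
  bins <- bin_bearings(or$relative_bearing, bin_width)
  op <- graphics::par(mar = c(1, 1, 3, 1), pty = "s")
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-1.45, 1.45), ylim = c(-1.45, 1.45),
                 axes = FALSE, xlab = "", ylab = "", asp = 1,
                 main = "Orientation relative to tidal flow", ...)
  th <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(cos(th), sin(th), col = "grey50")
  # compass angle a (deg, clockwise from top) -> plot coords
  px <- function(a, r) r * sin(deg2rad(a))
  py <- function(a, r) r * cos(deg2rad(a))
  for (a in c(0, 90, 180, 270))
    graphics::text(px(a, 1.38), py(a, 1.38),
                   c("0°", "90°", "180°", "270°")[a / 90 + 1],
                   cex = 0.8, col = "grey30")
  # stacked points per occupied bin
  occ <- bins[bins$count > 0, ]
  for (i in seq_len(nrow(occ))) {
    a <- occ$bin_start[i] + bin_width / 2
    rr <- 1.02 + 0.055 * (seq_len(occ$count[i]) - 1)
    graphics::points(px(a, rr), py(a, rr), pch = 16, cex = 0.5,
                     col = "navyblue")
  }
  g <- x$group
  graphics::arrows(0, 0, px(g$mean_direction, g$r), py(g$mean_direction, g$r),
                   length = 0.1, lwd = 2)
  for (a in unname(g$ci95))
    graphics::lines(c(0, px(a, 1)), c(0, py(a, 1)), lty = 2, col = "grey40")
  graphics::mtext(sprintf("N = %d, mean %.0f°, r = %.2f, p = %.3g",
                          g$n_oriented, g$mean_direction, g$r, g$p),
                  side = 1, line = -1, cex = 0.85)
  invisible(x)
}
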