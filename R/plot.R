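#' Plot a channel ranking on a schematic head map
#'
#' Projects the montage onto the plane (azimuthal view from above, nose up)
#' and highlights the ranked channels, in the style of the top-10 scalp
#' figures: selected electrodes are filled and color-graded by score,
#' unselected ones drawn hollow.
#'
#' @param ranking a `channel_ranking`.
#' @param layout the full `electrode_layout` the ranking was computed on.
#' @param file optional PNG path; when `NULL`, draws on the current device.
#' @param main plot title.
#' @export
plot_head_map <- function(ranking, layout, file = NULL, main = NULL) {
  stopifnot(inherits(ranking, "channel_ranking"),
            inherits(layout, "electrode_layout"))
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  # simple azimuthal projection: radius grows with inclination from vertex
  incl <- acos(pmin(1, pmax(-1, layout$coords[, 3])))
  az <- atan2(layout$coords[, 1], layout$coords[, 2])
  r <- incl / (pi / 2)
  px <- r * sin(az)
  py <- r * cos(az)
  op <- graphics::par(mar = c(1, 1, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NA, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = main %||% sprintf("Top %d channels (%s)",
                                          nrow(ranking),
                                          attr(ranking, "method") %||% "?"))
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(1.25 * cos(th), 1.25 * sin(th))
  graphics::lines(c(-0.12, 0, 0.12), c(1.24, 1.38, 1.24))  # nose
  sel <- match(layout$labels, ranking$channel)
  pal <- grDevices::colorRampPalette(c("#FFD700", "#FF4500"))(nrow(ranking))
  for (i in seq_along(layout$labels)) {
    if (is.na(sel[i])) {
      graphics::points(px[i], py[i], pch = 21, bg = "white", cex = 2.2)
    } else {
      graphics::points(px[i], py[i], pch = 21,
                       bg = pal[nrow(ranking) - sel[i] + 1], cex = 2.6)
    }
    graphics::text(px[i], py[i] - 0.12, layout$labels[i], cex = 0.6)
  }
  invisible(NULL)
}
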