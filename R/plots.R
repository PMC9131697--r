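# Minimal base-graphics renderers for the raster and map outputs.

#' Render normalized density maps to a PNG heatmap panel
#'
#' @param maps named list of `iss_kde` layers (typically section-normalized).
#' @param path output PNG path.
#' @param ncol panels per row.
#' @export
plot_density_maps <- function(maps, path, ncol = 4) {
  nr <- ceiling(length(maps) / ncol)
  grDevices::png(path, width = 280 * ncol, height = 280 * nr)
  op <- graphics::par(mfrow = c(nr, ncol), mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); dev.off() }, add = TRUE)
  for (nm in names(maps)) {
    l <- maps[[nm]]
    image(l$x, l$y, l$z, main = nm, axes = FALSE, asp = 1,
          col = hcl.colors(64, "inferno"), useRaster = TRUE)
  }
  invisible(path)
}

#' Plot a called cell map colored by type
#'
#' @param called an `iss_called` data frame.
#' @param layout optional `iss_layout` whose region outlines are drawn.
#' @export
plot_cell_map <- function(called, layout = NULL) {
  types <- attr(called, "type_ids") %||% sort(unique(called$called_type))
  cols <- setNames(hcl.colors(length(types), "Dark 3"), types)
  plot(called$x, called$y, col = cols[called$called_type], pch = 16,
       cex = 0.4, asp = 1, xlab = "x (um)", ylab = "y (um)")
  if (!is.null(layout))
    for (p in layout$regions) polygon(p[, 1], p[, 2], border = "grey40")
  invisible(called)
}
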