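# Patch-trace visualization: every materialized image labelled with its
# hierarchical name, with each child's crop outlined in its parent view.

# rebuild absolute frames from the trace's affine parameters
trace_frames <- function(trace, pyr) {
  frames <- list(I1 = root_frame(pyr))
  for (i in seq_len(nrow(trace))) {
    r <- trace[i, ]
    if (r$layer == 0L) next
    frames[[r$name]] <- compose_frames(frames[[r$parent]],
                                       affine_params(r$s, r$tx, r$ty))
  }
  frames
}

#' Render a patch trace to a PNG
#'
#' One panel per layer; each materialized patch is shown grey-filtered
#' (with removed background drawn white), labelled with its
#' hierarchical name, and each child's crop is outlined in its parent view.
#'
#' @param trace the trace data frame from [magnet_forward()].
#' @param pyr the pyramid it was computed on.
#' @param out_path output PNG path.
#' @param tile display size per patch in pixels.
#' @return `out_path`, invisibly.
#' @export
render_trace <- function(trace, pyr, out_path, tile = 120) {
  if (is.null(trace) || nrow(trace) == 0) stop("empty trace")
  frames <- trace_frames(trace, pyr)
  layers <- sort(unique(trace$layer))
  ncol_max <- max(table(trace$layer))
  pad <- 28
  grDevices::png(out_path, width = ncol_max * (tile + 8) + 16,
                 height = length(layers) * (tile + pad + 8) + 16,
                 type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, ncol_max * (tile + 8) + 16),
                        ylim = c(0, length(layers) * (tile + pad + 8) + 16),
                        asp = 1)
  for (li in seq_along(layers)) {
    l <- layers[li]
    rows <- trace[trace$layer == l, , drop = FALSE]
    y0 <- (length(layers) - li) * (tile + pad + 8) + 8
    for (k in seq_len(nrow(rows))) {
      r <- rows[k, ]
      fr <- frames[[r$name]]
      img <- grey_filter(read_region(pyr, fr, r$resolution))
      # removed (black) background shown white for visualization
      white <- grey_keep_mask(img) == 0
      img[white] <- 1
      x0 <- (k - 1) * (tile + 8) + 8
      graphics::rasterImage(grDevices::as.raster(img), x0, y0, x0 + tile,
                            y0 + tile, interpolate = FALSE)
      # outline children in this (parent) view
      kids <- trace[!is.na(trace$parent) & trace$parent == r$name, ,
                    drop = FALSE]
      for (m in seq_len(nrow(kids))) {
        kf <- frames[[kids$name[m]]]
        rx0 <- (kf$cx - kf$hw - (fr$cx - fr$hw)) / (2 * fr$hw)
        rx1 <- (kf$cx + kf$hw - (fr$cx - fr$hw)) / (2 * fr$hw)
        ry0 <- (kf$cy - kf$hh - (fr$cy - fr$hh)) / (2 * fr$hh)
        ry1 <- (kf$cy + kf$hh - (fr$cy - fr$hh)) / (2 * fr$hh)
        graphics::rect(x0 + rx0 * tile, y0 + (1 - ry1) * tile,
                       x0 + rx1 * tile, y0 + (1 - ry0) * tile,
                       border = "red", lwd = 1.5)
      }
      graphics::text(x0 + tile / 2, y0 + tile + 10, r$name, cex = 0.9)
    }
  }
  invisible(out_path)
}
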