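#' Per-cell feature heatmap
#'
#' Renders each cell region filled with a colour mapped from its feature
#' value, with a colour bar annotated with the value range, and writes the
#' figure as PNG. Cells without a matching geometry are drawn hatched and a
#' warning is logged. A degenerate value range (all cells equal) maps every
#' cell to the middle of the palette.
#'
#' @param features feature data frame with a `cell_id` column.
#' @param feature name of the feature column to map.
#' @param geoms list of `cell_geometry` objects.
#' @param out_path output PNG path.
#' @param palette palette function taking a number of colours, default
#'   `hcl.colors` with the viridis palette.
#' @param width_px,height_px device size.
#' @return invisibly, the per-cell colours (named by cell id).
#' @export
cell_heatmap <- function(features, feature, geoms, out_path,
                         palette = function(n) hcl.colors(n, "viridis"),
                         width_px = 800, height_px = 800) {
  if (!feature %in% names(features)) {
    stop("feature `", feature, "` not present in the feature table")
  }
  vals <- features[[feature]]
  ids <- features$cell_id
  cols256 <- palette(256)
  rng <- range(vals, finite = TRUE)
  if (diff(rng) > 0) {
    ci <- 1 + round(255 * (vals - rng[1]) / diff(rng))
  } else {
    ci <- rep(128L, length(vals))
  }
  cell_cols <- setNames(cols256[ci], ids)
  geom_ids <- vapply(geoms, `[[`, integer(1), "cell_id")
  missing_geom <- setdiff(ids, geom_ids)
  if (length(missing_geom) > 0) {
    warning("no geometry for cell id(s): ",
            paste(missing_geom, collapse = ", "), "; drawn hatched")
  }
  px <- geoms[[1]]$pixel_size_nm
  nx <- geoms[[1]]$canvas_px[1] * px
  ny <- geoms[[1]]$canvas_px[2] * px
  grDevices::png(out_path, width = width_px, height = height_px)
  on.exit(grDevices::dev.off(), add = TRUE)
  par(mar = c(2, 2, 2, 6))
  plot.new()
  plot.window(xlim = c(0, nx), ylim = c(ny, 0), asp = 1)
  title(main = feature)
  phi <- seq(0, 2 * pi, length.out = 120)
  for (g in geoms) {
    bx <- g$cell_axes_nm[1] * cos(phi)
    by <- g$cell_axes_nm[2] * sin(phi)
    w <- .from_local(bx, by, g$centre_nm, g$theta)
    col <- cell_cols[as.character(g$cell_id)]
    if (is.na(col)) {
      polygon(w$x, w$y, col = NA, border = "grey30", density = 20)
    } else {
      polygon(w$x, w$y, col = col, border = "grey30")
    }
  }
  # colour bar
  usr <- par("usr")
  xb <- usr[2] + 0.02 * diff(usr[1:2])
  yb <- seq(usr[3], usr[4], length.out = 257)
  for (i in seq_len(256)) {
    rect(xb, yb[i], xb + 0.03 * diff(usr[1:2]), yb[i + 1],
         col = cols256[i], border = NA, xpd = NA)
  }
  text(xb + 0.05 * diff(usr[1:2]), usr[3], sprintf("%.3g", rng[2]),
       xpd = NA, adj = 0)
  text(xb + 0.05 * diff(usr[1:2]), usr[4], sprintf("%.3g", rng[1]),
       xpd = NA, adj = 0)
  invisible(cell_cols)
}
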