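# Observation windows for Ripley statistics. A window knows its area and the
# distance from any interior point to its boundary (needed by the border
# edge correction). Windows are rectangles (tests, calibration), ellipses
# (nucleus), elliptical annuli (cytoplasm = cell minus nucleus) and boundary
# bands (the strip of width w inside the nuclear envelope).

#' Rectangular observation window
#'
#' @param xlim,ylim numeric length-2 ranges in nanometres.
#' @return a `ppwindow` object.
#' @export
rect_window <- function(xlim, ylim) {
  stopifnot(diff(xlim) > 0, diff(ylim) > 0)
  structure(list(type = "rect", xlim = xlim, ylim = ylim),
            class = "ppwindow")
}

#' Elliptical observation window (e.g. the nucleus)
#'
#' @param geom a `cell_geometry` object.
#' @param region `"nucleus"` or `"cell"`.
#' @return a `ppwindow` object.
#' @export
ellipse_window <- function(geom, region = c("nucleus", "cell")) {
  region <- match.arg(region)
  structure(list(type = "ellipse", geom = geom, region = region),
            class = "ppwindow")
}

#' Cytoplasmic observation window (cell minus nucleus)
#'
#' @param geom a `cell_geometry` object.
#' @return a `ppwindow` object.
#' @export
annulus_window <- function(geom) {
  structure(list(type = "annulus", geom = geom), class = "ppwindow")
}

#' Nuclear boundary-band observation window
#'
#' The set of points inside the nucleus at Euclidean distance at most
#' `band_width_nm` from the nuclear envelope. Its area is computed by
#' deterministic grid integration (the offset curve of an ellipse is not an
#' ellipse, so there is no closed form).
#'
#' The area uses the inner Steiner formula `w P - pi w^2` (exact for a
#' convex window whose minimum boundary curvature radius `b^2/a` exceeds the
#' band width `w`, with `P` the ellipse perimeter); for wider bands it falls
#' back to grid integration.
#'
#' @param geom a `cell_geometry` object.
#' @param band_width_nm band width in nanometres (> 0).
#' @param grid_n grid resolution per axis for the fallback area integration.
#' @return a `ppwindow` object.
#' @export
band_window <- function(geom, band_width_nm, grid_n = 201L) {
  stopifnot(band_width_nm > 0)
  a <- max(geom$nucleus_axes_nm)
  b <- min(geom$nucleus_axes_nm)
  w <- band_width_nm
  if (w < b^2 / a && w < b) {
    area <- w * .ellipse_perimeter(a, b) - pi * w^2
  } else if (w >= b) {
    area <- .ellipse_area(a, b)           # band covers the whole nucleus
  } else {
    xs <- seq(-a, a, length.out = grid_n)
    ys <- seq(-b, b, length.out = grid_n)
    gx <- rep(xs, times = grid_n)
    gy <- rep(ys, each = grid_n)
    d <- .ellipse_signed_distance_local(gx, gy, a, b)
    inband <- d < 0 & -d <= w
    area <- sum(inband) * (xs[2] - xs[1]) * (ys[2] - ys[1])
  }
  structure(list(type = "band", geom = geom, band_width_nm = band_width_nm,
                 area_nm2 = area), class = "ppwindow")
}

#' Window area
#'
#' @param w a `ppwindow` object.
#' @return area in square nanometres.
#' @export
window_area <- function(w) {
  stopifnot(inherits(w, "ppwindow"))
  switch(w$type,
    rect = diff(w$xlim) * diff(w$ylim),
    ellipse = {
      ax <- if (w$region == "nucleus") w$geom$nucleus_axes_nm else w$geom$cell_axes_nm
      .ellipse_area(ax[1], ax[2])
    },
    annulus = .ellipse_area(w$geom$cell_axes_nm[1], w$geom$cell_axes_nm[2]) -
      .ellipse_area(w$geom$nucleus_axes_nm[1], w$geom$nucleus_axes_nm[2]),
    band = w$area_nm2
  )
}

#' Distance from interior points to the window boundary
#'
#' @param w a `ppwindow` object.
#' @param x_nm,y_nm point coordinates (assumed inside the window).
#' @return numeric vector of distances in nanometres.
#' @export
window_boundary_distance <- function(w, x_nm, y_nm) {
  stopifnot(inherits(w, "ppwindow"))
  switch(w$type,
    rect = pmin(x_nm - w$xlim[1], w$xlim[2] - x_nm,
                y_nm - w$ylim[1], w$ylim[2] - y_nm),
    ellipse = {
      d <- if (w$region == "nucleus") {
        nucleus_boundary_distance(w$geom, x_nm, y_nm)
      } else {
        cell_boundary_distance(w$geom, x_nm, y_nm)
      }
      pmax(-d, 0)
    },
    annulus = {
      d_out <- pmax(-cell_boundary_distance(w$geom, x_nm, y_nm), 0)
      d_in <- pmax(nucleus_boundary_distance(w$geom, x_nm, y_nm), 0)
      pmin(d_out, d_in)
    },
    band = {
      depth <- pmax(-nucleus_boundary_distance(w$geom, x_nm, y_nm), 0)
      pmin(depth, pmax(w$band_width_nm - depth, 0))
    }
  )
}
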