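#' Render a ground truth into a multi-channel image
#'
#' The spot channel is a sum of unit-amplitude isotropic Gaussians (the
#' point-spread function) centred at the ground-truth positions, plus a
#' constant background and optional i.i.d. Gaussian noise. The nucleus and
#' cell-marker channels are filled from the rasterised masks, and the label
#' masks themselves are carried losslessly. Pixel `(i, j)` (row, column)
#' has its centre at `(j, i) * pixel_size_nm`.
#'
#' @param truth a `ground_truth` object from [simulate_cells()].
#' @param psf_sigma_px PSF standard deviation in pixels (> 0).
#' @param background constant background level added to the spot channel.
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param seed integer seed for the noise draw.
#' @return object of class `sim_image`: list with numeric matrices `spots`,
#'   `nucleus`, `cell` and integer matrices `cell_labels`, `nucleus_labels`,
#'   plus `pixel_size_nm`.
#' @export
render_image <- function(truth, psf_sigma_px = 1.5, background = 0.1,
                         noise_sd = 0, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"), psf_sigma_px > 0, noise_sd >= 0)
  px <- truth$geometry[[1]]$pixel_size_nm
  nx <- truth$geometry[[1]]$canvas_px[1]
  ny <- truth$geometry[[1]]$canvas_px[2]
  img <- matrix(background, nrow = ny, ncol = nx)
  sp <- truth$spots
  if (nrow(sp) > 0) {
    cx <- sp$x_nm / px                   # continuous pixel coordinates
    cy <- sp$y_nm / px
    if (any(cx < 0.5 | cx > nx + 0.5 | cy < 0.5 | cy > ny + 0.5)) {
      stop("ground-truth spots fall outside the canvas")
    }
    half <- ceiling(5 * psf_sigma_px)
    for (s in seq_len(nrow(sp))) {
      j0 <- round(cx[s]); i0 <- round(cy[s])
      jr <- max(1L, j0 - half):min(nx, j0 + half)
      ir <- max(1L, i0 - half):min(ny, i0 + half)
      gx <- exp(-((jr - cx[s])^2) / (2 * psf_sigma_px^2))
      gy <- exp(-((ir - cy[s])^2) / (2 * psf_sigma_px^2))
      img[ir, jr] <- img[ir, jr] + outer(gy, gx)
    }
  }
  if (noise_sd > 0) {
    img <- img + withr::with_seed(seed,
      matrix(rnorm(nx * ny, 0, noise_sd), nrow = ny, ncol = nx))
  }
  masks <- rasterize_geometry(truth$geometry)
  structure(list(
    spots = img,
    nucleus = (masks$nucleus_labels > 0) * 1,
    cell = (masks$cell_labels > 0) * 1,
    cell_labels = masks$cell_labels,
    nucleus_labels = masks$nucleus_labels,
    pixel_size_nm = px
  ), class = "sim_image")
}

#' @export
print.sim_image <- function(x, ...) {
  cat(sprintf("sim_image: %d x %d px at %g nm/px, %d cells\n",
              nrow(x$spots), ncol(x$spots), x$pixel_size_nm,
              max(x$cell_labels)))
  invisible(x)
}
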