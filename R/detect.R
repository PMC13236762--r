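# Spot detection, cell assignment and nucleus morphology: the image
# processing step upstream of feature extraction. Segmentation masks are an
# input (here produced by the synthetic generator); only the spots are
# detected de novo.

# scale-normalised, sign-flipped Laplacian-of-Gaussian kernel: blobs of
# scale ~ sigma become positive peaks; zero-sum so flat background maps to 0
.log_kernel <- function(sigma) {
  half <- max(2L, ceiling(4 * sigma))
  ax <- (-half):half
  g <- exp(-ax^2 / (2 * sigma^2))
  G <- outer(g, g)
  r2 <- outer(ax^2, ax^2, "+")
  k <- -(r2 - 2 * sigma^2) / sigma^2 * G   # -sigma^2 * Laplacian(G), scaled
  k - mean(k)
}

#' Detect diffraction-limited spots in a single-channel image
#'
#' Laplacian-of-Gaussian blob detection at the PSF scale: the image is
#' convolved with a scale-normalised LoG kernel, local maxima of the
#' response are kept when they exceed the response median plus
#' `threshold_sd` robust standard deviations (MAD), and spot centres are
#' refined to sub-pixel precision by a separable quadratic fit on the
#' response. A constant image yields an empty call set.
#'
#' @param image numeric matrix (rows = y, columns = x); pixel `(i, j)` has
#'   its centre at `(j, i) * pixel_size_nm`.
#' @param psf_sigma_px PSF standard deviation in pixels (> 0).
#' @param threshold_sd detection threshold in robust SD units (default 5).
#' @param pixel_size_nm physical pixel size.
#' @return data frame of spot calls: `x_nm`, `y_nm`, `intensity` (background
#'   subtracted image intensity at the peak), `cell_id` (`NA`, see
#'   [assign_spots()]) and `compartment` (`"unassigned"`).
#' @export
detect_spots <- function(image, psf_sigma_px = 1.5, threshold_sd = 5,
                         pixel_size_nm = 100) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a 2D numeric matrix")
  }
  stopifnot(psf_sigma_px > 0, threshold_sd >= 0, pixel_size_nm > 0)
  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      intensity = numeric(0), cell_id = integer(0),
                      compartment = character(0))
  ny <- nrow(image); nx <- ncol(image)
  k <- .log_kernel(psf_sigma_px)
  if (nrow(k) >= ny || ncol(k) >= nx) stop("image smaller than the LoG kernel")
  resp <- EBImage::filter2(image, k, boundary = "replicate")
  resp <- matrix(as.numeric(resp), nrow = ny)
  thr <- median(resp) + threshold_sd * mad(resp)
  thr <- max(thr, 1e-8 * max(abs(resp)))    # guard for noise-free images
  m <- max(2L, ceiling(psf_sigma_px))       # margin: maxima need neighbours
  core <- resp[(m + 1):(ny - m), (m + 1):(nx - m), drop = FALSE]
  shift <- function(di, dj) resp[(m + 1 + di):(ny - m + di),
                                 (m + 1 + dj):(nx - m + dj), drop = FALSE]
  ismax <- core > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- shift(di, dj)
    # strict against lexicographically earlier neighbours so an exact
    # plateau yields exactly one call
    if (di < 0 || (di == 0 && dj < 0)) {
      ismax <- ismax & (core > nb)
    } else {
      ismax <- ismax & (core >= nb)
    }
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  ii <- idx[, 1] + m                      # row (y) in full image
  jj <- idx[, 2] + m                      # col (x)
  # separable quadratic sub-pixel refinement on the LoG response
  refine <- function(fm1, f0, fp1) {
    den <- fm1 - 2 * f0 + fp1
    off <- ifelse(abs(den) > .Machine$double.eps, 0.5 * (fm1 - fp1) / den, 0)
    pmin(pmax(off, -0.5), 0.5)
  }
  oy <- refine(resp[cbind(ii - 1, jj)], resp[cbind(ii, jj)], resp[cbind(ii + 1, jj)])
  ox <- refine(resp[cbind(ii, jj - 1)], resp[cbind(ii, jj)], resp[cbind(ii, jj + 1)])
  bg <- median(image)
  data.frame(
    x_nm = (jj + ox) * pixel_size_nm,
    y_nm = (ii + oy) * pixel_size_nm,
    intensity = pmax(image[cbind(ii, jj)] - bg, 0),
    cell_id = NA_integer_,
    compartment = "unassigned"
  )
}

#' Assign spots to cells and compartments
#'
#' Each spot receives the `cell_id` of the cell-label pixel containing its
#' rounded coordinate (`NA` when the pixel is background) and a compartment:
#' `"nucleus"` when the nucleus label at that pixel matches the cell,
#' otherwise `"cytoplasm"`. Spots on the nucleus boundary pixel are nuclear
#' (membership is by label value at the rounded coordinate). Order of the
#' input spots is preserved.
#'
#' @param spots data frame of spot calls ([detect_spots()] or ground truth).
#' @param cell_labels,nucleus_labels integer label matrices of equal shape;
#'   every nonzero nucleus pixel must carry the same label as the cell pixel
#'   beneath it, otherwise the segmentation is inconsistent and an error is
#'   raised.
#' @param pixel_size_nm physical pixel size.
#' @return the spot data frame with `cell_id` and `compartment` filled in.
#' @export
assign_spots <- function(spots, cell_labels, nucleus_labels,
                         pixel_size_nm = 100) {
  stopifnot(is.matrix(cell_labels), is.matrix(nucleus_labels),
            all(dim(cell_labels) == dim(nucleus_labels)))
  bad <- nucleus_labels != 0 &
    (cell_labels == 0 | nucleus_labels != cell_labels)
  if (any(bad)) {
    stop("inconsistent segmentation: nucleus label present outside its cell label")
  }
  if (nrow(spots) == 0) {
    spots$cell_id <- integer(0); spots$compartment <- character(0)
    return(spots)
  }
  jj <- pmin(pmax(round(spots$x_nm / pixel_size_nm), 1L), ncol(cell_labels))
  ii <- pmin(pmax(round(spots$y_nm / pixel_size_nm), 1L), nrow(cell_labels))
  cid <- cell_labels[cbind(ii, jj)]
  nid <- nucleus_labels[cbind(ii, jj)]
  spots$cell_id <- ifelse(cid == 0L, NA_integer_, cid)
  spots$compartment <- ifelse(cid == 0L, "unassigned",
                              ifelse(nid == cid, "nucleus", "cytoplasm"))
  spots
}

#' Identify cells touching the image border
#'
#' Edge cells have truncated Ripley windows and are excluded from feature
#' extraction by default.
#'
#' @param cell_labels integer label matrix.
#' @return integer vector of label values present on the image border.
#' @export
edge_cells <- function(cell_labels) {
  border <- c(cell_labels[1, ], cell_labels[nrow(cell_labels), ],
              cell_labels[, 1], cell_labels[, ncol(cell_labels)])
  sort(unique(border[border != 0]))
}

#' Nucleus morphology from a label mask
#'
#' Per-nucleus area, perimeter, eccentricity and solidity in physical units.
#' Area is pixel count times the squared pixel size; the perimeter is the
#' arc length of the convex hull of the pixel centres (exact for the convex
#' nuclei considered here, and free of the staircase bias of boundary-pixel
#' counting); eccentricity is derived from the eigenvalues of the
#' pixel-coordinate covariance (`sqrt(1 - l2/l1)`); solidity is the area
#' divided by the convex-hull area, clamped to 1.
#'
#' @param nucleus_labels integer label matrix (0 = background).
#' @param pixel_size_nm physical pixel size.
#' @return data frame with columns `cell_id`, `morph_area_um2`,
#'   `morph_perimeter_um`, `morph_eccentricity`, `morph_solidity`; empty for
#'   an empty label image.
#' @export
nucleus_morphology <- function(nucleus_labels, pixel_size_nm = 100) {
  stopifnot(is.matrix(nucleus_labels))
  labs <- sort(unique(nucleus_labels[nucleus_labels > 0]))
  if (length(labs) == 0) {
    return(data.frame(cell_id = integer(0), morph_area_um2 = numeric(0),
                      morph_perimeter_um = numeric(0),
                      morph_eccentricity = numeric(0),
                      morph_solidity = numeric(0)))
  }
  px_um <- pixel_size_nm / 1e3
  out <- lapply(seq_along(labs), function(k) {
    lab <- labs[k]
    idx <- which(nucleus_labels == lab, arr.ind = TRUE)
    npx <- nrow(idx)
    xy <- cbind(idx[, 2], idx[, 1])     # (x, y) pixel centres
    ecc <- 0
    if (npx > 2) {
      ev <- eigen(stats::cov(xy), symmetric = TRUE, only.values = TRUE)$values
      if (ev[1] > 0) ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
    }
    hull <- chull(xy)
    hx <- xy[hull, 1]; hy <- xy[hull, 2]
    hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    solidity <- if (hull_area > 0) min(npx / hull_area, 1) else 1
    hull_perim <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
    data.frame(
      cell_id = as.integer(lab),
      morph_area_um2 = npx * px_um^2,
      morph_perimeter_um = hull_perim * px_um,
      morph_eccentricity = ecc,
      morph_solidity = solidity
    )
  })
  do.call(rbind, out)
}
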