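# File interfaces: multi-page TIFF for rendered channels and label masks,
# CSV for spot calls and cohort tables, YAML for generator parameters.

#' Write a rendered image as multi-page TIFF
#'
#' Pages, in order: spot channel, nucleus channel, cell-marker channel,
#' then the nucleus and cell label masks. Pages are stored as 32-bit
#' samples scaled by a fixed factor of 2^16 (the TIFF writer requires the
#' unit range); label values round-trip exactly and intensities to an
#' absolute quantisation of 2^-16 (~1.5e-5).
#'
#' @param image a `sim_image` from [render_image()].
#' @param path output TIFF path.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "sim_image"))
  s <- 65536
  pages <- list(image$spots, image$nucleus, image$cell,
                image$nucleus_labels * 1.0, image$cell_labels * 1.0)
  if (max(vapply(pages, max, numeric(1))) >= s) {
    stop("image values exceed the fixed TIFF scaling range")
  }
  tiff::writeTIFF(lapply(pages, function(p) p / s), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_image_tiff()]
#'
#' @param path TIFF path.
#' @param pixel_size_nm pixel size to attach (TIFF tags are not relied on).
#' @return a `sim_image` object.
#' @export
read_image_tiff <- function(path, pixel_size_nm = 100) {
  pages <- lapply(tiff::readTIFF(path, all = TRUE), function(p) p * 65536)
  stopifnot(length(pages) == 5)
  structure(list(
    spots = pages[[1]],
    nucleus = pages[[2]],
    cell = pages[[3]],
    nucleus_labels = matrix(as.integer(round(pages[[4]])), nrow = nrow(pages[[4]])),
    cell_labels = matrix(as.integer(round(pages[[5]])), nrow = nrow(pages[[5]])),
    pixel_size_nm = pixel_size_nm
  ), class = "sim_image")
}

#' Write / read spot calls as CSV
#'
#' Columns: `x_nm`, `y_nm`, `intensity` (if present), `cell_id`,
#' `compartment`.
#'
#' @param spots spot data frame (detected calls or ground truth).
#' @param path CSV path.
#' @export
write_spots <- function(spots, path) {
  write.csv(spots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spots
#' @export
read_spots <- function(path) {
  read.csv(path, check.names = FALSE)
}

#' Write phenotype parameters as YAML
#'
#' @param params a [phenotype_params()] object.
#' @param path YAML path.
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "phenotype_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  p <- yaml::read_yaml(path)
  do.call(phenotype_params, p)
}
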