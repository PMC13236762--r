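#' Phenotype parameters for the spot generator
#'
#' Bundles the generative knobs for one simulated cell phenotype: expected
#' spot copy number, nuclear allocation probability, the clustering mode and
#' its Thomas-process parameters, and nuclear-boundary enrichment.
#'
#' @param group_label one of `"control"`, `"aab_pos"`, `"t1d"`.
#' @param mean_spots_per_cell Poisson mean of the per-cell spot count.
#' @param nuclear_fraction probability a spot is allocated to the nucleus.
#' @param cluster_mode `"csr"` (complete spatial randomness) or `"clustered"`
#'   (parent--offspring Thomas-type process).
#' @param cluster_parent_intensity expected parents per square micrometre of
#'   compartment area (clustered mode).
#' @param cluster_offspring_mean expected offspring per parent; with the
#'   total count conditioned on `mean_spots_per_cell` this only sets the
#'   nominal parent load, see Details.
#' @param cluster_sigma_nm isotropic Gaussian scatter of offspring around
#'   their parent, nanometres.
#' @param boundary_enrichment fraction of nuclear spots relocated into the
#'   boundary band, in `[0, 1]`.
#' @param band_width_nm width of the band inside the nuclear envelope.
#'
#' @details The per-cell total is always Poisson(`mean_spots_per_cell`) so
#' that expression (feature group 1) stays decoupled from clustering
#' (group 3). In clustered mode the parents are Poisson over the compartment
#' and the realised spots are allocated uniformly across parents, i.e. a
#' Thomas process conditioned on its total count.
#'
#' @return a `phenotype_params` object (validated list).
#' @seealso [phenotype_preset()] for the per-group study defaults.
#' @export
phenotype_params <- function(group_label = c("control", "aab_pos", "t1d"),
                             mean_spots_per_cell = 40,
                             nuclear_fraction = 0.4,
                             cluster_mode = c("csr", "clustered"),
                             cluster_parent_intensity = 0.3,
                             cluster_offspring_mean = 10,
                             cluster_sigma_nm = 200,
                             boundary_enrichment = 0,
                             band_width_nm = 500) {
  group_label <- match.arg(group_label)
  cluster_mode <- match.arg(cluster_mode)
  stopifnot(
    mean_spots_per_cell > 0,
    nuclear_fraction >= 0, nuclear_fraction <= 1,
    cluster_parent_intensity > 0,
    cluster_offspring_mean > 0,
    cluster_sigma_nm > 0,
    boundary_enrichment >= 0, boundary_enrichment <= 1,
    band_width_nm > 0
  )
  structure(list(
    group_label = group_label,
    mean_spots_per_cell = mean_spots_per_cell,
    nuclear_fraction = nuclear_fraction,
    cluster_mode = cluster_mode,
    cluster_parent_intensity = cluster_parent_intensity,
    cluster_offspring_mean = cluster_offspring_mean,
    cluster_sigma_nm = cluster_sigma_nm,
    boundary_enrichment = boundary_enrichment,
    band_width_nm = band_width_nm
  ), class = "phenotype_params")
}

#' Study-condition phenotype presets
#'
#' Default generative settings per disease group, emulating the qualitative
#' contrasts reported for beta cells: higher copy number, higher nuclear
#' fraction, nuclear clustering and boundary aggregation in autoantibody
#' positive and diabetic cells relative to controls. The quantitative values
#' are package choices (the source imaging data are not deposited); they are
#' discussed in the methods vignette.
#'
#' @param group one of `"control"`, `"aab_pos"`, `"t1d"`.
#' @return a `phenotype_params` object.
#' @export
phenotype_preset <- function(group = c("control", "aab_pos", "t1d")) {
  group <- match.arg(group)
  switch(group,
    control = phenotype_params("control", mean_spots_per_cell = 40,
                               nuclear_fraction = 0.4, cluster_mode = "csr",
                               boundary_enrichment = 0),
    aab_pos = phenotype_params("aab_pos", mean_spots_per_cell = 60,
                               nuclear_fraction = 0.5,
                               cluster_mode = "clustered",
                               boundary_enrichment = 0.15),
    t1d = phenotype_params("t1d", mean_spots_per_cell = 80,
                           nuclear_fraction = 0.6,
                           cluster_mode = "clustered",
                           boundary_enrichment = 0.3)
  )
}

# uniform point in one compartment of a cell (image frame, nm)
.sample_compartment_uniform <- function(n, geom, compartment) {
  if (n == 0L) return(data.frame(x_nm = numeric(0), y_nm = numeric(0)))
  ax_cell <- geom$cell_axes_nm
  ax_nuc <- geom$nucleus_axes_nm
  if (compartment == "nucleus") {
    p <- .runif_ellipse(n, ax_nuc[1], ax_nuc[2])
  } else {
    # rejection from the cell ellipse; acceptance prob = 1 - area ratio >= 0.5
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < n) {
      m <- 2L * (n - length(xs)) + 10L
      q <- .runif_ellipse(m, ax_cell[1], ax_cell[2])
      keep <- (q$x / ax_nuc[1])^2 + (q$y / ax_nuc[2])^2 > 1
      xs <- c(xs, q$x[keep]); ys <- c(ys, q$y[keep])
    }
    p <- list(x = xs[seq_len(n)], y = ys[seq_len(n)])
  }
  w <- .from_local(p$x, p$y, geom$centre_nm, geom$theta)
  data.frame(x_nm = w$x, y_nm = w$y)
}

# clustered placement: parents uniform over the compartment, spots allocated
# uniformly over parents with Gaussian scatter, rejection-resampled into the
# compartment; zero parents yields an empty pattern
.sample_compartment_clustered <- function(n, geom, compartment, params) {
  if (n == 0L) return(data.frame(x_nm = numeric(0), y_nm = numeric(0)))
  area_um2 <- if (compartment == "nucleus") {
    .ellipse_area(geom$nucleus_axes_nm[1], geom$nucleus_axes_nm[2]) / 1e6
  } else {
    (.ellipse_area(geom$cell_axes_nm[1], geom$cell_axes_nm[2]) -
       .ellipse_area(geom$nucleus_axes_nm[1], geom$nucleus_axes_nm[2])) / 1e6
  }
  if (area_um2 <= 0) stop("compartment has zero area")
  n_par <- rpois(1, params$cluster_parent_intensity * area_um2)
  if (n_par == 0L) return(data.frame(x_nm = numeric(0), y_nm = numeric(0)))
  parents <- .sample_compartment_uniform(n_par, geom, compartment)
  pick <- sample.int(n_par, n, replace = TRUE)
  inside <- function(x, y) {
    if (compartment == "nucleus") point_in_region(geom, x, y, "nucleus")
    else point_in_region(geom, x, y, "cell") &
      !point_in_region(geom, x, y, "nucleus")
  }
  x <- numeric(n); y <- numeric(n)
  todo <- seq_len(n)
  tries <- 0L
  while (length(todo) > 0 && tries < 1000L) {
    tries <- tries + 1L
    xx <- parents$x_nm[pick[todo]] + rnorm(length(todo), 0, params$cluster_sigma_nm)
    yy <- parents$y_nm[pick[todo]] + rnorm(length(todo), 0, params$cluster_sigma_nm)
    ok <- inside(xx, yy)
    x[todo[ok]] <- xx[ok]
    y[todo[ok]] <- yy[ok]
    todo <- todo[!ok]
  }
  if (length(todo) > 0) {               # pathological sigma: fall back to parent
    x[todo] <- parents$x_nm[pick[todo]]
    y[todo] <- parents$y_nm[pick[todo]]
  }
  data.frame(x_nm = x, y_nm = y)
}

# relocate selected nuclear spots uniformly into the boundary band
.relocate_to_band <- function(k, geom, band_width_nm) {
  if (k == 0L) return(data.frame(x_nm = numeric(0), y_nm = numeric(0)))
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < k && tries < 5000L) {
    tries <- tries + 1L
    m <- 4L * (k - length(xs)) + 10L
    p <- .sample_compartment_uniform(m, geom, "nucleus")
    d <- nucleus_boundary_distance(geom, p$x_nm, p$y_nm)
    keep <- -d <= band_width_nm
    xs <- c(xs, p$x_nm[keep]); ys <- c(ys, p$y_nm[keep])
  }
  if (length(xs) < k) stop("failed to sample the nuclear boundary band")
  data.frame(x_nm = xs[seq_len(k)], y_nm = ys[seq_len(k)])
}

#' Sample a ground-truth spot pattern for one cell
#'
#' Draws a per-cell spot count from Poisson(`mean_spots_per_cell`), allocates
#' each spot to the nucleus with probability `nuclear_fraction`, places spots
#' uniformly (CSR) or by a Thomas-type cluster process within the
#' compartment, and finally relocates a `boundary_enrichment` fraction of the
#' nuclear spots uniformly into the band of width `band_width_nm` inside the
#' nuclear envelope.
#'
#' @param geom a `cell_geometry` object.
#' @param params a [phenotype_params()] object.
#' @param seed integer seed; output is bit-reproducible.
#' @return data frame with columns `x_nm`, `y_nm`, `cell_id`, `compartment`
#'   (`"nucleus"` or `"cytoplasm"`).
#' @export
sample_point_pattern <- function(geom, params, seed = 1) {
  stopifnot(inherits(geom, "cell_geometry"), inherits(params, "phenotype_params"))
  withr::with_seed(seed, .sample_point_pattern_impl(geom, params))
}

.sample_point_pattern_impl <- function(geom, params) {
  n <- rpois(1, params$mean_spots_per_cell)
  n_nuc <- rbinom(1, n, params$nuclear_fraction)
  n_cyt <- n - n_nuc
  place <- function(k, compartment) {
    if (params$cluster_mode == "csr") {
      .sample_compartment_uniform(k, geom, compartment)
    } else {
      .sample_compartment_clustered(k, geom, compartment, params)
    }
  }
  nuc <- place(n_nuc, "nucleus")
  cyt <- place(n_cyt, "cytoplasm")
  if (params$boundary_enrichment > 0 && nrow(nuc) > 0) {
    sel <- which(runif(nrow(nuc)) < params$boundary_enrichment)
    if (length(sel) > 0) {
      moved <- .relocate_to_band(length(sel), geom, params$band_width_nm)
      nuc$x_nm[sel] <- moved$x_nm
      nuc$y_nm[sel] <- moved$y_nm
    }
  }
  out <- rbind(
    if (nrow(nuc)) cbind(nuc, compartment = "nucleus") else NULL,
    if (nrow(cyt)) cbind(cyt, compartment = "cytoplasm") else NULL
  )
  if (is.null(out)) {
    out <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      compartment = character(0))
  }
  out$cell_id <- rep(geom$cell_id, nrow(out))
  rownames(out) <- NULL
  out[, c("x_nm", "y_nm", "cell_id", "compartment")]
}

#' Simulate a ground-truthed field of cells
#'
#' Convenience wrapper: one [sample_point_pattern()] per geometry, with
#' per-cell seeds derived deterministically from `seed`.
#'
#' @param geoms list of `cell_geometry` objects.
#' @param params a [phenotype_params()] object (shared by all cells).
#' @param seed integer seed.
#' @return object of class `ground_truth`: list with `spots` (one data frame
#'   for all cells), `geometry`, `params` and `seed`.
#' @export
simulate_cells <- function(geoms, params, seed = 1) {
  spots <- withr::with_seed(seed, {
    do.call(rbind, lapply(geoms, function(g) .sample_point_pattern_impl(g, params)))
  })
  structure(list(spots = spots, geometry = geoms, params = params, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d spots in %d cells (%s, %s)\n",
              nrow(x$spots), length(x$geometry),
              x$params$group_label, x$params$cluster_mode))
  invisible(x)
}
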