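# Shared fixtures: analytic geometries at beta-cell scale, built in code.

# one representative beta cell: 12 x 11 um cell, 8 x 7 um nucleus
canonical_cell <- function(theta = 0.3) {
  structure(list(
    cell_id = 1L,
    centre_nm = c(8000, 8000),
    cell_axes_nm = c(6000, 5500),
    nucleus_axes_nm = c(4000, 3500),
    theta = theta,
    pixel_size_nm = 100,
    canvas_px = c(160, 160)
  ), class = "cell_geometry")
}

# disc-shaped cell with a point-like nucleus, for analytic location nulls
disc_cell <- function(R_nm = 5000, nucleus_nm = 1) {
  structure(list(
    cell_id = 1L,
    centre_nm = c(6000, 6000),
    cell_axes_nm = c(R_nm, R_nm),
    nucleus_axes_nm = c(nucleus_nm, nucleus_nm),
    theta = 0,
    pixel_size_nm = 100,
    canvas_px = c(120, 120)
  ), class = "cell_geometry")
}

# per-cell H(457) of nuclear spots for one generated pattern
h457_nuclear <- function(geom, params, seed) {
  s <- sample_point_pattern(geom, params, seed)
  s <- s[s$compartment == "nucleus", , drop = FALSE]
  if (nrow(s) < 2) return(NA_real_)
  rc <- ripley_k(cbind(s$x_nm, s$y_nm), ellipse_window(geom, "nucleus"),
                 correction = "border")
  ripley_h_at(rc, 457)
}

# synthetic feature table for classifier unit tests (no imaging involved)
fake_features <- function(n, seed, count_shift = 0, h_shift = 0) {
  withr::with_seed(seed, data.frame(
    cell_id = seq_len(n),
    g1_total_count = rpois(n, 40 + count_shift),
    g1_nuclear_count = rpois(n, 20),
    g1_cyto_count = rpois(n, 20),
    g1_nc_ratio = exp(rnorm(n, 0, 0.3)),
    g2_mean_norm_radial = runif(n, 0.4, 0.8),
    g2_radial_dispersion = runif(n, 0.1, 0.3),
    g2_mean_dist_to_nuc_boundary_nm = rnorm(n, 200, 100),
    g3_H_nuc_at_r457 = rnorm(n, h_shift, 30),
    g3_H_cyto_at_r457 = rnorm(n, 0, 30),
    g3_H_nuc_max = rnorm(n, h_shift, 40),
    g4_boundary_fraction = runif(n, 0.1, 0.4),
    g4_boundary_H_at_r457 = rnorm(n, 0, 20),
    morph_area_um2 = rnorm(n, 40, 5),
    morph_perimeter_um = rnorm(n, 23, 2),
    morph_eccentricity = runif(n, 0.2, 0.7),
    morph_solidity = runif(n, 0.95, 1),
    imputed = runif(n) < 0.05
  ))
}

# feature table for a generated phenotype: geometry + spots + features
phenotype_features <- function(n_cells, params, geom_seed, spot_seed) {
  geoms <- make_cell_geometry(n_cells, seed = geom_seed)
  tr <- simulate_cells(geoms, params, seed = spot_seed)
  compute_feature_table(tr$spots, geoms)
}
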