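# The synthetic-data generator: geometry placement, spot sampling, image
# rendering and cohort tables.

test_that("cell geometries are valid, nested and seed-deterministic", {
  g1 <- make_cell_geometry(3, pixel_size_nm = 100, seed = 1)
  g2 <- make_cell_geometry(3, pixel_size_nm = 100, seed = 1)
  expect_identical(g1, g2)
  for (g in g1) {
    expect_true(all(g$nucleus_axes_nm < g$cell_axes_nm))
    frac <- prod(g$nucleus_axes_nm) / prod(g$cell_axes_nm)
    expect_gte(frac, 0.2)
    expect_lte(frac, 0.5)
  }
  expect_error(make_cell_geometry(100, seed = 1, canvas_px = 120),
               "could not place|too small")
})

test_that("50 placed cells have pairwise-disjoint pixel masks", {
  geoms <- make_cell_geometry(50, seed = 7, cell_axis_px = c(15, 25))
  px <- geoms[[1]]$pixel_size_nm
  pix <- lapply(geoms, function(g) {
    rmax <- max(g$cell_axes_nm) / px
    c_px <- g$centre_nm / px
    jr <- floor(c_px[1] - rmax):ceiling(c_px[1] + rmax)
    ir <- floor(c_px[2] - rmax):ceiling(c_px[2] + rmax)
    xx <- rep(jr, each = length(ir)) * px
    yy <- rep(ir, times = length(jr)) * px
    keep <- point_in_region(g, xx, yy, "cell")
    paste(rep(jr, each = length(ir))[keep], rep(ir, times = length(jr))[keep])
  })
  all_pix <- unlist(pix)
  expect_identical(anyDuplicated(all_pix), 0L)
})

test_that("spot counts are Poisson with the requested mean", {
  g <- canonical_cell()
  pp <- phenotype_params("control", mean_spots_per_cell = 40)
  counts <- vapply(1:500, function(i) {
    nrow(sample_point_pattern(g, pp, seed = i))
  }, numeric(1))
  se <- sqrt(40 / 500)
  expect_lt(abs(mean(counts) - 40), 3 * se)
})

test_that("compartment labels agree with recomputed region membership", {
  g <- canonical_cell(theta = 1.1)
  for (pp in list(phenotype_preset("control"), phenotype_preset("t1d"))) {
    s <- sample_point_pattern(g, pp, seed = 42)
    expect_true(all(point_in_region(g, s$x_nm, s$y_nm, "cell")))
    in_nuc <- point_in_region(g, s$x_nm, s$y_nm, "nucleus")
    expect_identical(s$compartment == "nucleus", in_nuc)
  }
})

test_that("degenerate nuclear fractions allocate all spots to one compartment", {
  g <- canonical_cell()
  all_nuc <- sample_point_pattern(
    g, phenotype_params("control", nuclear_fraction = 1), seed = 5)
  expect_true(all(all_nuc$compartment == "nucleus"))
  all_cyt <- sample_point_pattern(
    g, phenotype_params("control", nuclear_fraction = 0), seed = 5)
  expect_true(all(all_cyt$compartment == "cytoplasm"))
})

test_that("clustered mode shrinks nearest-neighbour distances vs CSR", {
  g <- canonical_cell()
  nn_mean <- function(mode, seed_off) {
    pp <- phenotype_params("control", mean_spots_per_cell = 60,
                           nuclear_fraction = 1, cluster_mode = mode,
                           cluster_sigma_nm = 200)
    mean(vapply(1:100, function(i) {
      s <- sample_point_pattern(g, pp, seed = seed_off + i)
      if (nrow(s) < 2) return(NA_real_)
      D <- as.matrix(dist(cbind(s$x_nm, s$y_nm)))
      diag(D) <- Inf
      mean(apply(D, 1, min))
    }, numeric(1)), na.rm = TRUE)
  }
  expect_lt(nn_mean("clustered", 100), nn_mean("csr", 100))
})

test_that("boundary enrichment relocates nuclear spots into the band", {
  g <- canonical_cell()
  pp <- phenotype_params("t1d", mean_spots_per_cell = 80,
                         nuclear_fraction = 1, boundary_enrichment = 1,
                         band_width_nm = 500)
  s <- sample_point_pattern(g, pp, seed = 3)
  depth <- -nucleus_boundary_distance(g, s$x_nm, s$y_nm)
  expect_true(all(depth >= 0 & depth <= 500 + 1e-6))
})

test_that("pattern generation is bit-reproducible and fields simulate", {
  geoms <- make_cell_geometry(4, seed = 2)
  pp <- phenotype_preset("aab_pos")
  t1 <- simulate_cells(geoms, pp, seed = 9)
  t2 <- simulate_cells(geoms, pp, seed = 9)
  expect_identical(t1$spots, t2$spots)
  expect_setequal(unique(t1$spots$cell_id), 1:4)
})

test_that("rendering places PSF peaks at spot pixels and respects emptiness", {
  geoms <- make_cell_geometry(1, seed = 4)
  g <- geoms[[1]]
  truth <- structure(list(
    spots = data.frame(x_nm = 5000, y_nm = 6000, cell_id = 1L,
                       compartment = "cytoplasm"),
    geometry = geoms, params = phenotype_preset("control"), seed = 1
  ), class = "ground_truth")
  img <- render_image(truth, psf_sigma_px = 1.5, background = 0.1,
                      noise_sd = 0)
  pk <- which(img$spots == max(img$spots), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(60, 50))   # row = y, col = x
  empty <- truth
  empty$spots <- truth$spots[0, ]
  img0 <- render_image(empty, background = 0.1, noise_sd = 0)
  expect_true(all(img0$spots == 0.1))
  outside <- truth
  outside$spots$x_nm <- 1e9
  expect_error(render_image(outside), "outside the canvas")
})

test_that("two spots 10 px apart render as exactly two maxima above background", {
  geoms <- make_cell_geometry(1, seed = 4)
  truth <- structure(list(
    spots = data.frame(x_nm = c(5000, 6000), y_nm = c(6000, 6000),
                       cell_id = 1L, compartment = "cytoplasm"),
    geometry = geoms, params = phenotype_preset("control"), seed = 1
  ), class = "ground_truth")
  img <- render_image(truth, psf_sigma_px = 1.5, background = 0.1,
                      noise_sd = 0)$spots
  n <- nrow(img)
  is_max <- 0L
  for (i in 2:(n - 1)) for (j in 2:(ncol(img) - 1)) {
    v <- img[i, j]
    if (v > 0.1 + 1e-9 && v == max(img[(i - 1):(i + 1), (j - 1):(j + 1)]) &&
        sum(img[(i - 1):(i + 1), (j - 1):(j + 1)] == v) == 1) {
      is_max <- is_max + 1L
    }
  }
  expect_identical(is_max, 2L)
})

test_that("cohort tables honour the log-normal model and the seed", {
  sp <- cohort_spec(seed = 11)
  t1 <- generate_cohort_table(sp)
  t2 <- generate_cohort_table(sp)
  expect_identical(t1, t2)
  expect_equal(as.integer(table(t1$group)[c("control", "aab_pos", "t1d")]),
               c(26L, 8L, 20L))
  # degenerate noise: every sample equals exp(group mean) exactly
  sp0 <- cohort_spec(n_per_group = c(a = 3, b = 3),
                     analyte_names = "m",
                     group_log_means = matrix(c(1, 2), nrow = 1,
                                              dimnames = list("m", c("a", "b"))),
                     log_sd = 1e-12, seed = 1)
  t0 <- generate_cohort_table(sp0)
  expect_equal(t0$m, exp(c(1, 1, 1, 2, 2, 2)), tolerance = 1e-9)
  expect_error(cohort_spec(group_log_means = matrix(Inf, 5, 3)), "finite")
})

test_that("a 1-log-unit group shift is detected by a rank test", {
  sp <- cohort_spec(n_per_group = c(a = 200, b = 200),
                    analyte_names = "m",
                    group_log_means = matrix(c(2, 3), nrow = 1,
                                             dimnames = list("m", c("a", "b"))),
                    log_sd = 0.8, seed = 21)
  tab <- generate_cohort_table(sp)
  p <- wilcox.test(m ~ group, data = tab)$p.value
  expect_lt(p, 0.001)
})

test_that("params and images round-trip through YAML and TIFF", {
  pp <- phenotype_preset("t1d")
  f <- tempfile(fileext = ".yaml")
  write_params_yaml(pp, f)
  expect_equal(read_params_yaml(f), pp)
  geoms <- make_cell_geometry(1, seed = 4)
  tr <- simulate_cells(geoms, phenotype_preset("control"), seed = 2)
  img <- render_image(tr, noise_sd = 0)
  tf <- tempfile(fileext = ".tif")
  write_image_tiff(img, tf)
  back <- read_image_tiff(tf, pixel_size_nm = img$pixel_size_nm)
  expect_identical(back$cell_labels, img$cell_labels)
  expect_identical(back$nucleus_labels, img$nucleus_labels)
  expect_lt(max(abs(back$spots - img$spots)), 1e-4)
})
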