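# Pairwise classification: splits, ROC/AUC, feature sets, importance
# ranking and the per-cell heatmap.

test_that("stratified splits have exact arithmetic and are reproducible", {
  labels <- rep(c("a", "b"), each = 50)
  sp <- split_train_test(labels, 0.8, seed = 1)
  expect_identical(length(sp$train), 80L)
  expect_identical(length(sp$test), 20L)
  expect_identical(as.integer(table(labels[sp$train])), c(40L, 40L))
  expect_identical(as.integer(table(labels[sp$test])), c(10L, 10L))
  expect_identical(sp, split_train_test(labels, 0.8, seed = 1))
  expect_error(split_train_test(c("a", "b", "b"), 0.8, 1), "at least 2")
})

test_that("splits are disjoint and exhaustive for 100 random seeds", {
  labels <- rep(c("a", "b", "c"), times = c(37, 21, 42))
  for (s in 1:100) {
    sp <- split_train_test(labels, 0.8, seed = s)
    expect_identical(length(intersect(sp$train, sp$test)), 0L)
    expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))
  }
})

test_that("empirical ROC/AUC agrees with the rank statistic and pROC", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      scores <- round(rnorm(80), 1)            # rounding forces ties
      labels <- rbinom(80, 1, 0.5) == 1
      if (!any(labels) || all(labels)) next
      roc <- empirical_roc(scores, labels)
      expect_lt(abs(roc$auc - empirical_auc(scores, labels)), 1e-9)
      expect_equal(roc$auc,
                   as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                  quiet = TRUE))))
      expect_true(all(diff(roc$roc_points$fpr) >= 0))
      expect_true(all(diff(roc$roc_points$tpr) >= 0))
      expect_equal(unlist(roc$roc_points[1, ]), c(fpr = 0, tpr = 0))
      expect_equal(unlist(roc$roc_points[nrow(roc$roc_points), ]),
                   c(fpr = 1, tpr = 1))
    }
  })
})

test_that("empirical AUC equals the brute-force concordance count", {
  withr::with_seed(4, {
    for (rep in 1:10) {
      n1 <- sample(3:25, 1); n0 <- sample(3:25, 1)
      scores <- c(round(rnorm(n1, 1), 1), round(rnorm(n0), 1))
      labels <- rep(c(TRUE, FALSE), c(n1, n0))
      conc <- 0
      for (i in which(labels)) for (j in which(!labels)) {
        conc <- conc + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
      }
      expect_equal(empirical_auc(scores, labels), conc / (n1 * n0))
    }
  })
})

test_that("permuted labels give null AUC; disjoint counts give AUC 1", {
  feats <- fake_features(500, seed = 10)
  null_labels <- withr::with_seed(11, sample(rep(c("a", "b"), each = 250)))
  rep_null <- train_pairwise(feats, null_labels, c("a", "b"),
                             "spatial_full", split_seed = 1, model_seed = 1)
  expect_gte(rep_null$auc, 0.4)
  expect_lte(rep_null$auc, 0.6)
  sep <- rbind(fake_features(100, seed = 12),
               fake_features(100, seed = 13, count_shift = 200))
  sep$cell_id <- seq_len(200)
  rep_sep <- train_pairwise(sep, rep(c("a", "b"), each = 100), c("a", "b"),
                            "expression_only", split_seed = 2, model_seed = 2)
  expect_equal(rep_sep$auc, 1.0)
})

test_that("feature sets audit their columns", {
  feats <- fake_features(10, seed = 1)
  expect_false(any(grepl("^morph_", feature_set_columns(feats, "spatial_full"))))
  expr_cols <- feature_set_columns(feats, "expression_only")
  expect_false(any(grepl("^g[234]_", expr_cols)))
  expect_true(all(grepl("^g1_", expr_cols)))
  morph_cols <- feature_set_columns(feats, "morphology_only")
  expect_true(all(grepl("^morph_", morph_cols)))
  expect_true("imputed" %in% feature_set_columns(feats, "spatial_full"))
})

test_that("reports are bit-reproducible given both seeds", {
  feats <- fake_features(200, seed = 20, h_shift = 0)
  labels <- rep(c("a", "b"), each = 100)
  r1 <- train_pairwise(feats, labels, c("a", "b"), split_seed = 5, model_seed = 6)
  r2 <- train_pairwise(feats, labels, c("a", "b"), split_seed = 5, model_seed = 6)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$importance, r2$importance)
  expect_identical(r1$roc_points, r2$roc_points)
})

test_that("constant feature columns are dropped with a warning", {
  feats <- fake_features(60, seed = 30)
  feats$g4_boundary_fraction <- 0.25
  feats$imputed <- FALSE
  expect_warning(
    train_pairwise(feats, rep(c("a", "b"), each = 30), c("a", "b"),
                   split_seed = 1, model_seed = 1),
    "constant")
})

test_that("a planted informative feature tops the importance ranking", {
  wins <- 0L
  for (s in 1:100) {
    feats <- fake_features(120, seed = 100 + s)
    labels <- rep(c("a", "b"), each = 60)
    feats$g3_H_nuc_at_r457 <- rnorm(120, ifelse(labels == "b", 120, 0), 30)
    rep_s <- train_pairwise(feats, labels, c("a", "b"), "spatial_full",
                            split_seed = s, model_seed = s, ntree = 100)
    top <- rank_features(rep_s, 1)$feature
    if (identical(top, "g3_H_nuc_at_r457")) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("all-noise importances stay balanced and top_k is honoured", {
  shares <- vapply(1:50, function(s) {
    feats <- fake_features(150, seed = 300 + s)
    rep_s <- train_pairwise(feats, rep(c("a", "b"), each = 75), c("a", "b"),
                            "spatial_full", split_seed = s, model_seed = s,
                            ntree = 100)
    imp <- rep_s$importance
    max(imp) / mean(imp)
  }, numeric(1))
  expect_gte(mean(shares < 3), 0.95)
  feats <- fake_features(60, seed = 2)
  rep0 <- train_pairwise(feats, rep(c("a", "b"), each = 30), c("a", "b"),
                         split_seed = 1, model_seed = 1, ntree = 50)
  expect_identical(nrow(rank_features(rep0, 0)), 0L)
  full <- rank_features(rep0, 1000)
  expect_identical(nrow(full), length(rep0$importance))
  expect_true(all(diff(full$importance) <= 0))
})

test_that("cell heatmaps render deterministically and encode the values", {
  geoms <- make_cell_geometry(3, seed = 40)
  feats <- data.frame(cell_id = c(1L, 2L),   # cell 3 has no feature row
    g3_H_nuc_at_r457 = c(0, 1))
  f <- tempfile(fileext = ".png")
  cols <- expect_warning(
    cell_heatmap(feats, "g3_H_nuc_at_r457", geoms[1:2], f),
    regexp = NA)
  expect_true(file.exists(f))
  pal <- hcl.colors(256, "viridis")
  expect_identical(unname(cols), pal[c(1, 256)])   # endpoints of the palette
  # uniform values: middle colour, no error from the degenerate range
  feats$g3_H_nuc_at_r457 <- c(2, 2)
  cell_heatmap(feats, "g3_H_nuc_at_r457", geoms[1:2], f)
  # missing geometry warns
  expect_warning(cell_heatmap(data.frame(cell_id = c(1L, 9L), v = c(0, 1)),
                              "v", geoms[1:2], f), "no geometry")
  expect_error(cell_heatmap(feats, "nope", geoms, f), "not present")
  # read-back: both mapped fill colours appear with cell-sized areas
  feats2 <- data.frame(cell_id = c(1L, 2L), v = c(0, 1))
  f2 <- tempfile(fileext = ".png")
  cell_heatmap(feats2, "v", geoms[1:2], f2,
               palette = function(n) grDevices::gray.colors(n, 0.2, 0.8))
  img <- png::readPNG(f2)
  lum <- img[, , 1]
  dark <- sum(abs(lum - 0.2) < 0.03)     # cell with value 0
  light <- sum(abs(lum - 0.8) < 0.03)    # cell with value 1
  expect_gt(dark, 500)
  expect_gt(light, 500)
})
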