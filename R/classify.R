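# Supervised pairwise classification of cells from feature vectors, ROC
# comparison across feature sets, feature ranking and per-cell heatmaps.

#' Empirical ROC curve and AUC
#'
#' Builds the ROC polygon by sweeping the decision threshold over the unique
#' scores (ties collapse into diagonal segments) and returns the trapezoidal
#' AUC, which equals the normalised Mann--Whitney U statistic of the scores.
#'
#' @param scores numeric scores, larger = more like the positive class.
#' @param labels logical or 0/1 vector, `TRUE` = positive class.
#' @return list with `roc_points` (data frame `fpr`, `tpr` from (0,0) to
#'   (1,1)) and `auc`.
#' @export
empirical_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels),
            any(labels), any(!labels))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores so ties produce a single diagonal step
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y, grp, sum)
  fp <- tapply(!y, grp, sum)
  tpr <- c(0, cumsum(tp) / sum(labels))
  fpr <- c(0, cumsum(fp) / sum(!labels))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc_points = data.frame(fpr = as.numeric(fpr), tpr = as.numeric(tpr)),
       auc = as.numeric(auc))
}

#' Empirical AUC (rank form)
#'
#' Mann--Whitney form of the AUC: the probability that a random positive
#' scores above a random negative, with ties counting one half.
#'
#' @inheritParams empirical_roc
#' @return AUC in `[0, 1]`.
#' @export
empirical_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  stopifnot(n1 > 0, n0 > 0)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified train/test split
#'
#' Splits cells into disjoint, exhaustive train and test sets, stratified by
#' label: per class, `round(n_class * train_fraction)` cells go to training.
#' Deterministic given `seed`.
#'
#' @param labels per-cell class labels.
#' @param train_fraction fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, train_fraction = 0.8, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  tab <- table(labels)
  if (any(tab < 2)) stop("every class needs at least 2 cells to split")
  withr::with_seed(seed, {
    train <- unlist(lapply(names(tab), function(cl) {
      idx <- which(labels == cl)
      sample(idx, round(length(idx) * train_fraction))
    }), use.names = FALSE)
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Feature-set column selection
#'
#' `spatial_full` uses all four feature groups plus the imputation flag;
#' `expression_only` uses the group-1 columns; `morphology_only` uses the
#' nucleus-morphology columns.
#'
#' @param features feature data frame.
#' @param feature_set one of `"spatial_full"`, `"expression_only"`,
#'   `"morphology_only"`.
#' @return character vector of column names.
#' @export
feature_set_columns <- function(features,
                                feature_set = c("spatial_full",
                                                "expression_only",
                                                "morphology_only")) {
  feature_set <- match.arg(feature_set)
  nm <- names(features)
  switch(feature_set,
    spatial_full = nm[grepl("^g[1-4]_", nm) | nm == "imputed"],
    expression_only = nm[grepl("^g1_", nm)],
    morphology_only = nm[grepl("^morph_", nm)]
  )
}

#' Train and evaluate one pairwise classifier
#'
#' Fits a bagged decision-tree ensemble (a random forest with `mtry` equal
#' to the number of predictors, i.e. plain bagging) on the training cells of
#' the two requested classes and evaluates ROC/AUC and accuracy on the
#' held-out test cells. Constant feature columns are dropped with a warning.
#'
#' @param features feature data frame (one row per cell).
#' @param labels per-cell class labels aligned with `features`.
#' @param pair character vector of the two class labels; the second is
#'   treated as the positive class.
#' @param feature_set see [feature_set_columns()].
#' @param train_fraction passed to [split_train_test()].
#' @param split_seed,model_seed seeds for the split and the ensemble fit;
#'   reports are bit-reproducible given both.
#' @param ntree number of trees (default 500).
#' @return object of class `classifier_report`: `pair`, `feature_set`,
#'   `auc`, `roc_points`, `test_accuracy`, `split_seed`, `model_seed`,
#'   `importance` (named impurity-decrease importances) and `n_train`,
#'   `n_test`.
#' @export
train_pairwise <- function(features, labels, pair,
                           feature_set = "spatial_full",
                           train_fraction = 0.8,
                           split_seed = 1, model_seed = 1, ntree = 500) {
  stopifnot(length(pair) == 2, all(pair %in% labels))
  keep <- labels %in% pair
  feats <- features[keep, , drop = FALSE]
  labs <- factor(labels[keep], levels = pair)
  cols <- feature_set_columns(feats, feature_set)
  X <- feats[, cols, drop = FALSE]
  X[] <- lapply(X, as.numeric)
  const <- vapply(X, function(v) length(unique(v)) < 2, logical(1))
  if (any(const)) {
    warning("dropping constant feature column(s): ",
            paste(names(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no non-constant feature columns left")
  sp <- split_train_test(labs, train_fraction, split_seed)
  fit <- withr::with_seed(model_seed,
    randomForest::randomForest(x = X[sp$train, , drop = FALSE],
                               y = labs[sp$train],
                               ntree = ntree, mtry = ncol(X)))
  prob <- predict(fit, X[sp$test, , drop = FALSE], type = "prob")[, pair[2]]
  pred <- predict(fit, X[sp$test, , drop = FALSE])
  roc <- empirical_roc(prob, labs[sp$test] == pair[2])
  imp <- fit$importance[, "MeanDecreaseGini"]
  structure(list(
    pair = pair,
    feature_set = feature_set,
    auc = roc$auc,
    roc_points = roc$roc_points,
    test_accuracy = mean(pred == labs[sp$test]),
    split_seed = split_seed,
    model_seed = model_seed,
    importance = imp,
    n_train = length(sp$train),
    n_test = length(sp$test)
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("classifier_report: %s vs %s [%s]\n  AUC = %.3f, accuracy = %.3f (train %d / test %d)\n",
              x$pair[1], x$pair[2], x$feature_set, x$auc, x$test_accuracy,
              x$n_train, x$n_test))
  invisible(x)
}

#' Rank features by classifier importance
#'
#' @param report a `classifier_report`.
#' @param top_k number of features to return; larger than the number of
#'   features returns the full list, 0 an empty one.
#' @return data frame `feature`, `importance`, sorted by decreasing
#'   importance with ties broken lexicographically by feature name.
#' @export
rank_features <- function(report, top_k = 10L) {
  stopifnot(inherits(report, "classifier_report"), top_k >= 0)
  imp <- report$importance
  ord <- order(-imp, names(imp))
  out <- data.frame(feature = names(imp)[ord],
                    importance = as.numeric(imp[ord]))
  head(out, min(top_k, nrow(out)))
}

#' Export a report as JSON
#'
#' @param report a `classifier_report`.
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(
    pair = report$pair, feature_set = report$feature_set,
    auc = report$auc, test_accuracy = report$test_accuracy,
    split_seed = report$split_seed, model_seed = report$model_seed,
    importance = as.list(report$importance)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
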