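# Biomarker-panel stage: differential-expression filtering, group
# comparisons and multi-algorithm ensemble feature ranking for EV-miRNA
# cohort tables.

#' Differential-expression filter
#'
#' Keeps analytes with fold change at least `fc_min` in either direction
#' (fold changes are ratios, so down-regulation is tested against
#' `1 / fc_min`) and p value strictly below `p_max`. Row order is preserved
#' and the filter is idempotent.
#'
#' @param rows data frame with columns `fold_change` (> 0) and `p_value`.
#' @param fc_min minimum fold change (> 1), default 1.5.
#' @param p_max exclusive p-value threshold in (0, 1), default 0.05.
#' @return the surviving rows.
#' @examples
#' de_filter(data.frame(analyte = c("a", "b"),
#'                      fold_change = c(2, 1.2), p_value = c(0.01, 0.01)))
#' @export
de_filter <- function(rows, fc_min = 1.5, p_max = 0.05) {
  stopifnot(fc_min > 1, p_max > 0, p_max < 1,
            all(c("fold_change", "p_value") %in% names(rows)))
  if (any(rows$fold_change <= 0)) stop("fold changes must be positive ratios")
  keep <- (rows$fold_change >= fc_min | rows$fold_change <= 1 / fc_min) &
    rows$p_value < p_max
  rows[keep, , drop = FALSE]
}

#' Group comparisons for one analyte
#'
#' One-way ANOVA across all groups plus Mann--Whitney U tests for every
#' group pair, with per-group summaries. Data that are constant across all
#' groups take the degenerate path F = 0, p = 1 rather than dividing by a
#' zero variance.
#'
#' @param table cohort data frame with a `group` column and one column per
#'   analyte (see [generate_cohort_table()]).
#' @param analyte name of the analyte column.
#' @param group_col name of the group column.
#' @return list with `anova` (`F`, `p`, `df`), `pairwise` (data frame
#'   `group1`, `group2`, `U`, `p`) and `summary` (per-group `n`, `mean`,
#'   `sd`).
#' @export
group_compare <- function(table, analyte, group_col = "group") {
  stopifnot(analyte %in% names(table), group_col %in% names(table))
  x <- table[[analyte]]
  g <- factor(table[[group_col]])
  if (any(tapply(x, g, length) < 2)) stop("every group needs >= 2 samples")
  summ <- data.frame(
    group = levels(g),
    n = as.integer(tapply(x, g, length)),
    mean = as.numeric(tapply(x, g, mean)),
    sd = as.numeric(tapply(x, g, sd))
  )
  if (diff(range(x)) == 0) {
    an <- list(F = 0, p = 1, df = c(nlevels(g) - 1L, length(x) - nlevels(g)))
  } else {
    a <- anova(lm(x ~ g))
    an <- list(F = a$`F value`[1], p = a$`Pr(>F)`[1], df = a$Df)
  }
  pairs <- combn(levels(g), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    x1 <- x[g == g1]; x2 <- x[g == g2]
    if (diff(range(c(x1, x2))) == 0) {
      U <- length(x1) * length(x2) / 2
      p <- 1
    } else {
      wt <- suppressWarnings(wilcox.test(x1, x2))
      U <- unname(wt$statistic)
      p <- wt$p.value
    }
    data.frame(group1 = g1, group2 = g2, U = U, p = p)
  }))
  list(anova = an, pairwise = pw, summary = summ)
}

# ---- ensemble ranking ------------------------------------------------------

# per-algorithm raw importances on standardised features; larger = better.
# Constant analytes receive -Inf so every algorithm ranks them last.
.imp_lvq <- function(X, y) {
  cb <- class::olvq1(X, y, class::lvqinit(X, y))
  pa <- colMeans(cb$x[cb$cl == levels(y)[1], , drop = FALSE])
  pb <- colMeans(cb$x[cb$cl == levels(y)[2], , drop = FALSE])
  abs(pa - pb)
}

.imp_dt <- function(X, y) {
  safe <- paste0("V", seq_len(ncol(X)))     # analyte names may be non-syntactic
  df <- as.data.frame(X)
  names(df) <- safe
  df$.y <- y
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(cp = 0, minsplit = 5,
                                                     xval = 0))
  imp <- setNames(rep(0, ncol(X)), safe)
  vi <- fit$variable.importance
  imp[names(vi)] <- vi
  setNames(imp, colnames(X))
}

.imp_rf <- function(X, y) {
  fit <- randomForest::randomForest(X, y, ntree = 500)
  fit$importance[colnames(X), "MeanDecreaseGini"]
}

.imp_svm <- function(X, y) {
  fit <- e1071::svm(X, y, kernel = "linear", scale = FALSE)
  w <- t(fit$coefs) %*% fit$SV
  setNames(abs(as.numeric(w)), colnames(X))
}

# Feature reconstruction error: increase in the least-squares error of a
# rank-k linear reconstruction of the standardised data matrix when the
# feature is withheld from the basis. k = min(3, p - 1).
.imp_fre <- function(X, y) {
  p <- ncol(X)
  k <- min(3L, p - 1L)
  recon_err <- function(basis_cols) {
    B <- X[, basis_cols, drop = FALSE]
    sv <- svd(B, nu = min(k, ncol(B)), nv = 0)
    U <- sv$u[, seq_len(min(k, ncol(B))), drop = FALSE]
    R <- X - U %*% (t(U) %*% X)
    sum(R^2)
  }
  e_full <- recon_err(seq_len(p))
  vapply(seq_len(p), function(j) recon_err(setdiff(seq_len(p), j)) - e_full,
         numeric(1))
}

#' Ensemble feature ranking across five algorithms
#'
#' Ranks analytes by their ability to separate two groups, combining five
#' importance measures: learning vector quantisation (LVQ, prototype
#' separation), a single decision tree (DT, impurity decrease including
#' surrogates), a random forest (RF, ensemble impurity decrease), a linear
#' support-vector machine (SVM, absolute hyperplane weight) and the feature
#' reconstruction error (FRE, increase in rank-k linear reconstruction error
#' when the feature is withheld). All algorithms operate on standardised
#' abundances, so the ranking is invariant to affine rescaling of any
#' analyte. Each algorithm's importances are converted to a coefficient
#' equal to the rank position (1 = most important, ties broken by analyte
#' name); the aggregate rank orders analytes by the mean coefficient, a
#' lower coefficient indicating better performance across all algorithms.
#' Constant analytes are assigned the worst coefficient by every algorithm.
#'
#' @param table cohort data frame (`group` column + analyte columns).
#' @param groups the two group labels to contrast.
#' @param analytes analyte column names; defaults to all non-id columns.
#' @param seed integer seed (LVQ and RF are stochastic).
#' @return data frame with one row per analyte: per-algorithm coefficients
#'   (`lvq`, `dt`, `rf`, `svm`, `fre`), `mean_coefficient` and
#'   `aggregate_rank` (1 = best).
#' @export
rank_ensemble <- function(table, groups, analytes = NULL, seed = 1) {
  stopifnot(length(groups) == 2, "group" %in% names(table))
  if (is.null(analytes)) {
    analytes <- setdiff(names(table), c("sample_id", "group"))
  }
  keep <- table$group %in% groups
  if (min(table(table$group[keep])) < 3) stop("need >= 3 samples per group")
  X0 <- as.matrix(table[keep, analytes, drop = FALSE])
  y <- factor(table$group[keep], levels = groups)
  const <- apply(X0, 2, function(v) diff(range(v)) == 0)
  Xs <- X0
  Xs[, !const] <- scale(X0[, !const, drop = FALSE])
  Xs[, const] <- 0
  colnames(Xs) <- analytes
  algos <- list(lvq = .imp_lvq, dt = .imp_dt, rf = .imp_rf,
                svm = .imp_svm, fre = .imp_fre)
  coefs <- withr::with_seed(seed, {
    vapply(algos, function(f) {
      imp <- rep(-Inf, length(analytes))
      names(imp) <- analytes
      if (any(!const)) {
        got <- f(Xs[, !const, drop = FALSE], y)
        imp[colnames(Xs)[!const]] <- got
      }
      ord <- order(-imp, analytes)
      rk <- integer(length(imp))
      rk[ord] <- seq_along(imp)
      rk
    }, integer(length(analytes)))
  })
  coefs <- matrix(coefs, nrow = length(analytes),
                  dimnames = list(analytes, names(algos)))
  mean_coef <- rowMeans(coefs)
  ord <- order(mean_coef, analytes)
  agg <- integer(length(analytes))
  agg[ord] <- seq_along(analytes)
  out <- data.frame(analyte = analytes, coefs, mean_coefficient = mean_coef,
                    aggregate_rank = agg, check.names = FALSE,
                    row.names = NULL)
  out[order(out$aggregate_rank), ]
}
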