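#' Specify a synthetic EV-miRNA cohort
#'
#' Describes a three-group cohort (control, autoantibody positive, recent
#' onset type 1 diabetes) of samples by analyte abundance: each measurement
#' is log-normal, `exp(Normal(group_log_mean, log_sd))`, emulating the
#' right-skewed plasma EV miRNA concentrations the panel stage consumes.
#'
#' @param n_per_group named integer vector of group sizes (all >= 2). The
#'   default mirrors the clinical cohort scale: 26 control, 8 AAb+, 20 T1D.
#' @param analyte_names analyte (miRNA) names; default is the five-marker
#'   panel miR-155-5p, miR-146a-5p, miR-30c-1-3p, miR-802, miR-124-3p.
#' @param group_log_means numeric matrix, analytes x groups, of natural-log
#'   mean abundances. The default encodes the reported direction of change:
#'   miR-155-5p/146a-5p/30c-1-3p/802 up and miR-124-3p down in T1D versus
#'   control, with intermediate shifts for miR-146a-5p/802/124-3p in AAb+.
#' @param log_sd log-scale standard deviation (> 0).
#' @param seed integer seed.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group = c(control = 26, aab_pos = 8, t1d = 20),
                        analyte_names = c("miR-155-5p", "miR-146a-5p",
                                          "miR-30c-1-3p", "miR-802",
                                          "miR-124-3p"),
                        group_log_means = NULL,
                        log_sd = 0.8,
                        seed = 1) {
  stopifnot(all(n_per_group >= 2), log_sd > 0, length(analyte_names) >= 1)
  if (is.null(names(n_per_group))) {
    stop("`n_per_group` must be a named vector of group sizes")
  }
  groups <- names(n_per_group)
  if (is.null(group_log_means)) {
    if (!identical(length(analyte_names), 5L) ||
        !identical(groups, c("control", "aab_pos", "t1d"))) {
      stop("default `group_log_means` only covers the default 5-analyte, ",
           "3-group panel; supply a matrix")
    }
    group_log_means <- cbind(
      control = rep(2.3, 5),
      aab_pos = 2.3 + c(0.3, 0.6, 0.2, 0.6, -0.6),
      t1d     = 2.3 + c(1.0, 1.0, 0.8, 1.0, -1.0)
    )
    rownames(group_log_means) <- analyte_names
  }
  group_log_means <- as.matrix(group_log_means)
  if (!all(is.finite(group_log_means))) stop("non-finite group log means")
  stopifnot(nrow(group_log_means) == length(analyte_names),
            ncol(group_log_means) == length(groups))
  structure(list(
    n_per_group = n_per_group,
    analyte_names = analyte_names,
    group_log_means = group_log_means,
    log_sd = log_sd,
    seed = seed
  ), class = "cohort_spec")
}

#' Generate a cohort abundance table
#'
#' @param spec a [cohort_spec()] object.
#' @return data frame with columns `sample_id`, `group` and one abundance
#'   column per analyte; deterministic given `spec$seed`.
#' @examples
#' tab <- generate_cohort_table(cohort_spec(seed = 7))
#' table(tab$group)
#' @export
generate_cohort_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- names(spec$n_per_group)
  withr::with_seed(spec$seed, {
    rows <- lapply(seq_along(groups), function(gi) {
      n <- spec$n_per_group[gi]
      vals <- vapply(seq_along(spec$analyte_names), function(ai) {
        exp(rnorm(n, spec$group_log_means[ai, gi], spec$log_sd))
      }, numeric(n))
      vals <- matrix(vals, nrow = n)
      df <- data.frame(
        sample_id = sprintf("%s_%02d", groups[gi], seq_len(n)),
        group = groups[gi]
      )
      colnames(vals) <- spec$analyte_names
      cbind(df, as.data.frame(vals, check.names = FALSE))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
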