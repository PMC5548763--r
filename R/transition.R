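#' Filter features before cross-condition correlation
#'
#' Two-stage filter applied within one feature class, in this order:
#'
#' 1. *Extreme-intensity cut*: at each time point the intensities of both
#'    conditions are pooled over all same-class features; any feature whose
#'    intensity (in either condition) reaches the top `percentile` or
#'    bottom `percentile` of that pool at any time point is removed
#'    (inclusive thresholds).
#' 2. *Unresponsive cut*: for the survivors, the per-timepoint distribution
#'    of intensity differences (treatment minus control) is formed; a
#'    feature whose absolute difference is within `sd_mult` standard
#'    deviations of that distribution at every time point is removed.
#'
#' The survivor set does not depend on feature order.
#'
#' @param dataset An [expression_dataset].
#' @param class Feature class, one of `"nontf"`, `"tf"`, `"mirna"`,
#'   `"gene"`.
#' @param percentile Tail fraction removed at each end (default 0.01).
#' @param sd_mult Width of the unresponsive band in difference-SD units.
#' @return Character vector of surviving feature ids.
#' @export
filter_for_pcc <- function(dataset, class, percentile = 0.01, sd_mult = 1) {
  ctrl <- intensity_matrix(dataset, class, dataset$conditions[1])
  trt <- intensity_matrix(dataset, class, dataset$conditions[2])
  if (nrow(ctrl) == 0L) stop(sprintf("no features in class '%s'", class))
  keep <- rep(TRUE, nrow(ctrl))
  for (j in seq_len(ncol(ctrl))) {
    pool <- c(ctrl[, j], trt[, j])
    hi <- stats::quantile(pool, 1 - percentile, names = FALSE)
    lo <- stats::quantile(pool, percentile, names = FALSE)
    keep <- keep & ctrl[, j] < hi & trt[, j] < hi &
      ctrl[, j] > lo & trt[, j] > lo
  }
  diffs <- (trt - ctrl)[keep, , drop = FALSE]
  if (nrow(diffs) > 1L) {
    sds <- apply(diffs, 2L, stats::sd)
    unresponsive <- rowSums(sweep(abs(diffs), 2L, sd_mult * sds, `>`)) == 0L
  } else unresponsive <- rep(FALSE, nrow(diffs))
  rownames(ctrl)[keep][!unresponsive]
}

#' Cross-condition Pearson correlation at one time point
#'
#' Correlates the control-condition intensity vector against the
#' treatment-condition intensity vector across a feature subset.
#'
#' @param dataset An [expression_dataset].
#' @param features Character vector of feature ids (>= 3), all of one class.
#' @param timepoint A time-point label of the dataset.
#' @return The Pearson correlation coefficient.
#' @export
condition_pcc <- function(dataset, features, timepoint) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!timepoint %in% dataset$timepoints)
    stop(sprintf("unknown timepoint '%s'", timepoint))
  if (length(features) < 3L)
    stop("at least 3 features are required for a correlation")
  all_feats <- rbind(dataset$genes, dataset$mirnas)
  missing <- setdiff(features, rownames(all_feats))
  if (length(missing)) stop(sprintf("unknown feature '%s'", missing[1]))
  x <- all_feats[features, paste(dataset$conditions[1], timepoint, sep = "_")]
  y <- all_feats[features, paste(dataset$conditions[2], timepoint, sep = "_")]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop(sprintf("zero variance in the %s intensities at %s",
                 if (stats::sd(x) == 0) dataset$conditions[1] else
                   dataset$conditions[2], timepoint))
  stats::cor(x, y)
}

#' Cross-condition correlation profile over time
#'
#' Applies [filter_for_pcc] and [condition_pcc] per feature class and time
#' point and reports, per class, the time point at which the correlation is
#' lowest (the transition point of the response).
#'
#' @param dataset An [expression_dataset].
#' @param classes Feature classes to profile.
#' @param percentile,sd_mult Passed to [filter_for_pcc].
#' @return Data frame with columns `class`, `timepoint`, `pcc`,
#'   `n_features`, plus an attribute `argmin` (named character vector:
#'   class -> time point of minimum correlation).
#' @export
transition_profile <- function(dataset, classes = c("nontf", "tf", "mirna"),
                               percentile = 0.01, sd_mult = 1) {
  rows <- list()
  argmin <- character(0)
  for (cl in classes) {
    feats <- filter_for_pcc(dataset, cl, percentile, sd_mult)
    pccs <- vapply(dataset$timepoints,
                   function(t) condition_pcc(dataset, feats, t), numeric(1))
    rows[[cl]] <- data.frame(class = cl, timepoint = dataset$timepoints,
                             pcc = unname(pccs),
                             n_features = length(feats),
                             stringsAsFactors = FALSE)
    argmin[cl] <- dataset$timepoints[which.min(pccs)]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "argmin") <- argmin
  out
}
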