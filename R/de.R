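#' Call differential expression by the mean +/- 2 SD fold-change rule
#'
#' For each time point, the mean and standard deviation of the log2 fold
#' changes of all features (of one class: genes and miRNAs are thresholded
#' separately) are computed, and a feature is labelled `+1` when its fold
#' change exceeds `mean + k*SD`, `-1` when it falls below `mean - k*SD`, and
#' `0` otherwise. A feature is differentially expressed (DE) when it carries
#' a nonzero label at one or more time points.
#'
#' The envelope is centred at the per-timepoint mean by default; `center =
#' "zero"` centres it at 0. The dispersion uses the sample SD (`n - 1`
#' denominator) by default; `sd_method = "population"` uses `n`.
#'
#' @param fc Numeric matrix of log2 fold changes, features (>= 2) by time
#'   points, finite everywhere.
#' @param k Envelope width in SD units (default 2).
#' @param center `"mean"` or `"zero"`.
#' @param sd_method `"sample"` or `"population"`.
#' @return An object of class `de_calls`: list with `labels` (integer
#'   matrix in \{-1, 0, +1\}), `mean`, `sd`, `upper`, `lower` (per-timepoint
#'   numeric vectors) and `k`.
#' @export
call_de <- function(fc, k = 2, center = c("mean", "zero"),
                    sd_method = c("sample", "population")) {
  center <- match.arg(center)
  sd_method <- match.arg(sd_method)
  if (!is.matrix(fc) || !is.numeric(fc)) stop("'fc' must be a numeric matrix")
  if (nrow(fc) < 2L) stop("at least 2 features are needed to estimate the SD")
  if (anyNA(fc) || any(!is.finite(fc))) stop("'fc' must be finite")
  n <- nrow(fc)
  mu <- if (center == "mean") colMeans(fc) else
    stats::setNames(rep(0, ncol(fc)), colnames(fc))
  s <- apply(fc, 2L, stats::sd)
  if (sd_method == "population") s <- s * sqrt((n - 1) / n)
  upper <- mu + k * s
  lower <- mu - k * s
  labels <- matrix(0L, n, ncol(fc), dimnames = dimnames(fc))
  labels[sweep(fc, 2L, upper, `>`)] <- 1L
  labels[sweep(fc, 2L, lower, `<`)] <- -1L
  structure(list(labels = labels, mean = mu, sd = s,
                 upper = upper, lower = lower, k = k),
            class = "de_calls")
}

#' Features called DE at any time point
#' @param calls A `de_calls` object.
#' @return Character vector of DE feature ids.
#' @export
de_features <- function(calls) {
  stopifnot(inherits(calls, "de_calls"))
  rownames(calls$labels)[rowSums(calls$labels != 0L) > 0L]
}

#' Classify first emergence of DE calls (New+/Old+ sets)
#'
#' For each time point `t`, the up-regulated features split into the New+
#' set (label `+1` at `t` and at no earlier time point) and the Old+ set
#' (label `+1` at `t` and at some earlier time point); the two sets are
#' disjoint and their union is all up-regulated features at `t`. A
#' feature's first emergence is the earliest time point with any nonzero
#' label.
#'
#' @param calls A `de_calls` object.
#' @return An `emergence_table`: list with `first_emergence` (named
#'   character vector, `NA` for never-DE features), `new_up` and `old_up`
#'   (lists of feature-id vectors per time point).
#' @export
classify_emergence <- function(calls) {
  stopifnot(inherits(calls, "de_calls"))
  lab <- calls$labels
  tps <- colnames(lab)
  first_idx <- apply(lab != 0L, 1L, function(z) match(TRUE, z))
  first <- ifelse(is.na(first_idx), NA_character_, tps[first_idx])
  names(first) <- rownames(lab)
  up_before <- matrix(FALSE, nrow(lab), ncol(lab))
  if (ncol(lab) > 1L)
    for (j in 2:ncol(lab))
      up_before[, j] <- up_before[, j - 1L] | lab[, j - 1L] == 1L
  new_up <- old_up <- stats::setNames(vector("list", length(tps)), tps)
  for (j in seq_along(tps)) {
    up <- lab[, j] == 1L
    new_up[[j]] <- rownames(lab)[up & !up_before[, j]]
    old_up[[j]] <- rownames(lab)[up & up_before[, j]]
  }
  structure(list(first_emergence = first, new_up = new_up, old_up = old_up),
            class = "emergence_table")
}

#' Summarize DE calls over time
#'
#' Per-timepoint counts of DE features (any nonzero label), up- and
#' down-regulated features, New+/Old+ set sizes, and the proportion of all
#' DE features whose first emergence falls at that time point.
#'
#' @param calls A `de_calls` object.
#' @param emergence Optional [classify_emergence] result (recomputed when
#'   omitted).
#' @param classes Optional named character vector of feature classes (as
#'   from [feature_classes]); adds per-class DE counts.
#' @return Data frame with one row per time point.
#' @export
de_summary <- function(calls, emergence = NULL, classes = NULL) {
  stopifnot(inherits(calls, "de_calls"))
  if (is.null(emergence)) emergence <- classify_emergence(calls)
  lab <- calls$labels
  tps <- colnames(lab)
  n_de_total <- length(de_features(calls))
  first <- emergence$first_emergence
  out <- data.frame(
    timepoint = tps,
    n_de = colSums(lab != 0L),
    n_up = colSums(lab == 1L),
    n_down = colSums(lab == -1L),
    n_new_up = lengths(emergence$new_up),
    n_old_up = lengths(emergence$old_up),
    first_time_proportion = if (n_de_total)
      vapply(tps, function(t) sum(first == t, na.rm = TRUE), 0) / n_de_total
      else 0,
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(classes)) {
    cls <- classes[rownames(lab)]
    for (cl in unique(stats::na.omit(cls)))
      out[[paste0("n_de_", cl)]] <-
        colSums(lab[!is.na(cls) & cls == cl, , drop = FALSE] != 0L)
  }
  out
}
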