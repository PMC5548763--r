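#' Infer miRNA-to-TF suppression events
#'
#' A DE miRNA is inferred to suppress a DE TF gene at a time point when all
#' three conditions hold: (1) the (miRNA, TF) pair is present in the
#' miRNA-target interaction table, (2) the miRNA is up-regulated (label
#' `+1`) at that time point, and (3) the TF gene is *not* up-regulated there
#' (label 0 or -1). Both features must be DE (nonzero label at some time
#' point); for the miRNA this is implied by condition (2).
#'
#' Table rows whose miRNA or TF id is absent from the respective call table
#' are skipped with a warning.
#'
#' @param calls_mirna,calls_tf `de_calls` objects for miRNAs and TF genes,
#'   sharing the same time-point axis.
#' @param target_table Data frame with columns `regulator` (miRNA id) and
#'   `target` (TF gene id).
#' @return Data frame of events with columns `mirna`, `tf`, `timepoint`,
#'   ordered by miRNA, TF, then time.
#' @export
infer_suppression <- function(calls_mirna, calls_tf, target_table) {
  stopifnot(inherits(calls_mirna, "de_calls"), inherits(calls_tf, "de_calls"))
  tps <- colnames(calls_mirna$labels)
  if (!identical(tps, colnames(calls_tf$labels)))
    stop("miRNA and TF call tables must share the timepoint axis")
  tab <- unique(target_table[, c("regulator", "target")])
  known <- tab$regulator %in% rownames(calls_mirna$labels) &
    tab$target %in% rownames(calls_tf$labels)
  if (any(!known)) {
    bad <- tab[!known, ]
    warning(sprintf("skipping %d interaction row(s) with unknown ids (e.g. %s -> %s)",
                    nrow(bad), bad$regulator[1], bad$target[1]))
    tab <- tab[known, ]
  }
  tf_de <- rowSums(calls_tf$labels != 0L) > 0L
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    m <- tab$regulator[i]
    f <- tab$target[i]
    if (!tf_de[[f]]) next
    hit <- calls_mirna$labels[m, ] == 1L & calls_tf$labels[f, ] != 1L
    if (any(hit))
      rows[[length(rows) + 1L]] <-
        data.frame(mirna = m, tf = f, timepoint = tps[hit],
                   stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), tf = character(),
               timepoint = character(), stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$tf, match(out$timepoint, tps),
                   method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Count suppressing miRNAs and suppressed TFs over time
#'
#' @param events Event data frame from [infer_suppression].
#' @param timepoints Ordered time-point labels (report rows even for time
#'   points with no event).
#' @return List with `per_timepoint` (data frame: `timepoint`,
#'   `n_suppressing_mirnas`, `n_suppressed_tfs`) and `overall` (named list
#'   with the distinct totals across all time points).
#' @export
suppression_counts <- function(events, timepoints) {
  per_tp <- data.frame(
    timepoint = timepoints,
    n_suppressing_mirnas = vapply(timepoints, function(t)
      length(unique(events$mirna[events$timepoint == t])), 0L),
    n_suppressed_tfs = vapply(timepoints, function(t)
      length(unique(events$tf[events$timepoint == t])), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_timepoint = per_tp,
       overall = list(n_suppressing_mirnas = length(unique(events$mirna)),
                      n_suppressed_tfs = length(unique(events$tf))))
}
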