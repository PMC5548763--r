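#' Probe-level intensity matrix
#'
#' Container for raw array intensities before probe-to-gene collapse.
#'
#' @param intensities Numeric matrix, probes (rows, named) by samples
#'   (columns, named with unique `<condition>_<timepoint>` labels).
#' @param probe_gene Optional named character vector mapping probe id to
#'   gene (or miRNA) symbol; names must cover all probes.
#' @param replicate_groups Optional named character/factor vector assigning
#'   each sample column to a replicate group (defaults to singleton groups).
#' @return An object of class `probe_matrix`.
#' @export
probe_matrix <- function(intensities, probe_gene = NULL,
                         replicate_groups = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix")
  if (is.null(rownames(intensities)) || anyDuplicated(rownames(intensities)))
    stop("probes must have unique row names")
  if (is.null(colnames(intensities)) || anyDuplicated(colnames(intensities)))
    stop("samples must have unique column names")
  if (!is.null(probe_gene)) {
    missing <- setdiff(rownames(intensities), names(probe_gene))
    if (length(missing))
      stop(sprintf("probe_gene mapping missing for probe '%s'", missing[1]))
  }
  if (!is.null(replicate_groups)) {
    if (is.null(names(replicate_groups)) ||
        !all(colnames(intensities) %in% names(replicate_groups)))
      stop("replicate_groups must be named by sample")
  }
  structure(list(intensities = intensities, probe_gene = probe_gene,
                 replicate_groups = replicate_groups),
            class = "probe_matrix")
}

.pm_update <- function(pm, intensities) {
  pm$intensities <- intensities
  if (!is.null(pm$probe_gene))
    pm$probe_gene <- pm$probe_gene[rownames(intensities)]
  pm
}

#' Within-array median scaling
#'
#' Rescales each sample by a single positive factor so that every sample's
#' median equals the global reference (by default the median of the sample
#' medians). A global multiplicative rescale leaves fold changes and
#' correlations untouched, so the choice of reference only fixes the
#' intensity unit.
#'
#' @param probes A [probe_matrix].
#' @param reference Target median; default `median(sample medians)`.
#' @return The scaled [probe_matrix]; within-sample rank order is preserved.
#' @export
median_scale <- function(probes, reference = NULL) {
  stopifnot(inherits(probes, "probe_matrix"))
  m <- probes$intensities
  meds <- apply(m, 2L, stats::median)
  if (any(meds <= 0))
    stop(sprintf("sample '%s' has non-positive median; cannot scale",
                 colnames(m)[which(meds <= 0)[1]]))
  if (is.null(reference)) reference <- stats::median(meds)
  .pm_update(probes, sweep(m, 2L, reference / meds, `*`))
}

#' Average replicate samples
#'
#' Replaces each replicate group by its per-probe arithmetic mean (the
#' convention for repeated cDNA hybridizations of the same sample).
#'
#' @param probes A [probe_matrix] with `replicate_groups` set (singleton
#'   groups are allowed and act as the identity).
#' @param combine Averaging function over a group: `"mean"` (cDNA arrays) or
#'   `"median"` (replicate miRNA probes are usually combined upstream; see
#'   [mirna_preprocess]).
#' @return A [probe_matrix] with one column per replicate group, columns
#'   named by group in first-appearance order.
#' @export
average_replicates <- function(probes, combine = c("mean", "median")) {
  stopifnot(inherits(probes, "probe_matrix"))
  combine <- match.arg(combine)
  groups <- probes$replicate_groups
  if (is.null(groups)) stop("replicate grouping is required")
  m <- probes$intensities
  groups <- as.character(groups[colnames(m)])
  if (anyNA(groups)) stop("every sample needs a replicate group")
  ids <- unique(groups)
  f <- if (combine == "mean") rowMeans else
    function(x) apply(x, 1L, stats::median)
  out <- vapply(ids, function(g) f(m[, groups == g, drop = FALSE]),
                numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), ids))
  pm <- .pm_update(probes, out)
  pm$replicate_groups <- NULL
  pm
}

#' Filter low-intensity probes
#'
#' Drops every probe whose intensity is below `min_intensity` (default 1,
#' which also removes negative values) in any sample of either condition.
#' Retained probes are therefore >= 1 everywhere, keeping log2 ratios finite.
#'
#' @param probes A [probe_matrix].
#' @param min_intensity Lower bound applied to every sample.
#' @return The filtered [probe_matrix] (possibly with zero rows).
#' @export
filter_probes <- function(probes, min_intensity = 1) {
  stopifnot(inherits(probes, "probe_matrix"))
  m <- probes$intensities
  keep <- rowSums(m < min_intensity | is.na(m)) == 0L
  .pm_update(probes, m[keep, , drop = FALSE])
}

#' Between-sample quantile normalization
#'
#' Each sample is sorted from highest to lowest; the reference value for a
#' rank position is the median across samples of the values at that
#' position; each sample's value is then re-assigned the reference value of
#' its rank. Ties within a sample are broken by original row order (stable),
#' and all samples end up with the identical multiset of values. The
#' operation is idempotent.
#'
#' @param x A [probe_matrix] or a plain numeric matrix (features x samples).
#' @return Object of the same type as `x`.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "probe_matrix"))
    return(.pm_update(x, quantile_normalize(x$intensities)))
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix")
  if (nrow(x) == 0L || ncol(x) < 2L) return(x)
  # column j sorted descending at each rank; reference = per-rank median
  ord <- apply(x, 2L, order, decreasing = TRUE, method = "radix")
  sorted <- vapply(seq_len(ncol(x)), function(j) x[ord[, j], j],
                   numeric(nrow(x)))
  ref <- apply(sorted, 1L, stats::median)
  out <- x
  for (j in seq_len(ncol(x))) out[ord[, j], j] <- ref
  out
}

#' Collapse probes to genes by maximum absolute fold change
#'
#' When several probes map to one gene, the probe whose per-timepoint
#' absolute log2 fold changes have the largest sum over all time points is
#' kept to represent the gene. Fold changes must be computed per probe from
#' the post-normalization intensities.
#'
#' @param probes A [probe_matrix] with a `probe_gene` mapping.
#' @param fold_changes_per_probe Numeric matrix, probes by time points, of
#'   log2 fold changes; row names must cover the probes.
#' @return Numeric matrix of intensities with one row per gene (row names
#'   are gene symbols). Genes with no surviving probe are absent.
#' @export
collapse_probes <- function(probes, fold_changes_per_probe) {
  stopifnot(inherits(probes, "probe_matrix"))
  if (is.null(probes$probe_gene)) stop("probe_gene mapping is required")
  m <- probes$intensities
  ids <- rownames(m)
  if (!all(ids %in% rownames(fold_changes_per_probe)))
    stop("fold changes missing for some probes")
  score <- rowSums(abs(fold_changes_per_probe[ids, , drop = FALSE]))
  genes <- probes$probe_gene[ids]
  # stable argmax per gene: first probe (input order) among score maxima
  keep <- vapply(split(seq_along(ids), genes), function(idx) {
    idx[which.max(score[idx])]
  }, integer(1))
  out <- m[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  out[order(rownames(out), method = "radix"), , drop = FALSE]
}

#' Preprocess a miRNA probe matrix
#'
#' Applies the miRNA-specific cleaning: miRNAs whose detection flags are
#' negative in every replicate probe on every chip are removed; replicate
#' probes of one miRNA are combined by their median; the combined matrix is
#' then quantile-normalized between samples.
#'
#' @param probes A [probe_matrix] whose `probe_gene` maps probes to miRNA
#'   ids.
#' @param flags Numeric matrix aligned to `probes$intensities` (same
#'   dimensions/names); negative values mark undetected measurements.
#' @return Numeric matrix of normalized intensities, one row per retained
#'   miRNA.
#' @export
mirna_preprocess <- function(probes, flags) {
  stopifnot(inherits(probes, "probe_matrix"))
  if (is.null(probes$probe_gene)) stop("probe_gene mapping is required")
  m <- probes$intensities
  if (missing(flags) || is.null(flags)) stop("detection flags are required")
  if (!is.matrix(flags) || !identical(dim(flags), dim(m)))
    stop("'flags' must be a matrix aligned to the intensities")
  rownames(flags) <- rownames(m)
  mirna <- probes$probe_gene[rownames(m)]
  all_neg <- vapply(split(seq_len(nrow(m)), mirna), function(idx) {
    all(flags[idx, , drop = FALSE] < 0)
  }, logical(1))
  keep_mirnas <- names(all_neg)[!all_neg]
  idx_keep <- which(mirna %in% keep_mirnas)
  m <- m[idx_keep, , drop = FALSE]
  mirna <- mirna[idx_keep]
  groups <- split(seq_len(nrow(m)), mirna)
  combined <- matrix(NA_real_, length(groups), ncol(m),
                     dimnames = list(names(groups), colnames(m)))
  for (g in names(groups))
    combined[g, ] <- apply(m[groups[[g]], , drop = FALSE], 2L, stats::median)
  quantile_normalize(combined)
}

#' Log2 fold changes from paired condition matrices
#'
#' Low-level counterpart of [fold_changes] for plain matrices.
#'
#' @param treatment,control Numeric matrices, features by time points, with
#'   identical dimnames and strictly positive entries.
#' @return Matrix of `log2(treatment/control)`.
#' @export
compute_fold_changes <- function(treatment, control) {
  if (!identical(dim(treatment), dim(control)) ||
      !identical(dimnames(treatment), dimnames(control)))
    stop("treatment and control matrices must be aligned")
  if (any(treatment <= 0) || any(control <= 0))
    stop("non-positive intensity encountered; filter probes first")
  log2(treatment) - log2(control)
}
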