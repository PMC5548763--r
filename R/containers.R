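#' Two-condition time-course expression dataset
#'
#' Bundles the normalized, linear-scale intensity matrices for genes
#' (including transcription-factor genes) and miRNAs measured under two
#' conditions (control first, treatment second) at an ordered series of
#' time points, together with the feature class annotation (TF gene,
#' non-TF gene, miRNA) and an optional list of cardiovascular-associated
#' (CV) genes used for enrichment tests.
#'
#' Columns of both matrices must be named `<condition>_<timepoint>` and be
#' ordered condition-major (all control samples first, in time-point order,
#' then all treatment samples).
#'
#' @param genes Numeric matrix, gene features (rows, named) by samples.
#'   All values must be positive and finite.
#' @param mirnas Numeric matrix of miRNA features by samples; may have zero
#'   rows. Same column layout as `genes`.
#' @param tf_genes Character vector of gene symbols (a subset of
#'   `rownames(genes)`) annotated as transcription factors.
#' @param cv_genes Character vector of cardiovascular-associated gene
#'   symbols; symbols absent from the dataset are kept (they may refer to
#'   unexpressed genes) but ignored downstream.
#' @param timepoints Ordered character vector of time-point labels
#'   (at least two).
#' @param conditions Length-2 character vector, control condition first.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `genes`, `mirnas`, `tf_genes`, `cv_genes`, `timepoints`, `conditions`.
#' @export
expression_dataset <- function(genes, mirnas, tf_genes, cv_genes = character(),
                               timepoints,
                               conditions = c("sham", "TAB")) {
  if (length(conditions) != 2L || anyDuplicated(conditions))
    stop("'conditions' must be two distinct labels (control first)")
  if (length(timepoints) < 2L || anyDuplicated(timepoints))
    stop("'timepoints' must be >= 2 distinct ordered labels")
  genes <- .check_expr_matrix(genes, conditions, timepoints, "genes")
  mirnas <- .check_expr_matrix(mirnas, conditions, timepoints, "mirnas",
                               allow_empty = TRUE)
  tf_genes <- as.character(tf_genes)
  if (!all(tf_genes %in% rownames(genes)))
    stop("every TF symbol must be a row of 'genes'")
  if (length(intersect(rownames(genes), rownames(mirnas))))
    stop("gene and miRNA identifiers must not overlap")
  structure(list(genes = genes, mirnas = mirnas,
                 tf_genes = tf_genes, cv_genes = as.character(cv_genes),
                 timepoints = as.character(timepoints),
                 conditions = as.character(conditions)),
            class = "expression_dataset")
}

.sample_names <- function(conditions, timepoints) {
  paste(rep(conditions, each = length(timepoints)),
        rep(timepoints, times = length(conditions)), sep = "_")
}

.check_expr_matrix <- function(m, conditions, timepoints, what,
                               allow_empty = FALSE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop(sprintf("'%s' must be a numeric matrix", what))
  if (nrow(m) == 0L && !allow_empty)
    stop(sprintf("'%s' must have at least one row", what))
  expected <- .sample_names(conditions, timepoints)
  if (is.null(colnames(m)) || !identical(colnames(m), expected))
    stop(sprintf("'%s' columns must be exactly: %s", what,
                 paste(expected, collapse = ", ")))
  if (nrow(m) > 0L) {
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
      stop(sprintf("'%s' must have unique row names", what))
    if (anyNA(m) || any(!is.finite(m)) || any(m <= 0))
      stop(sprintf("'%s' intensities must be positive and finite", what))
  }
  m
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d genes (%d TF) / %d miRNAs; %d timepoints (%s); conditions %s vs %s\n",
    nrow(x$genes), length(x$tf_genes), nrow(x$mirnas),
    length(x$timepoints), paste(x$timepoints, collapse = ","),
    x$conditions[1], x$conditions[2]))
  invisible(x)
}

#' Feature class labels of a dataset
#'
#' @param dataset An [expression_dataset].
#' @return Named character vector mapping every feature id to one of
#'   `"tf"`, `"gene"` (non-TF gene) or `"mirna"`.
#' @export
feature_classes <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  g <- rownames(dataset$genes)
  cls <- ifelse(g %in% dataset$tf_genes, "tf", "gene")
  names(cls) <- g
  m <- rownames(dataset$mirnas)
  c(cls, stats::setNames(rep("mirna", length(m)), m))
}

.class_rows <- function(dataset, class) {
  switch(class,
    gene  = dataset$genes,
    tf    = dataset$genes[rownames(dataset$genes) %in% dataset$tf_genes, ,
                          drop = FALSE],
    nontf = dataset$genes[!rownames(dataset$genes) %in% dataset$tf_genes, ,
                          drop = FALSE],
    mirna = dataset$mirnas,
    stop(sprintf("unknown feature class '%s'", class)))
}

#' Extract an intensity matrix for one feature class and condition
#'
#' @param dataset An [expression_dataset].
#' @param class One of `"gene"` (all genes), `"tf"`, `"nontf"`, `"mirna"`.
#' @param condition A condition label of the dataset, or `NULL` for all
#'   samples.
#' @return Numeric matrix, features by samples (columns named by time point
#'   when a single condition is selected).
#' @export
intensity_matrix <- function(dataset, class = "gene", condition = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  m <- .class_rows(dataset, match.arg(class, c("gene", "tf", "nontf", "mirna")))
  if (is.null(condition)) return(m)
  if (!condition %in% dataset$conditions)
    stop(sprintf("unknown condition '%s'", condition))
  out <- m[, paste(condition, dataset$timepoints, sep = "_"), drop = FALSE]
  colnames(out) <- dataset$timepoints
  out
}

#' Per-timepoint log2 fold changes (treatment over control)
#'
#' For every feature of the requested class, computes
#' `log2(treatment / control)` at each time point from the linear-scale
#' intensities. Intensities must be strictly positive (enforced upstream by
#' the probe filter), so the result is finite everywhere.
#'
#' @inheritParams intensity_matrix
#' @return Numeric matrix, features by time points, of log2 ratios.
#' @export
fold_changes <- function(dataset, class = "gene") {
  ctrl <- intensity_matrix(dataset, class, dataset$conditions[1])
  trt <- intensity_matrix(dataset, class, dataset$conditions[2])
  log2(trt) - log2(ctrl)
}
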