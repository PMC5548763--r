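# File-format adapters. All tabular formats are TSV with a header row;
# parsers are strict (header and field-count validation with line numbers)
# and tolerate CRLF line endings.

.read_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sub("\r$", "", readLines(path, warn = FALSE))
}

.split_tsv <- function(lines, path, n_fields) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  if (length(bad))
    stop(sprintf("%s: line %d has %d fields, expected %d",
                 path, bad[1] + 1L, lengths(parts)[bad[1]], n_fields))
  parts
}

.check_header <- function(got, expected, path) {
  if (!identical(got, expected))
    stop(sprintf("%s: bad header; expected columns '%s', found '%s'",
                 path, paste(expected, collapse = "', '"),
                 paste(got, collapse = "', '")))
}

#' Read an expression matrix from TSV
#'
#' Expects a header `feature<TAB><condition>_<timepoint>...`; sample columns
#' must cover every condition x timepoint combination, condition-major.
#'
#' @param path File path.
#' @param conditions,timepoints Expected sample layout.
#' @return Numeric matrix with feature row names.
#' @export
read_expression_tsv <- function(path, conditions = c("sham", "TAB"),
                                timepoints = NULL) {
  lines <- .read_lines(path)
  if (!length(lines)) stop(sprintf("%s: empty file", path))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "feature")
    stop(sprintf("%s: first header column must be 'feature'", path))
  samples <- header[-1]
  if (is.null(timepoints)) {
    # infer timepoint order from the control condition's columns
    ctrl <- grep(paste0("^", conditions[1], "_"), samples, value = TRUE)
    timepoints <- sub(paste0("^", conditions[1], "_"), "", ctrl)
  }
  .check_header(samples, .sample_names(conditions, timepoints), path)
  parts <- .split_tsv(lines[-1], path, length(header))
  ids <- vapply(parts, `[[`, "", 1L)
  vals <- vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[-1]))
    v
  }, numeric(length(samples)))
  m <- if (length(ids)) t(matrix(vals, nrow = length(samples))) else
    matrix(numeric(), 0L, length(samples))
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1]
    stop(sprintf("%s: line %d contains a non-numeric intensity", path, bad + 1L))
  }
  dimnames(m) <- list(ids, samples)
  m
}

#' Write an expression matrix to TSV
#'
#' @param m Numeric matrix with feature row names and sample column names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  con <- file(path, "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(paste(c("feature", colnames(m)), collapse = "\t"), con)
  if (nrow(m)) {
    rows <- apply(format(m, trim = TRUE, digits = 15, scientific = FALSE),
                  1L, paste, collapse = "\t")
    writeLines(paste(rownames(m), rows, sep = "\t"), con)
  }
  invisible(path)
}

#' Read / write a one-symbol-per-line feature list
#' @param path File path.
#' @return Character vector of symbols (blank lines dropped).
#' @export
read_feature_list <- function(path) {
  x <- .read_lines(path)
  x[nzchar(x)]
}

#' @rdname read_feature_list
#' @param symbols Character vector to write.
#' @export
write_feature_list <- function(symbols, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(as.character(symbols), con)
  invisible(path)
}

#' Read / write a two-column regulator-target interaction table
#'
#' The file must have the header `regulator<TAB>target`.
#'
#' @param path File path.
#' @return Data frame with character columns `regulator`, `target`.
#' @export
read_pair_table <- function(path) {
  lines <- .read_lines(path)
  if (!length(lines)) stop(sprintf("%s: empty file", path))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  .check_header(header, c("regulator", "target"), path)
  parts <- .split_tsv(lines[-1], path, 2L)
  data.frame(regulator = vapply(parts, `[[`, "", 1L),
             target = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' @rdname read_pair_table
#' @param pairs Data frame with columns `regulator`, `target`.
#' @export
write_pair_table <- function(pairs, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines("regulator\ttarget", con)
  if (nrow(pairs))
    writeLines(paste(pairs$regulator, pairs$target, sep = "\t"), con)
  invisible(path)
}

#' Read / write GMT-style annotation sets
#'
#' Each line is `term<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path File path.
#' @return Named list of character vectors (term id -> members) with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("%s: line %d has fewer than 3 fields (term, description, members)",
                 path, bad[1]))
  terms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(terms))
    stop(sprintf("%s: duplicated term id '%s'", path, terms[duplicated(terms)][1]))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- terms
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, "", 2L), terms)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors; an optional `descriptions`
#'   attribute (named character) supplies the second column.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(names(sets), names(sets))
  con <- file(path, "wb"); on.exit(close(con))
  for (term in names(sets))
    writeLines(paste(c(term, desc[[term]], sets[[term]]), collapse = "\t"), con)
  invisible(path)
}

#' Read / write a typed, signed network edge list
#'
#' Columns: `source`, `target`, `type`, `sign`, `pcc`.
#'
#' @param path File path.
#' @return Data frame of edges.
#' @export
read_edge_list <- function(path) {
  lines <- .read_lines(path)
  if (!length(lines)) stop(sprintf("%s: empty file", path))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  .check_header(header, c("source", "target", "type", "sign", "pcc"), path)
  parts <- .split_tsv(lines[-1], path, 5L)
  data.frame(source = vapply(parts, `[[`, "", 1L),
             target = vapply(parts, `[[`, "", 2L),
             type = vapply(parts, `[[`, "", 3L),
             sign = as.integer(vapply(parts, `[[`, "", 4L)),
             pcc = as.numeric(vapply(parts, `[[`, "", 5L)),
             stringsAsFactors = FALSE)
}

#' @rdname read_edge_list
#' @param edges Data frame with columns `source`, `target`, `type`, `sign`,
#'   `pcc`.
#' @export
write_edge_list <- function(edges, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines("source\ttarget\ttype\tsign\tpcc", con)
  if (nrow(edges))
    writeLines(paste(edges$source, edges$target, edges$type, edges$sign,
                     format(edges$pcc, trim = TRUE, digits = 15),
                     sep = "\t"), con)
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
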