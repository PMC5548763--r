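#' Hypergeometric over-representation analysis with BH FDR control
#'
#' Tests each annotation set for over-representation in a query gene set
#' relative to a background population (typically all expressed genes).
#' Annotation-set members outside the background are ignored at test time.
#' The per-term p-value is the one-sided hypergeometric upper tail
#' (probability of an overlap at least as large under random sampling of
#' the query from the background); q-values are Benjamini-Hochberg adjusted
#' across all tested terms, including terms with zero overlap (reported
#' with p = 1) so that the number of tests is stable.
#'
#' @param query Character vector of gene ids, a subset of `background`.
#' @param sets Named list of character vectors (term id -> members), e.g.
#'   from [read_gmt].
#' @param background Character vector, the reference population.
#' @param fdr FDR threshold for the `enriched` flag (default 0.05).
#' @return Data frame sorted by `q`, then `p`, then term id, with columns
#'   `term`, `overlap`, `query_size`, `term_size`, `background_size`, `p`,
#'   `q`, `enriched`.
#' @export
enrich <- function(query, sets, background, fdr = 0.05) {
  query <- unique(query)
  background <- unique(background)
  if (!length(query)) stop("empty query set")
  if (!length(background)) stop("empty background")
  if (!all(query %in% background))
    stop("query must be a subset of the background")
  if (!length(sets)) stop("no annotation sets supplied")
  N <- length(background)
  n <- length(query)
  terms <- names(sets)
  overlap <- term_size <- integer(length(sets))
  p <- numeric(length(sets))
  for (i in seq_along(sets)) {
    members <- intersect(sets[[i]], background)
    K <- length(members)
    x <- length(intersect(query, members))
    overlap[i] <- x
    term_size[i] <- K
    p[i] <- if (x == 0L) 1 else
      stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  }
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term = terms, overlap = overlap, query_size = n,
                    term_size = term_size, background_size = N,
                    p = p, q = q, enriched = q < fdr,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$term, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Background excluding basal transcription machinery
#'
#' Removes a gene set (e.g. genes annotated to fundamental transcriptional
#' molecular functions) from a background population; used when testing
#' enrichment of TF genes themselves, where the transcription machinery
#' would otherwise dominate every term.
#'
#' @param background Character vector.
#' @param exclusion Character vector of gene ids to remove.
#' @return The reduced background; an error if nothing remains.
#' @export
background_excluding_transcription_terms <- function(background, exclusion) {
  out <- setdiff(unique(background), exclusion)
  if (!length(out)) stop("exclusion removes the entire background")
  out
}
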