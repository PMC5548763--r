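#' Build a TF co-expression network from temporal profiles
#'
#' Connects two transcription-factor genes by an undirected edge when the
#' Pearson correlation of their treatment-condition temporal profiles
#' reaches the threshold (positive correlation only). Profiles with zero
#' variance have no defined correlation and produce no edges. The result
#' is a simple graph with no self-edges.
#'
#' @param profiles Numeric matrix, TF genes (rows, named) by time points
#'   (>= 3), typically the treatment-condition intensities.
#' @param threshold Minimum PCC for an edge (default 0.9).
#' @return An object of class `coexpression_network`: list with `nodes`
#'   (character vector, all input TFs) and `edges` (data frame `from`,
#'   `to`, `pcc`, with `from < to` lexicographically).
#' @export
build_tf_network <- function(profiles, threshold = 0.9) {
  if (!is.matrix(profiles) || ncol(profiles) < 3L)
    stop("'profiles' must be a matrix with >= 3 timepoints")
  if (is.null(rownames(profiles)) || anyDuplicated(rownames(profiles)))
    stop("'profiles' must have unique row names")
  nodes <- rownames(profiles)
  n <- length(nodes)
  edges <- data.frame(from = character(), to = character(), pcc = numeric(),
                      stringsAsFactors = FALSE)
  if (n >= 2L) {
    cc <- suppressWarnings(stats::cor(t(profiles)))  # NA for zero variance
    idx <- which(upper.tri(cc) & !is.na(cc) & cc >= threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      a <- nodes[idx[, 1L]]
      b <- nodes[idx[, 2L]]
      swap <- a > b
      edges <- data.frame(from = ifelse(swap, b, a),
                          to = ifelse(swap, a, b),
                          pcc = cc[idx], stringsAsFactors = FALSE)
      edges <- edges[order(edges$from, edges$to, method = "radix"), ]
      rownames(edges) <- NULL
    }
  }
  structure(list(nodes = nodes, edges = edges),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

.net_edge_matrix <- function(network) {
  cbind(match(network$edges$from, network$nodes),
        match(network$edges$to, network$nodes))
}

#' Find all bridges of a co-expression network
#'
#' A bridge is an edge whose removal increases the number of connected
#' components of the graph.
#'
#' @param network A `coexpression_network` (or a list with `nodes` and an
#'   `edges` data frame with columns `from`, `to`).
#' @return Data frame of bridge edges (columns `from`, `to`).
#' @export
find_bridges <- function(network) {
  em <- .net_edge_matrix(network)
  idx <- .graph_bridges(length(network$nodes), em)
  out <- network$edges[idx, c("from", "to"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition a co-expression network by iterated bridge bisection
#'
#' Connected components larger than `min_size` are split step by step: the
#' largest unfinished partition is examined, the balancing value of each of
#' its bridges (the size of the larger of the two parts its removal
#' creates) is computed, and the bridge with the smallest balancing value
#' whose removal leaves both parts larger than `min_size` is cut (ties are
#' broken by the lexicographically smallest `(from, to)` pair). The process
#' repeats until no admissible cut exists anywhere. Components of size
#' `min_size` or smaller — including isolated nodes — are assigned to the
#' residual module, id 0.
#'
#' Module ids 1, 2, ... are assigned to final partitions in decreasing size
#' order (ties by smallest member id), so module 1 is always the largest.
#'
#' @param network A `coexpression_network`.
#' @param min_size Both parts of an admissible cut must exceed this size
#'   (default 10); components this small go to the residual module.
#' @return An object of class `module_partition`: list with `membership`
#'   (named integer vector, 0 = residual), `modules` (list of node vectors
#'   by module id), and `cuts` (data frame `from`, `to`, `balancing` in cut
#'   order).
#' @export
bisect_network <- function(network, min_size = 10) {
  nodes <- network$nodes
  n <- length(nodes)
  em <- .net_edge_matrix(network)
  comp <- if (n) .graph_components(n, em) else integer(0)
  parts <- split(seq_len(n), comp)
  work <- Filter(function(p) length(p) > min_size, parts)
  residual <- sort(unlist(Filter(function(p) length(p) <= min_size, parts),
                          use.names = FALSE))
  done <- list()
  cuts <- data.frame(from = character(), to = character(),
                     balancing = integer(), stringsAsFactors = FALSE)
  # edges live in a global pool; a cut deletes one edge
  alive <- rep(TRUE, nrow(em))
  while (length(work)) {
    sizes <- lengths(work)
    first_ids <- vapply(work, function(p) min(nodes[p]), "")
    pick <- order(-sizes, first_ids, method = "radix")[1]
    part <- work[[pick]]
    work <- work[-pick]
    in_part <- logical(n)
    in_part[part] <- TRUE
    eidx <- which(alive & in_part[em[, 1L]] & in_part[em[, 2L]])
    # bridges of the current partition, on local indices
    local <- match(seq_len(n), part)
    lem <- cbind(local[em[eidx, 1L]], local[em[eidx, 2L]])
    br <- eidx[.graph_bridges(length(part), lem)]
    if (length(br)) {
      # balancing value: size of the larger side after removing the bridge
      side <- vapply(br, function(e) {
        keep <- eidx[eidx != e]
        lc <- .graph_components(length(part),
                                cbind(local[em[keep, 1L]],
                                      local[em[keep, 2L]]))
        a <- sum(lc == lc[local[em[e, 1L]]])
        c(a, length(part) - a)
      }, numeric(2))
      small <- pmin(side[1, ], side[2, ])
      balancing <- pmax(side[1, ], side[2, ])
      admissible <- small > min_size
      br <- br[admissible]
      balancing <- balancing[admissible]
    } else balancing <- integer(0)
    if (!length(br)) {
      done[[length(done) + 1L]] <- part
      next
    }
    key_from <- nodes[em[br, 1L]]
    key_to <- nodes[em[br, 2L]]
    # orient each bridge so from < to before tie-breaking
    swap <- key_from > key_to
    tmp <- key_from[swap]; key_from[swap] <- key_to[swap]; key_to[swap] <- tmp
    sel <- order(balancing, key_from, key_to, method = "radix")[1]
    e <- br[sel]
    alive[e] <- FALSE
    cuts <- rbind(cuts, data.frame(from = key_from[sel], to = key_to[sel],
                                   balancing = as.integer(balancing[sel]),
                                   stringsAsFactors = FALSE))
    keep <- eidx[eidx != e]
    lc <- .graph_components(length(part),
                            cbind(local[em[keep, 1L]], local[em[keep, 2L]]))
    work <- c(work, list(part[lc == 1L], part[lc == 2L]))
  }
  # number final modules by decreasing size, ties by smallest node id
  if (length(done)) {
    ord <- order(-lengths(done), vapply(done, function(p) min(nodes[p]), ""),
                 method = "radix")
    done <- done[ord]
  }
  membership <- stats::setNames(integer(n), nodes)
  modules <- list()
  for (i in seq_along(done)) {
    ids <- sort(nodes[done[[i]]], method = "radix")
    membership[ids] <- i
    modules[[as.character(i)]] <- ids
  }
  if (length(residual))
    modules[["0"]] <- sort(nodes[residual], method = "radix")
  structure(list(membership = membership, modules = modules, cuts = cuts),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- lengths(x$modules)
  cat(sprintf("module_partition: %d modules (%s)%s; %d cuts\n",
              sum(names(x$modules) != "0"),
              paste(sizes[names(sizes) != "0"], collapse = "/"),
              if ("0" %in% names(x$modules))
                sprintf(" + residual of %d", sizes[["0"]]) else "",
              nrow(x$cuts)))
  invisible(x)
}

#' Genes co-expressed with a TF
#'
#' Returns the differentially expressed genes whose treatment-condition
#' temporal profile correlates with the TF's profile at or above the
#' threshold.
#'
#' @param tf_profile Numeric vector, the TF's temporal profile.
#' @param gene_profiles Numeric matrix, candidate genes by time points.
#' @param threshold Minimum PCC (default 0.9).
#' @return Character vector of gene ids.
#' @export
coexpressed_de_genes <- function(tf_profile, gene_profiles, threshold = 0.9) {
  if (!is.matrix(gene_profiles) || ncol(gene_profiles) != length(tf_profile))
    stop("profile lengths must agree")
  pcc <- suppressWarnings(
    as.numeric(stats::cor(tf_profile, t(gene_profiles))))
  rownames(gene_profiles)[!is.na(pcc) & pcc >= threshold]
}

#' Per-module regulation counts over time
#'
#' Counts the up- (+1) and down- (-1) regulated TF genes of each module at
#' each time point.
#'
#' @param partition A `module_partition`.
#' @param calls A `de_calls` object covering the partition's nodes.
#' @return Data frame with columns `module`, `timepoint`, `n_up`, `n_down`.
#' @export
module_regulation_summary <- function(partition, calls) {
  stopifnot(inherits(partition, "module_partition"),
            inherits(calls, "de_calls"))
  lab <- calls$labels
  missing <- setdiff(names(partition$membership), rownames(lab))
  if (length(missing))
    stop(sprintf("DE calls missing for node '%s'", missing[1]))
  rows <- list()
  for (mod in names(partition$modules)) {
    sub <- lab[partition$modules[[mod]], , drop = FALSE]
    rows[[mod]] <- data.frame(module = as.integer(mod),
                              timepoint = colnames(lab),
                              n_up = colSums(sub == 1L),
                              n_down = colSums(sub == -1L),
                              row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$module, match(out$timepoint, colnames(lab))), ]
}
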