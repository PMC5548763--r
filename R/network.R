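# Construction of the integrated signed TF-miRNA-gene regulatory network.
# Three edge types are derived from temporal co-expression in the treatment
# condition plus curated/predicted interaction tables:
#   tf_target    TF gene  -> target gene, sign = sign of the PCC, requires
#                |PCC| >= threshold and a supporting interaction-table row
#   mirna_target miRNA    -> target gene, sign -1, requires
#                PCC <= -threshold and a supporting table row
#   tf_mirna     TF gene  -> miRNA, sign +1, requires PCC >= threshold in
#                the treatment condition but < threshold in the control
#                (treatment-specific co-expression)
# Suppression events (see infer_suppression) enter the merged network as
# miRNA -> TF edges of type "suppression", sign -1.

.pair_pcc <- function(profiles, a, b) {
  # PCC per row pair; NA when either profile has zero variance
  suppressWarnings(vapply(seq_along(a), function(i)
    stats::cor(profiles[a[i], ], profiles[b[i], ]), numeric(1)))
}

.edge_frame <- function(source, target, type, sign, pcc) {
  out <- data.frame(source = source, target = target,
                    type = rep_len(as.character(type), length(source)),
                    sign = rep_len(as.integer(sign), length(source)),
                    pcc = as.numeric(pcc),
                    stringsAsFactors = FALSE)
  out <- out[order(out$source, out$target, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' TF-to-target regulatory edges
#'
#' A directed edge TF -> gene is emitted for every interaction-table pair
#' of DE features whose treatment-condition profiles are co-expressed,
#' positively or negatively (`|PCC| >= threshold`); the edge sign is the
#' sign of the correlation.
#'
#' @param profiles Numeric matrix of treatment-condition temporal profiles
#'   (rows named by feature, covering TFs and genes).
#' @param de_features Character vector of DE feature ids; both ends of an
#'   edge must be DE.
#' @param tf_table Data frame with columns `regulator` (TF), `target`
#'   (gene).
#' @param threshold Minimum |PCC| (default 0.9).
#' @param profiles_ctl Optional control-condition profiles; when supplied
#'   together with `treatment_specific = TRUE`, an edge additionally
#'   requires `|PCC| < threshold` in the control condition.
#' @param treatment_specific Require the co-expression to be absent in the
#'   control condition (default `FALSE`).
#' @return Edge data frame (`source`, `target`, `type`, `sign`, `pcc`).
#' @export
tf_target_edges <- function(profiles, de_features, tf_table, threshold = 0.9,
                            profiles_ctl = NULL, treatment_specific = FALSE) {
  tab <- unique(tf_table[, c("regulator", "target")])
  tab <- tab[tab$regulator %in% de_features & tab$target %in% de_features &
               tab$regulator %in% rownames(profiles) &
               tab$target %in% rownames(profiles) &
               tab$regulator != tab$target, , drop = FALSE]
  pcc <- .pair_pcc(profiles, tab$regulator, tab$target)
  hit <- !is.na(pcc) & abs(pcc) >= threshold
  if (treatment_specific) {
    if (is.null(profiles_ctl))
      stop("'profiles_ctl' is required when treatment_specific = TRUE")
    pcc_ctl <- .pair_pcc(profiles_ctl, tab$regulator, tab$target)
    hit <- hit & (is.na(pcc_ctl) | abs(pcc_ctl) < threshold)
  }
  .edge_frame(tab$regulator[hit], tab$target[hit], "tf_target",
              sign(pcc[hit]), pcc[hit])
}

#' miRNA-to-target regulatory edges
#'
#' A directed negative edge miRNA -> gene is emitted for every
#' interaction-table pair of DE features whose treatment-condition profiles
#' are negatively co-expressed (`PCC <= -threshold`).
#'
#' @inheritParams tf_target_edges
#' @param mirna_table Data frame with columns `regulator` (miRNA),
#'   `target` (gene).
#' @return Edge data frame.
#' @export
mirna_target_edges <- function(profiles, de_features, mirna_table,
                               threshold = 0.9) {
  tab <- unique(mirna_table[, c("regulator", "target")])
  tab <- tab[tab$regulator %in% de_features & tab$target %in% de_features &
               tab$regulator %in% rownames(profiles) &
               tab$target %in% rownames(profiles), , drop = FALSE]
  pcc <- .pair_pcc(profiles, tab$regulator, tab$target)
  hit <- !is.na(pcc) & pcc <= -threshold
  .edge_frame(tab$regulator[hit], tab$target[hit], "mirna_target",
              -1L, pcc[hit])
}

#' Treatment-specific TF-miRNA co-expression edges
#'
#' A directed positive edge TF -> miRNA is emitted for every pair of DE TF
#' and DE miRNA that is positively co-expressed in the treatment condition
#' (`PCC >= threshold`) but not in the control condition
#' (`PCC < threshold`): co-expression specific to the treatment.
#'
#' @param tf_profiles_trt,mirna_profiles_trt Treatment-condition profile
#'   matrices for DE TFs and DE miRNAs.
#' @param tf_profiles_ctl,mirna_profiles_ctl Matching control-condition
#'   profiles (same rows).
#' @param threshold Minimum PCC (default 0.9).
#' @return Edge data frame with type `tf_mirna`.
#' @export
tf_mirna_edges <- function(tf_profiles_trt, mirna_profiles_trt,
                           tf_profiles_ctl, mirna_profiles_ctl,
                           threshold = 0.9) {
  if (!identical(rownames(tf_profiles_trt), rownames(tf_profiles_ctl)) ||
      !identical(rownames(mirna_profiles_trt), rownames(mirna_profiles_ctl)))
    stop("treatment and control profiles must cover the same features")
  if (nrow(tf_profiles_trt) == 0L || nrow(mirna_profiles_trt) == 0L)
    return(.edge_frame(character(), character(), character(),
                       integer(), numeric()))
  cc_trt <- suppressWarnings(stats::cor(t(tf_profiles_trt),
                                        t(mirna_profiles_trt)))
  cc_ctl <- suppressWarnings(stats::cor(t(tf_profiles_ctl),
                                        t(mirna_profiles_ctl)))
  hit <- which(!is.na(cc_trt) & cc_trt >= threshold &
                 (is.na(cc_ctl) | cc_ctl < threshold), arr.ind = TRUE)
  .edge_frame(rownames(cc_trt)[hit[, 1L]], colnames(cc_trt)[hit[, 2L]],
              "tf_mirna", 1L, cc_trt[hit])
}

#' Assemble the integrated regulatory network
#'
#' Merges the typed edge lists (including suppression events converted to
#' `suppression` edges) into one network; duplicate `(source, target,
#' type)` triples are collapsed (first occurrence kept). Every edge
#' endpoint must be an annotated node.
#'
#' @param edges Data frame of edges (`source`, `target`, `type`, `sign`,
#'   `pcc`) or a list of such data frames, e.g. the outputs of
#'   [tf_target_edges], [mirna_target_edges], [tf_mirna_edges].
#' @param node_classes Named character vector mapping every node id to
#'   `"tf"`, `"gene"` or `"mirna"` (as from [feature_classes]).
#' @param cv_genes Character vector of cardiovascular-associated symbols.
#' @param emergence Optional `emergence_table`; attaches each node's first
#'   DE emergence time point.
#' @param suppression_events Optional event data frame from
#'   [infer_suppression]; pairs with at least one event become miRNA -> TF
#'   `suppression` edges (sign -1, pcc `NA`).
#' @return An object of class `regulatory_network`: list with `nodes`
#'   (data frame `id`, `class`, `cv`, `first_emergence`) and `edges`.
#' @export
build_network <- function(edges, node_classes, cv_genes = character(),
                          emergence = NULL, suppression_events = NULL) {
  if (is.data.frame(edges)) edges <- list(edges)
  all_edges <- do.call(rbind, edges)
  if (is.null(all_edges))
    all_edges <- .edge_frame(character(), character(), character(),
                             integer(), numeric())
  if (!is.null(suppression_events) && nrow(suppression_events)) {
    pairs <- unique(suppression_events[, c("mirna", "tf")])
    all_edges <- rbind(all_edges,
                       data.frame(source = pairs$mirna, target = pairs$tf,
                                  type = "suppression", sign = -1L,
                                  pcc = NA_real_, stringsAsFactors = FALSE))
  }
  all_edges <- all_edges[!duplicated(all_edges[, c("source", "target", "type")]), ]
  ids <- unique(c(all_edges$source, all_edges$target))
  dangling <- setdiff(ids, names(node_classes))
  if (length(dangling))
    stop(sprintf("edge endpoint '%s' has no node annotation", dangling[1]))
  ids <- sort(ids, method = "radix")
  first <- rep(NA_character_, length(ids))
  if (!is.null(emergence)) {
    fe <- emergence$first_emergence
    first[ids %in% names(fe)] <- unname(fe[ids[ids %in% names(fe)]])
  }
  nodes <- data.frame(id = ids,
                      class = unname(node_classes[ids]),
                      cv = ids %in% cv_genes,
                      first_emergence = first,
                      stringsAsFactors = FALSE)
  all_edges <- all_edges[order(all_edges$source, all_edges$target,
                               all_edges$type, method = "radix"), ]
  rownames(all_edges) <- NULL
  structure(list(nodes = nodes, edges = all_edges),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d nodes (%s), %d edges (%s)\n",
              nrow(x$nodes),
              paste(names(table(x$nodes$class)),
                    table(x$nodes$class), sep = ":", collapse = " "),
              nrow(x$edges),
              paste(names(table(x$edges$type)),
                    table(x$edges$type), sep = ":", collapse = " ")))
  invisible(x)
}

#' Per-node degree bookkeeping (hub records)
#'
#' For every node, counts outward and inward edges split by sign. The
#' identities `total = outward + inward`, `outward = outward_pos +
#' outward_neg` and `inward = inward_pos + inward_neg` hold by
#' construction.
#'
#' @param network A `regulatory_network`.
#' @return Data frame with columns `id`, `class`, `cv`, `first_emergence`,
#'   `total`, `outward`, `outward_pos`, `outward_neg`, `inward`,
#'   `inward_pos`, `inward_neg`.
#' @export
hub_records <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  nodes <- network$nodes
  e <- network$edges
  cnt <- function(end, s) {
    tab <- table(factor(e[[end]][e$sign == s], levels = nodes$id))
    as.integer(tab)
  }
  out <- nodes
  out$outward_pos <- cnt("source", 1L)
  out$outward_neg <- cnt("source", -1L)
  out$inward_pos <- cnt("target", 1L)
  out$inward_neg <- cnt("target", -1L)
  out$outward <- out$outward_pos + out$outward_neg
  out$inward <- out$inward_pos + out$inward_neg
  out$total <- out$outward + out$inward
  out[, c("id", "class", "cv", "first_emergence", "total",
          "outward", "outward_pos", "outward_neg",
          "inward", "inward_pos", "inward_neg")]
}

#' Rank first-emergence hubs per time point
#'
#' For each time point, the regulators (TF genes and miRNAs) whose first DE
#' emergence is that time point are sorted by total degree (descending,
#' ties by id) and the top `k_tf` TFs and top `k_mirna` miRNAs are
#' reported.
#'
#' @param network A `regulatory_network` whose nodes carry
#'   `first_emergence`.
#' @param timepoints Ordered time-point labels.
#' @param k_tf,k_mirna How many top TFs / miRNAs to report per time point.
#' @param calls Optional list of `de_calls` (e.g. `list(gene = ..., mirna =
#'   ...)`) used to append per-timepoint DE labels to each record.
#' @return Data frame of hub records with additional columns `timepoint`
#'   and `rank` (per class within time point).
#' @export
rank_hubs <- function(network, timepoints, k_tf = 5, k_mirna = 3,
                      calls = NULL) {
  rec <- hub_records(network)
  rec <- rec[rec$class %in% c("tf", "mirna"), , drop = FALSE]
  rows <- list()
  for (tp in timepoints) {
    for (cl in c("tf", "mirna")) {
      k <- if (cl == "tf") k_tf else k_mirna
      sub <- rec[rec$class == cl & !is.na(rec$first_emergence) &
                   rec$first_emergence == tp, , drop = FALSE]
      if (!nrow(sub)) next
      sub <- sub[order(-sub$total, sub$id, method = "radix"), , drop = FALSE]
      sub <- utils::head(sub, k)
      sub$timepoint <- tp
      sub$rank <- seq_len(nrow(sub))
      rows[[length(rows) + 1L]] <- sub
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(rec[0, ], timepoint = character(0), rank = integer(0))
  rownames(out) <- NULL
  if (!is.null(calls) && nrow(out)) {
    lab <- do.call(rbind, lapply(calls, `[[`, "labels"))
    for (tp in timepoints)
      out[[paste0("label_", tp)]] <-
        ifelse(out$id %in% rownames(lab), lab[out$id, tp], NA_integer_)
  }
  out
}

#' Validate the edge invariants of a regulatory network
#'
#' Recomputes, for every edge, the profile correlation and (for table-backed
#' types) the supporting interaction row, and checks the type-specific
#' rule. Used by tests and the pipeline as a safety net.
#'
#' @param network A `regulatory_network`.
#' @param profiles_trt,profiles_ctl Treatment/control profile matrices
#'   covering all nodes.
#' @param tf_table,mirna_table Interaction tables.
#' @param threshold PCC threshold used at construction.
#' @return `TRUE` (invisibly) if all edges validate; otherwise an error.
#' @export
validate_network <- function(network, profiles_trt, profiles_ctl,
                             tf_table, mirna_table, threshold = 0.9) {
  e <- network$edges
  has_pair <- function(tab, s, t)
    any(tab$regulator == s & tab$target == t)
  for (i in seq_len(nrow(e))) {
    s <- e$source[i]; t <- e$target[i]
    ok <- switch(e$type[i],
      tf_target = {
        p <- stats::cor(profiles_trt[s, ], profiles_trt[t, ])
        abs(p) >= threshold && has_pair(tf_table, s, t) &&
          e$sign[i] == sign(p)
      },
      mirna_target = {
        p <- stats::cor(profiles_trt[s, ], profiles_trt[t, ])
        p <= -threshold && has_pair(mirna_table, s, t) && e$sign[i] == -1L
      },
      tf_mirna = {
        p <- stats::cor(profiles_trt[s, ], profiles_trt[t, ])
        q <- stats::cor(profiles_ctl[s, ], profiles_ctl[t, ])
        p >= threshold && (is.na(q) || q < threshold) && e$sign[i] == 1L
      },
      suppression = e$sign[i] == -1L && has_pair(mirna_table, s, t),
      stop(sprintf("unknown edge type '%s'", e$type[i])))
    if (!isTRUE(ok))
      stop(sprintf("edge %s -> %s (%s) violates its invariant",
                   s, t, e$type[i]))
  }
  invisible(TRUE)
}

#' Cardiovascular-gene enrichment among network targets
#'
#' Computes the proportion of CV-flagged members of a target set and a
#' one-sided hypergeometric p-value for over-representation relative to a
#' background set.
#'
#' @param target_set Character vector, a subset of `background`.
#' @param cv_list Character vector of CV gene symbols.
#' @param background Character vector, the reference population (e.g. all
#'   DE genes or all expressed genes).
#' @return List with `proportion`, `p_value`, and the underlying counts.
#' @export
cv_enrichment <- function(target_set, cv_list, background) {
  target_set <- unique(target_set)
  background <- unique(background)
  if (!length(background)) stop("empty background")
  if (!length(target_set)) stop("empty target set")
  if (!all(target_set %in% background))
    stop("target set must be a subset of the background")
  cv_bg <- intersect(cv_list, background)
  x <- length(intersect(target_set, cv_bg))
  n <- length(target_set)
  K <- length(cv_bg)
  N <- length(background)
  p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  list(proportion = x / n, p_value = p,
       counts = list(cv_in_targets = x, target_size = n,
                     cv_in_background = K, background_size = N))
}
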