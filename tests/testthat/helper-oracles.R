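# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-implementations (loops, exhaustive scans,
# enumeration) kept separate from the package's own code paths.

# two-pass mean +/- k*SD differential-expression caller
oracle_de <- function(fc, k = 2) {
  out <- matrix(0L, nrow(fc), ncol(fc), dimnames = dimnames(fc))
  for (j in seq_len(ncol(fc))) {
    x <- fc[, j]
    m <- sum(x) / length(x)
    s <- sqrt(sum((x - m)^2) / (length(x) - 1))
    for (i in seq_len(nrow(fc))) {
      if (x[i] > m + k * s) out[i, j] <- 1L
      else if (x[i] < m - k * s) out[i, j] <- -1L
    }
  }
  out
}

# textbook two-pass Pearson correlation
oracle_pcc <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# connected-component count by label propagation until fixpoint
oracle_n_components <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      a <- comp[edges[r, 1]]; b <- comp[edges[r, 2]]
      if (a != b) { comp[comp == max(a, b)] <- min(a, b); changed <- TRUE }
    }
    if (!changed) break
  }
  length(unique(comp))
}

# bridges by removing each edge in turn and testing connectivity
oracle_bridges <- function(n, edges) {
  base <- oracle_n_components(n, edges)
  which(vapply(seq_len(nrow(edges)), function(e) {
    oracle_n_components(n, edges[-e, , drop = FALSE]) > base
  }, logical(1)))
}

# triple-loop suppression rule
oracle_suppression <- function(lab_mirna, lab_tf, pairs) {
  rows <- list()
  tps <- colnames(lab_mirna)
  for (i in seq_len(nrow(pairs))) {
    m <- pairs$regulator[i]; f <- pairs$target[i]
    if (!m %in% rownames(lab_mirna) || !f %in% rownames(lab_tf)) next
    if (all(lab_tf[f, ] == 0L)) next
    for (t in tps) {
      if (lab_mirna[m, t] == 1L && lab_tf[f, t] != 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = m, tf = f, timepoint = t, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(mirna = character(), tf = character(),
               timepoint = character(), stringsAsFactors = FALSE)
  out[order(out$mirna, out$tf, match(out$timepoint, tps),
            method = "radix"), , drop = FALSE]
}

# hypergeometric upper tail by summation of the exact pmf
oracle_hyper_tail <- function(x, K, N, n) {
  ks <- x:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(length(a))
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# random simple graph as a coexpression_network-shaped object
random_network <- function(n, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- data.frame(from = nodes[pairs[keep, 1]],
                      to = nodes[pairs[keep, 2]],
                      pcc = stats::runif(sum(keep), 0.9, 1),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges),
            class = "coexpression_network")
}

# k cliques (given sizes) joined into a random tree by single bridges
clique_tree_network <- function(sizes, seed) {
  set.seed(seed)
  nodes <- character(0)
  membership <- integer(0)
  edges <- list()
  offset <- 0L
  for (k in seq_along(sizes)) {
    ids <- sprintf("c%02d_%03d", k, seq_len(sizes[k]))
    nodes <- c(nodes, ids)
    membership <- c(membership, rep(k, sizes[k]))
    pr <- t(utils::combn(ids, 2))
    edges[[length(edges) + 1L]] <-
      data.frame(from = pr[, 1], to = pr[, 2], pcc = 1,
                 stringsAsFactors = FALSE)
    offset <- offset + sizes[k]
  }
  # random tree over cliques; bridge endpoints picked at random
  for (k in seq_len(length(sizes))[-1]) {
    other <- sample.int(k - 1, 1)
    a <- sprintf("c%02d_%03d", k, sample.int(sizes[k], 1))
    b <- sprintf("c%02d_%03d", other, sample.int(sizes[other], 1))
    edges[[length(edges) + 1L]] <-
      data.frame(from = min(a, b), to = max(a, b), pcc = 1,
                 stringsAsFactors = FALSE)
  }
  list(network = structure(list(nodes = nodes,
                                edges = do.call(rbind, edges)),
                           class = "coexpression_network"),
       membership = stats::setNames(membership, nodes))
}
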