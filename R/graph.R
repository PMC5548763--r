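# Internal helpers for small simple undirected graphs. Nodes are handled
# as integer indices into a character id vector; edges as a two-column
# integer matrix. Graphs here are TF co-expression networks (hundreds of
# nodes), so plain BFS/DFS in R is ample.

.graph_adj <- function(n, edges) {
  # adjacency as a list of (neighbor, edge-id) integer matrices
  adj <- rep(list(matrix(integer(), 0L, 2L)), n)
  if (nrow(edges)) {
    inc <- rbind(cbind(edges[, 1L], seq_len(nrow(edges))),
                 cbind(edges[, 2L], seq_len(nrow(edges))))
    nb <- c(edges[, 2L], edges[, 1L])
    sp <- split(seq_len(nrow(inc)), inc[, 1L])
    for (v in names(sp))
      adj[[as.integer(v)]] <- cbind(nb[sp[[v]]], inc[sp[[v]], 2L])
  }
  adj
}

.graph_components <- function(n, edges) {
  adj <- .graph_adj(n, edges)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[v]][, 1L]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

# Bridge finding by depth-first search with low-link values (the classic
# linear-time approach), implemented with an explicit frame stack so deep
# graphs cannot overflow R's call stack. The tree edge into a node is
# skipped by edge id (not by parent node), which stays correct even in the
# presence of parallel edges. Returns the edge indices that are bridges.
.graph_bridges <- function(n, edges) {
  if (!nrow(edges)) return(integer(0))
  adj <- .graph_adj(n, edges)
  disc <- integer(n)          # discovery time, 0 = unvisited
  low <- integer(n)
  parent_edge <- integer(n)   # edge id used to enter the node, 0 at roots
  timer <- 0L
  is_bridge <- logical(nrow(edges))
  for (s in seq_len(n)) {
    if (disc[s]) next
    frame_v <- s; frame_i <- 1L   # per-frame: node and neighbor cursor
    timer <- timer + 1L
    disc[s] <- low[s] <- timer
    while (length(frame_v)) {
      d <- length(frame_v)
      v <- frame_v[d]
      nb <- adj[[v]]
      if (frame_i[d] <= nrow(nb)) {
        u <- nb[frame_i[d], 1L]
        e <- nb[frame_i[d], 2L]
        frame_i[d] <- frame_i[d] + 1L
        if (e == parent_edge[v]) next
        if (disc[u]) {
          low[v] <- min(low[v], disc[u])
        } else {
          parent_edge[u] <- e
          timer <- timer + 1L
          disc[u] <- low[u] <- timer
          frame_v <- c(frame_v, u)
          frame_i <- c(frame_i, 1L)
        }
      } else {
        # v is finished: fold its low-link into the parent and test the
        # tree edge between them
        frame_v <- frame_v[-d]
        frame_i <- frame_i[-d]
        if (length(frame_v)) {
          p <- frame_v[length(frame_v)]
          low[p] <- min(low[p], low[v])
          if (low[v] > disc[p]) is_bridge[parent_edge[v]] <- TRUE
        }
      }
    }
  }
  which(is_bridge)
}
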