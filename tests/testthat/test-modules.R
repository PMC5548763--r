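test_that("network construction matches the all-pairs PCC scan", {
  set.seed(14)
  prof <- matrix(rnorm(30 * 5), 30, 5,
                 dimnames = list(sprintf("tf%02d", 1:30), paste0("t", 1:5)))
  prof[1:10, ] <- rep(prof[1, ], each = 10) +
    matrix(rnorm(50, 0, 0.05), 10, 5)  # a correlated block
  net <- build_tf_network(prof, threshold = 0.9)
  got <- paste(net$edges$from, net$edges$to)
  want <- character(0)
  for (i in 1:29) for (j in (i + 1):30) {
    p <- oracle_pcc(prof[i, ], prof[j, ])
    if (!is.na(p) && p >= 0.9)
      want <- c(want, paste(rownames(prof)[i], rownames(prof)[j]))
  }
  expect_setequal(got, want)
  expect_true(all(net$edges$pcc >= 0.9))
})

test_that("network edge rules: identity, anti-correlation, zero variance", {
  prof <- rbind(a = c(1, 2, 3, 4, 5),
                b = c(2, 4, 6, 8, 10),   # identical shape -> PCC 1
                c = c(5, 4, 3, 2, 1),    # anti-correlated -> no edge
                d = c(3, 3, 3, 3, 3))    # zero variance -> no edge
  net <- build_tf_network(prof)
  expect_identical(paste(net$edges$from, net$edges$to), "a b")
  expect_equal(net$edges$pcc, 1.0)
})

test_that("find_bridges handles path and triangle", {
  path <- structure(list(
    nodes = c("a", "b", "c"),
    edges = data.frame(from = c("a", "b"), to = c("b", "c"), pcc = 1)),
    class = "coexpression_network")
  expect_identical(nrow(find_bridges(path)), 2L)
  tri <- structure(list(
    nodes = c("a", "b", "c"),
    edges = data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                       pcc = 1)), class = "coexpression_network")
  expect_identical(nrow(find_bridges(tri)), 0L)
})

test_that("find_bridges equals the remove-and-test oracle on random graphs", {
  for (seed in 1:25) {
    net <- random_network(n = sample(5:30, 1), p_edge = runif(1, 0.03, 0.3),
                          seed = seed)
    em <- cbind(match(net$edges$from, net$nodes),
                match(net$edges$to, net$nodes))
    got <- find_bridges(net)
    want_idx <- oracle_bridges(length(net$nodes), em)
    expect_identical(paste(got$from, got$to),
                     paste(net$edges$from, net$edges$to)[want_idx])
  }
})

test_that("two cliques joined by a bridge split at the bridge", {
  ct <- clique_tree_network(c(12, 12), seed = 3)
  part <- bisect_network(ct$network, min_size = 10)
  expect_identical(nrow(part$cuts), 1L)
  expect_identical(part$cuts$balancing, 12L)
  expect_identical(sort(unname(lengths(part$modules))), c(12L, 12L))
  expect_equal(adjusted_rand_index(part$membership[names(ct$membership)],
                                   ct$membership), 1)
})

test_that("a single clique stays one module with no cuts", {
  ct <- clique_tree_network(15, seed = 1)
  part <- bisect_network(ct$network)
  expect_identical(nrow(part$cuts), 0L)
  expect_identical(unname(lengths(part$modules)), 15L)
})

test_that("chained cliques are cut most-balanced-first", {
  # cliques 15-12-11 in a chain: the 15|23 cut (balancing 23) precedes
  # the 12|11 cut; final modules are exactly the cliques
  nodes <- c(sprintf("a%02d", 1:15), sprintf("b%02d", 1:12),
             sprintf("c%02d", 1:11))
  clique_edges <- function(ids) {
    pr <- t(utils::combn(ids, 2))
    data.frame(from = pr[, 1], to = pr[, 2], pcc = 1,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(clique_edges(nodes[1:15]), clique_edges(nodes[16:27]),
                 clique_edges(nodes[28:38]),
                 data.frame(from = c("a01", "b01"), to = c("b01", "c01"),
                            pcc = 1))
  net <- structure(list(nodes = nodes, edges = edges),
                   class = "coexpression_network")
  part <- bisect_network(net, min_size = 10)
  expect_identical(part$cuts$from, c("a01", "b01"))
  expect_identical(part$cuts$to, c("b01", "c01"))
  expect_identical(part$cuts$balancing, c(23L, 12L))
  expect_identical(unname(lengths(part$modules)[c("1", "2", "3")]),
                   c(15L, 12L, 11L))
  truth <- rep(1:3, c(15, 12, 11))
  expect_equal(adjusted_rand_index(part$membership[nodes], truth), 1)
})

test_that("clique trees are recovered exactly (planted partitions)", {
  for (seed in 1:10) {
    set.seed(seed)
    sizes <- sample(11:16, sample(2:4, 1), replace = TRUE)
    ct <- clique_tree_network(sizes, seed = seed + 100)
    part <- bisect_network(ct$network, min_size = 10)
    expect_equal(adjusted_rand_index(part$membership[names(ct$membership)],
                                     ct$membership), 1)
    expect_identical(nrow(part$cuts), length(sizes) - 1L)
  }
})

test_that("small components and isolated nodes go to the residual module", {
  ct <- clique_tree_network(c(12, 12), seed = 5)
  net <- ct$network
  net$nodes <- c(net$nodes, "iso1", "iso2", "s1", "s2")
  net$edges <- rbind(net$edges,
                     data.frame(from = "s1", to = "s2", pcc = 1))
  part <- bisect_network(net, min_size = 10)
  expect_identical(part$modules[["0"]], c("iso1", "iso2", "s1", "s2"))
  expect_true(all(part$membership[c("iso1", "iso2", "s1", "s2")] == 0L))
})

test_that("coexpressed_de_genes equals the per-gene PCC scan", {
  set.seed(6)
  tfp <- rnorm(5)
  gp <- matrix(rnorm(40 * 5), 40, 5,
               dimnames = list(sprintf("g%02d", 1:40), NULL))
  gp[1, ] <- tfp * 2 + 1          # identical shape -> included
  gp[2, ] <- -tfp                 # anti-correlated -> excluded
  got <- coexpressed_de_genes(tfp, gp, threshold = 0.9)
  want <- rownames(gp)[vapply(seq_len(nrow(gp)), function(i)
    oracle_pcc(tfp, gp[i, ]) >= 0.9, TRUE)]
  expect_identical(got, want)
  expect_true("g01" %in% got)
  expect_false("g02" %in% got)
})

test_that("module regulation summary counts labels per module", {
  lab <- rbind(tf1 = c(1L, 1L, 0L), tf2 = c(1L, -1L, 0L),
               tf3 = c(0L, -1L, -1L), tf4 = c(0L, 0L, 0L))
  colnames(lab) <- paste0("t", 1:3)
  calls <- structure(list(labels = lab), class = "de_calls")
  part <- structure(list(
    membership = c(tf1 = 1L, tf2 = 1L, tf3 = 2L, tf4 = 2L),
    modules = list(`1` = c("tf1", "tf2"), `2` = c("tf3", "tf4")),
    cuts = data.frame()), class = "module_partition")
  s <- module_regulation_summary(part, calls)
  expect_equal(s$n_up[s$module == 1], c(2, 1, 0))
  expect_equal(s$n_down[s$module == 2], c(0, 1, 1))
  expect_true(all(s$n_up + s$n_down <= 2))
})

test_that("planted expression modules are recovered end-to-end", {
  specs <- list(list(size = 30, pattern = c(2, 2.5, 2, 1, -1)),
                list(size = 25, pattern = c(-1, -0.5, 0.5, 1.5, 2.5)),
                list(size = 15, pattern = c(0, -1.5, -2.5, -1.5, 0)))
  aris <- vapply(1:3, function(seed) {
    cfg <- simulation_config(
      n_genes = 50, n_tfs = 300, n_mirnas = 0, noise_sd = 0.1,
      module_specs = specs, frac_de_genes = 0, n_tf_target_pairs = 0,
      n_mirna_target_pairs = 0, n_suppression_pairs = 0, seed = seed)
    sim <- simulate_dataset(cfg)
    calls <- call_de(fold_changes(sim$dataset, "gene"))
    de_tfs <- intersect(de_features(calls), sim$dataset$tf_genes)
    net <- build_tf_network(
      intensity_matrix(sim$dataset, "tf", "TAB")[de_tfs, , drop = FALSE])
    part <- bisect_network(net)
    truth <- sim$truth$module_of
    mem <- part$membership[names(truth)]
    mem[is.na(mem)] <- -1L  # module TFs missed by the DE caller, if any
    adjusted_rand_index(mem, truth)
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})
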