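rand_profiles <- function(n, prefix, seed, correlated_with = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(n)), NULL))
  m
}

test_that("tf_target_edges equals the per-pair oracle", {
  set.seed(41)
  prof <- rbind(rand_profiles(8, "tf", 41), rand_profiles(20, "g", 42))
  prof[9, ] <- prof[1, ] * 3 + 2           # g01 ~ tf01, PCC 1
  prof[10, ] <- -prof[2, ]                  # g02 ~ -tf02, PCC -1
  tab <- expand.grid(regulator = rownames(prof)[1:8],
                     target = rownames(prof)[9:28],
                     stringsAsFactors = FALSE)
  de <- rownames(prof)  # everything DE
  edges <- tf_target_edges(prof, de, tab, threshold = 0.9)
  key <- paste(edges$source, edges$target)
  for (i in seq_len(nrow(tab))) {
    p <- oracle_pcc(prof[tab$regulator[i], ], prof[tab$target[i], ])
    k <- paste(tab$regulator[i], tab$target[i])
    expect_identical(k %in% key, abs(p) >= 0.9, info = k)
    if (abs(p) >= 0.9)
      expect_identical(edges$sign[key == k], as.integer(sign(p)))
  }
  # non-DE or non-table pairs never appear
  edges2 <- tf_target_edges(prof, setdiff(de, "g01"), tab, 0.9)
  expect_false("g01" %in% edges2$target)
})

test_that("mirna_target_edges requires table support and negative PCC", {
  prof <- rbind(m1 = c(1, 2, 3, 4, 5), g1 = -c(1, 2, 3, 4, 5) + 10,
                g2 = c(1, 2, 3, 4, 5))
  tab <- data.frame(regulator = "m1", target = "g1")
  e <- mirna_target_edges(prof, rownames(prof), tab, 0.9)
  expect_identical(paste(e$source, e$target), "m1 g1")
  expect_identical(e$sign, -1L)
  # negatively co-expressed but absent from the table -> no edge
  tab2 <- data.frame(regulator = "m1", target = "g2")
  expect_identical(nrow(mirna_target_edges(prof, rownames(prof), tab2, 0.9)),
                   0L)
})

test_that("tf_mirna_edges demands treatment-specific co-expression", {
  trt_tf <- rbind(tf1 = c(1, 2, 3, 4, 5), tf2 = c(5, 3, 4, 1, 2))
  trt_mir <- rbind(m1 = c(2, 4, 6, 8, 10), m2 = c(1, 2, 3, 4, 5))
  ctl_tf <- rbind(tf1 = c(2, 1, 3, 2, 4), tf2 = c(1, 2, 3, 4, 5))
  ctl_mir <- rbind(m1 = c(5, 1, 4, 2, 3), m2 = c(2, 4, 6, 8, 10))
  e <- tf_mirna_edges(trt_tf, trt_mir, ctl_tf, ctl_mir, 0.9)
  # tf1-m1 and tf1-m2: treatment PCC 1; control PCC < 0.9 for both
  expect_setequal(paste(e$source, e$target), c("tf1 m1", "tf1 m2"))
  # raise control correlation for tf1-m1 -> edge must disappear
  ctl_tf2 <- rbind(tf1 = c(1, 2, 3, 4, 5), tf2 = c(1, 2, 3, 4, 5))
  ctl_mir2 <- rbind(m1 = c(2, 4, 6, 8, 10), m2 = c(5, 1, 4, 2, 3))
  e2 <- tf_mirna_edges(trt_tf, trt_mir, ctl_tf2, ctl_mir2, 0.9)
  expect_false("tf1 m1" %in% paste(e2$source, e2$target))
  expect_true("tf1 m2" %in% paste(e2$source, e2$target))
})

test_that("edge constructors equal brute-force scans on random instances", {
  for (seed in 1:10) {
    set.seed(seed)
    prof_trt <- matrix(rnorm(25 * 5), 25, 5,
                       dimnames = list(c(sprintf("tf%02d", 1:5),
                                         sprintf("g%02d", 1:15),
                                         sprintf("m%02d", 1:5)), NULL))
    prof_ctl <- prof_trt + matrix(rnorm(125, 0, 2), 25, 5)
    de <- sample(rownames(prof_trt), 20)
    tfs <- grep("^tf", rownames(prof_trt), value = TRUE)
    genes <- grep("^g", rownames(prof_trt), value = TRUE)
    mirs <- grep("^m0", rownames(prof_trt), value = TRUE)
    tab_tf <- unique(data.frame(regulator = sample(tfs, 15, TRUE),
                                target = sample(genes, 15, TRUE),
                                stringsAsFactors = FALSE))
    tab_m <- unique(data.frame(regulator = sample(mirs, 15, TRUE),
                               target = sample(genes, 15, TRUE),
                               stringsAsFactors = FALSE))
    thr <- 0.5  # loose threshold so random profiles produce edges
    e_tf <- tf_target_edges(prof_trt, de, tab_tf, thr)
    e_m <- mirna_target_edges(prof_trt, de, tab_m, thr)
    de_tf <- intersect(tfs, de); de_m <- intersect(mirs, de)
    e_tm <- tf_mirna_edges(prof_trt[de_tf, , drop = FALSE],
                           prof_trt[de_m, , drop = FALSE],
                           prof_ctl[de_tf, , drop = FALSE],
                           prof_ctl[de_m, , drop = FALSE], thr)
    # oracles
    want_tf <- want_m <- want_tm <- character(0)
    for (i in seq_len(nrow(tab_tf))) {
      r <- tab_tf$regulator[i]; t <- tab_tf$target[i]
      if (r %in% de && t %in% de &&
          abs(oracle_pcc(prof_trt[r, ], prof_trt[t, ])) >= thr)
        want_tf <- c(want_tf, paste(r, t))
    }
    for (i in seq_len(nrow(tab_m))) {
      r <- tab_m$regulator[i]; t <- tab_m$target[i]
      if (r %in% de && t %in% de &&
          oracle_pcc(prof_trt[r, ], prof_trt[t, ]) <= -thr)
        want_m <- c(want_m, paste(r, t))
    }
    for (f in de_tf) for (m in de_m) {
      if (oracle_pcc(prof_trt[f, ], prof_trt[m, ]) >= thr &&
          oracle_pcc(prof_ctl[f, ], prof_ctl[m, ]) < thr)
        want_tm <- c(want_tm, paste(f, m))
    }
    expect_setequal(paste(e_tf$source, e_tf$target), want_tf)
    expect_setequal(paste(e_m$source, e_m$target), want_m)
    expect_setequal(paste(e_tm$source, e_tm$target), want_tm)
  }
})

star_network <- function() {
  # one TF, 30 targets, ~75% positively regulated
  targets <- sprintf("g%02d", 1:30)
  signs <- rep(c(1L, -1L), c(22, 8))
  edges <- data.frame(source = "tf1", target = targets, type = "tf_target",
                      sign = signs, pcc = signs * 0.95,
                      stringsAsFactors = FALSE)
  classes <- stats::setNames(c("tf", rep("gene", 30)), c("tf1", targets))
  build_network(edges, classes)
}

test_that("build_network assembles a star with the expected degrees", {
  net <- star_network()
  expect_identical(nrow(net$nodes), 31L)
  rec <- hub_records(net)
  tf <- rec[rec$id == "tf1", ]
  expect_identical(tf$outward, 30L)
  expect_identical(tf$outward_pos, 22L)
  expect_identical(tf$outward_neg, 8L)
  expect_identical(tf$inward, 0L)
  expect_identical(tf$total, 30L)
  expect_equal(tf$outward_pos / tf$outward, 22 / 30)
})

test_that("build_network rejects dangling endpoints and collapses duplicates", {
  edges <- data.frame(source = c("tf1", "tf1"), target = c("g1", "g1"),
                      type = "tf_target", sign = 1L, pcc = 0.95)
  classes <- c(tf1 = "tf", g1 = "gene")
  net <- build_network(edges, classes)
  expect_identical(nrow(net$edges), 1L)
  expect_error(build_network(edges, c(tf1 = "tf")), "annotation")
  # empty input -> empty network
  empty <- build_network(list(), classes)
  expect_identical(nrow(empty$nodes), 0L)
  expect_identical(nrow(empty$edges), 0L)
})

test_that("networks round-trip through edge-list serialization", {
  net <- star_network()
  path <- withr::local_tempfile()
  write_edge_list(net$edges, path)
  back <- read_edge_list(path)
  expect_equal(back, net$edges)
})

test_that("suppression events merge as inward negative TF edges", {
  edges <- data.frame(source = "tf1", target = "g1", type = "tf_target",
                      sign = 1L, pcc = 0.95, stringsAsFactors = FALSE)
  ev <- data.frame(mirna = "m1", tf = "tf1", timepoint = c("t1", "t2"))
  classes <- c(tf1 = "tf", g1 = "gene", m1 = "mirna")
  net <- build_network(edges, classes, suppression_events = ev)
  sup <- net$edges[net$edges$type == "suppression", ]
  expect_identical(nrow(sup), 1L)  # one edge despite two timepoints
  rec <- hub_records(net)
  expect_identical(rec$inward_neg[rec$id == "tf1"], 1L)
  expect_identical(rec$total[rec$id == "tf1"], 2L)
})

test_that("hub identities and ranking match a sort oracle", {
  set.seed(55)
  ids <- c(sprintf("tf%02d", 1:8), sprintf("m%02d", 1:4),
           sprintf("g%02d", 1:10))
  classes <- stats::setNames(rep(c("tf", "mirna", "gene"), c(8, 4, 10)), ids)
  edges <- unique(data.frame(
    source = sample(ids[1:12], 60, TRUE),
    target = sample(ids, 60, TRUE),
    type = "tf_target",
    sign = sample(c(-1L, 1L), 60, TRUE),
    pcc = runif(60, -1, 1), stringsAsFactors = FALSE))
  edges <- edges[edges$source != edges$target, ]
  tps <- paste0("t", 1:3)
  fe <- stats::setNames(sample(c(tps, NA), length(ids), TRUE), ids)
  emergence <- structure(list(first_emergence = fe),
                         class = "emergence_table")
  net <- build_network(edges, classes, emergence = emergence)
  rec <- hub_records(net)
  expect_equal(rec$total, rec$outward + rec$inward)
  expect_equal(rec$outward, rec$outward_pos + rec$outward_neg)
  expect_equal(rec$inward, rec$inward_pos + rec$inward_neg)
  # per-node recount from the raw edge list
  for (i in sample(nrow(rec), 5)) {
    id <- rec$id[i]
    expect_identical(rec$outward[i], sum(net$edges$source == id))
    expect_identical(rec$inward[i], sum(net$edges$target == id))
  }
  hubs <- rank_hubs(net, tps, k_tf = 3, k_mirna = 2)
  for (tp in unique(hubs$timepoint)) for (cl in c("tf", "mirna")) {
    sub <- hubs[hubs$timepoint == tp & hubs$class == cl, ]
    if (!nrow(sub)) next
    pool <- rec[rec$class == cl & !is.na(rec$first_emergence) &
                  rec$first_emergence == tp, ]
    pool <- pool[order(-pool$total, pool$id, method = "radix"), ]
    expect_identical(sub$id,
                     utils::head(pool$id, if (cl == "tf") 3 else 2))
    expect_true(all(diff(sub$total) <= 0))
  }
})

test_that("an edgeless regulator is still rankable with total 0", {
  edges <- data.frame(source = "tf1", target = "g1", type = "tf_target",
                      sign = 1L, pcc = 1, stringsAsFactors = FALSE)
  classes <- c(tf1 = "tf", g1 = "gene", tf2 = "tf")
  fe <- c(tf1 = "t1", g1 = "t1", tf2 = "t1")
  net <- build_network(edges, classes,
                       emergence = structure(list(first_emergence = fe),
                                             class = "emergence_table"))
  # tf2 has no edges, hence is not a node; rank_hubs must not invent it
  hubs <- rank_hubs(net, "t1")
  expect_false("tf2" %in% hubs$id)
  expect_identical(hubs$total[hubs$id == "tf1"], 1L)
})

test_that("cv_enrichment equals exhaustive enumeration on small counts", {
  background <- sprintf("g%03d", 1:100)
  cv <- background[1:20]
  target <- c(background[1:5], background[21:25])  # 5 of 10 CV
  res <- cv_enrichment(target, cv, background)
  expect_equal(res$proportion, 0.5)
  expect_equal(res$p_value, oracle_hyper_tail(5, 20, 100, 10),
               tolerance = 1e-12)
  # target composition identical to background -> p >= 0.5
  res2 <- cv_enrichment(background, cv, background)
  expect_gte(res2$p_value, 0.5)
  expect_equal(cv_enrichment(cv, cv, background)$proportion, 1.0)
  expect_error(cv_enrichment(character(0), cv, background), "target")
  expect_error(cv_enrichment("gX", cv, background), "subset")
})

test_that("the network validator accepts pipeline-built edges", {
  sim <- simulate_dataset(simulation_config(n_genes = 150, n_tfs = 60,
                                            n_mirnas = 30, seed = 17))
  ds <- sim$dataset
  prof_trt <- rbind(intensity_matrix(ds, "gene", "TAB"),
                    intensity_matrix(ds, "mirna", "TAB"))
  prof_ctl <- rbind(intensity_matrix(ds, "gene", "sham"),
                    intensity_matrix(ds, "mirna", "sham"))
  calls_g <- call_de(fold_changes(ds, "gene"))
  calls_m <- call_de(fold_changes(ds, "mirna"))
  de_all <- c(de_features(calls_g), de_features(calls_m))
  de_tfs <- intersect(de_features(calls_g), ds$tf_genes)
  de_mirs <- de_features(calls_m)
  tab_m_gene <- sim$tables$mirna_target[
    !sim$tables$mirna_target$target %in% ds$tf_genes, ]
  e <- list(
    tf_target_edges(prof_trt, de_all, sim$tables$tf_target, 0.9),
    mirna_target_edges(prof_trt, de_all, tab_m_gene, 0.9),
    tf_mirna_edges(prof_trt[de_tfs, , drop = FALSE],
                   prof_trt[de_mirs, , drop = FALSE],
                   prof_ctl[de_tfs, , drop = FALSE],
                   prof_ctl[de_mirs, , drop = FALSE], 0.9))
  net <- build_network(e, feature_classes(ds), cv_genes = ds$cv_genes)
  expect_gt(nrow(net$edges), 0)
  expect_true(validate_network(net, prof_trt, prof_ctl,
                               sim$tables$tf_target, tab_m_gene, 0.9))
})
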