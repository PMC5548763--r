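make_pm <- function(m, ...) probe_matrix(m, ...)

test_that("median scaling hits the reference median and preserves order", {
  m <- matrix(c(5, 10, 20,
                10, 20, 40), ncol = 2,
              dimnames = list(paste0("p", 1:3), c("s1", "s2")))
  scaled <- median_scale(make_pm(m))$intensities
  # sample medians 10 and 20 -> global median 15 -> factors 1.5 and 0.75
  expect_equal(unname(scaled[, 1]), c(5, 10, 20) * 1.5)
  expect_equal(unname(scaled[, 2]), c(10, 20, 40) * 0.75)
  expect_equal(apply(scaled, 2, median), c(s1 = 15, s2 = 15))
  # identical samples are a fixed point
  m2 <- cbind(s1 = c(1, 5, 9), s2 = c(1, 5, 9))
  rownames(m2) <- paste0("p", 1:3)
  expect_equal(median_scale(make_pm(m2))$intensities, m2)
  # single sample: factor 1
  m3 <- m[, 1, drop = FALSE]
  expect_equal(median_scale(make_pm(m3))$intensities, m3)
  # rank order within each sample unchanged (random case)
  set.seed(1)
  m4 <- matrix(rexp(60) + 0.1, ncol = 4,
               dimnames = list(paste0("p", 1:15), paste0("s", 1:4)))
  s4 <- median_scale(make_pm(m4))$intensities
  for (j in 1:4) expect_identical(order(s4[, j]), order(m4[, j]))
  # non-positive median is an error
  m5 <- matrix(c(-2, -1, 0), ncol = 1,
               dimnames = list(paste0("p", 1:3), "s1"))
  expect_error(median_scale(make_pm(m5)), "median")
})

test_that("replicate averaging is the per-group arithmetic mean", {
  m <- matrix(c(2, 1, 4, 2, 6, 9), nrow = 2,
              dimnames = list(c("p1", "p2"), c("a1", "a2", "a3")))
  pm <- make_pm(m, replicate_groups = c(a1 = "g1", a2 = "g1", a3 = "g2"))
  avg <- average_replicates(pm)$intensities
  expect_equal(avg, matrix(c(3, 1.5, 6, 9), nrow = 2,
                           dimnames = list(c("p1", "p2"), c("g1", "g2"))))
  # three replicates (1, 2, 9) -> 4
  m2 <- matrix(c(1, 2, 9), nrow = 1,
               dimnames = list("p1", c("a", "b", "c")))
  pm2 <- make_pm(m2, replicate_groups = c(a = "g", b = "g", c = "g"))
  expect_equal(unname(average_replicates(pm2)$intensities[1, 1]), 4)
  # singleton groups are the identity
  pm3 <- make_pm(m, replicate_groups = c(a1 = "a1", a2 = "a2", a3 = "a3"))
  expect_equal(unname(average_replicates(pm3)$intensities), unname(m))
  expect_error(average_replicates(make_pm(m)), "grouping")
})

test_that("probe filter retains exactly the everywhere->=1 probes", {
  set.seed(42)
  m <- matrix(round(rexp(300, 0.3), 2), ncol = 6,
              dimnames = list(sprintf("p%03d", 1:50), paste0("s", 1:6)))
  kept <- rownames(filter_probes(make_pm(m))$intensities)
  manual <- rownames(m)[vapply(seq_len(nrow(m)),
                               function(i) all(m[i, ] >= 1), TRUE)]
  expect_identical(kept, manual)
  # a single sub-threshold value removes the probe
  m2 <- matrix(c(5, 0.5, 5, 5), nrow = 1,
               dimnames = list("p1", paste0("s", 1:4)))
  expect_identical(nrow(filter_probes(make_pm(m2))$intensities), 0L)
  # all >= 1 is the identity
  expect_equal(filter_probes(make_pm(m + 1))$intensities, m + 1)
})

test_that("quantile normalization matches the hand-worked toy case", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(2, 4, 6))
  rownames(m) <- paste0("p", 1:3)
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(1.5, 3, 4.5))
  expect_equal(unname(qn[, 2]), c(1.5, 3, 4.5))
})

test_that("quantile normalization invariants hold on random matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rlnorm(40 * 4), ncol = 4,
                dimnames = list(sprintf("p%02d", 1:40), paste0("s", 1:4)))
    qn <- quantile_normalize(m)
    # identical multiset of values in every sample
    for (j in 2:4) expect_equal(sort(qn[, j]), sort(qn[, 1]),
                                ignore_attr = TRUE)
    # idempotence
    expect_equal(quantile_normalize(qn), qn)
    # identical samples unchanged
    ident <- cbind(s1 = m[, 1], s2 = m[, 1])
    expect_equal(quantile_normalize(ident), ident)
  }
})

test_that("probe collapse keeps the max-|FC|-sum probe per gene", {
  # toy: 10 genes, up to 3 probes each, checked against a brute-force scan
  set.seed(7)
  genes <- sprintf("g%02d", 1:10)
  probe_gene <- character(0)
  for (g in genes) {
    k <- sample(1:3, 1)
    probe_gene <- c(probe_gene, stats::setNames(
      rep(g, k), sprintf("%s_probe%d", g, seq_len(k))))
  }
  probes <- names(probe_gene)
  m <- matrix(rlnorm(length(probes) * 4, 3), ncol = 4,
              dimnames = list(probes, paste0("s", 1:4)))
  fc <- matrix(rnorm(length(probes) * 5), ncol = 5,
               dimnames = list(probes, paste0("t", 1:5)))
  collapsed <- collapse_probes(make_pm(m, probe_gene = probe_gene), fc)
  expect_identical(rownames(collapsed), sort(unique(unname(probe_gene))))
  for (g in unique(probe_gene)) {
    mine <- probes[probe_gene == g]
    best <- mine[which.max(rowSums(abs(fc[mine, , drop = FALSE])))]
    expect_equal(collapsed[g, ], m[best, ], ignore_attr = TRUE)
  }
  # single-probe genes are passed through unchanged
  pg1 <- stats::setNames(c("gA", "gB"), c("p1", "p2"))
  m1 <- matrix(1:4, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
  storage.mode(m1) <- "double"
  fc1 <- matrix(0, 2, 2, dimnames = list(c("p1", "p2"), c("t1", "t2")))
  expect_equal(unname(collapse_probes(make_pm(m1, probe_gene = pg1), fc1)),
               unname(m1))
})

test_that("miRNA preprocessing applies the flag rule and median combine", {
  probes <- c("m1_a", "m1_b", "m2_a", "m2_b", "m3_a")
  pg <- stats::setNames(c("m1", "m1", "m2", "m2", "m3"), probes)
  m <- matrix(c(1, 5, 100, 2, 3, 4,
                10, 20, 30, 40, 50, 60,
                7, 8, 9), nrow = 5, byrow = TRUE,
              dimnames = list(probes, c("s1", "s2", "s3")))
  flags <- matrix(1, 5, 3, dimnames = dimnames(m))
  flags["m2_a", ] <- -1
  flags["m2_b", ] <- -1   # m2: all flags negative -> removed
  flags["m3_a", 1:2] <- -1  # m3: one flag >= 0 -> retained
  out <- mirna_preprocess(probe_matrix(m, probe_gene = pg), flags)
  expect_identical(rownames(out), c("m1", "m3"))
  # median of replicates before normalization: m1 -> (1.5, 4, 52)
  m_comb <- rbind(m1 = apply(m[1:2, ], 2, median), m3 = m["m3_a", ])
  expect_equal(out, quantile_normalize(m_comb), ignore_attr = TRUE)
  expect_error(mirna_preprocess(probe_matrix(m, probe_gene = pg), NULL),
               "flags")
})

test_that("fold changes are log2 treatment-over-control ratios", {
  trt <- matrix(c(8, 2, 1), 3, dimnames = list(letters[1:3], "t1"))
  ctl <- matrix(c(2, 2, 4), 3, dimnames = list(letters[1:3], "t1"))
  expect_equal(unname(compute_fold_changes(trt, ctl)[, 1]), c(2, 0, -2))
  expect_error(compute_fold_changes(trt, ctl * 0), "positive")
})
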