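# Synthetic two-condition time-course expression data with serialized
# ground truth. The generator emulates the statistical structure the
# downstream analysis assumes: log-normal intensity background shared
# between conditions, treatment-only log2 effects, planted TF co-expression
# modules with distinct temporal activation patterns, planted DE genes and
# miRNAs with sustained temporal response shapes, planted TF->target and
# miRNA->target regulation consistent with the interaction tables, and
# planted miRNA->TF suppression (miRNA up while the TF's effect is
# withheld).

#' Default planted TF module specifications
#'
#' Three modules with distinct temporal activation patterns (log2 effect
#' per time point, treatment condition only): an early-responding module
#' that switches off (and dips) late, a late-rising module, and a
#' mid-repressed module. Patterns given for five time points are linearly
#' interpolated onto other grids.
#'
#' @param timepoints Ordered time-point labels.
#' @param effect Scale of the patterns in log2 units; the default ties the
#'   module amplitude to the generator's single effect-size knob.
#' @param n_tfs Number of TF genes the modules must fit into; sizes
#'   30/25/15 at the default `n_tfs = 300` are scaled proportionally for
#'   other TF counts.
#' @return List of `list(size =, pattern =)` entries.
#' @export
default_module_specs <- function(timepoints = c("d3", "d5", "d7", "d14", "d28"),
                                 effect = 2, n_tfs = 300) {
  base <- list(list(size = 30, pattern = c(1, 1.25, 1, 0.5, -0.5)),
               list(size = 25, pattern = c(-0.5, -0.25, 0.25, 0.75, 1.25)),
               list(size = 15, pattern = c(0, -0.75, -1.25, -0.75, 0)))
  specs <- lapply(base, function(m) {
    m$size <- as.integer(round(m$size * n_tfs / 300))
    m$pattern <- effect * .resample_curve(m$pattern, length(timepoints))
    m
  })
  Filter(function(m) m$size > 0, specs)
}

.resample_curve <- function(y, len) {
  if (length(y) == len) return(y)
  stats::approx(seq(0, 1, length.out = length(y)), y,
                xout = seq(0, 1, length.out = len))$y
}

# Temporal response shapes for planted DE features (multipliers of
# de_effect). Sustained responses with different onsets, as seen for
# stress-response genes; each shape has nonzero variance so that planted
# profiles carry co-expression signal.
.shape_library <- function(len) {
  lapply(list(early = c(1, 1, 1, 0.6, 0.3),
              mid = c(0.3, 1, 1, 1, 0.3),
              late = c(0.3, 0.6, 1, 1, 1)),
         .resample_curve, len = len)
}

.cfg_check <- function(cond, field, msg) {
  if (!cond) stop(sprintf("invalid simulation config: %s (%s)", msg, field),
                  call. = FALSE)
}

#' Simulation configuration
#'
#' Validates and assembles the parameters of [simulate_dataset]. Defaults
#' describe a desk-scale study: 2 conditions x 5 time points, 2,000 non-TF
#' genes, 300 TF genes, 150 miRNAs, three planted TF modules (sizes
#' 30/25/15) with distinct temporal patterns, 10% planted DE features with
#' 2-unit log2 effects over sustained response shapes, and interaction
#' tables (half planted regulation, half decoy rows) scaled to 5% of the
#' gene count.
#'
#' @param n_genes Number of non-TF genes.
#' @param n_tfs Number of TF genes.
#' @param n_mirnas Number of miRNAs.
#' @param timepoints Ordered labels (>= 2).
#' @param conditions Length-2 labels, control first.
#' @param baseline_log_mean,baseline_log_sd Mean/SD of the per-feature
#'   baseline log2 intensity.
#' @param noise_sd SD (log2 units) of the measurement noise of a *fold
#'   change*; each condition receives independent per-cell noise of SD
#'   `noise_sd/sqrt(2)` so that log2(treatment/control) has noise SD
#'   `noise_sd`.
#' @param module_specs List of `list(size, pattern)` planted TF modules;
#'   pattern is a signed log2 effect per time point (treatment only). Sizes
#'   must sum to at most `n_tfs`.
#' @param frac_de_genes Fraction of non-TF genes (and of miRNAs) given a
#'   planted differential-expression effect.
#' @param de_effect Log2 fold-change magnitude of planted DE effects.
#' @param de_shapes Optional list of temporal multiplier vectors for
#'   planted effects; default is a 3-shape sustained-response library.
#' @param n_tf_target_pairs,n_mirna_target_pairs Interaction-table sizes;
#'   half of each table is planted regulation, half decoy rows.
#' @param n_suppression_pairs Planted miRNA -> TF suppression pairs.
#' @param frac_cv Fraction of gene symbols flagged cardiovascular-associated.
#' @param frac_positive_regulation Probability that a planted TF->target
#'   regulation is positive.
#' @param seed Integer seed; identical config and seed give bit-identical
#'   output.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000, n_tfs = 300, n_mirnas = 150,
                              timepoints = c("d3", "d5", "d7", "d14", "d28"),
                              conditions = c("sham", "TAB"),
                              baseline_log_mean = 8, baseline_log_sd = 2,
                              noise_sd = 0.25,
                              module_specs = default_module_specs(
                                timepoints, de_effect, n_tfs),
                              frac_de_genes = 0.1, de_effect = 2,
                              de_shapes = NULL,
                              n_tf_target_pairs = round(0.05 * n_genes),
                              n_mirna_target_pairs = round(0.05 * n_genes),
                              n_suppression_pairs = round(0.1 * n_mirnas),
                              frac_cv = 0.2,
                              frac_positive_regulation = 0.75,
                              seed = 1L) {
  counts <- c(n_genes = n_genes, n_tfs = n_tfs, n_mirnas = n_mirnas,
              n_tf_target_pairs = n_tf_target_pairs,
              n_mirna_target_pairs = n_mirna_target_pairs,
              n_suppression_pairs = n_suppression_pairs)
  for (f in names(counts))
    .cfg_check(is.numeric(counts[[f]]) && length(counts[[f]]) == 1 &&
                 counts[[f]] >= 0 && counts[[f]] == round(counts[[f]]),
               f, "counts must be non-negative integers")
  for (f in c("frac_de_genes", "frac_cv", "frac_positive_regulation")) {
    v <- get(f)
    .cfg_check(is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1, f,
               "proportions must lie in [0, 1]")
  }
  .cfg_check(length(timepoints) >= 2 && !anyDuplicated(timepoints),
             "timepoints", "need >= 2 distinct timepoints")
  .cfg_check(length(conditions) == 2 && !anyDuplicated(conditions),
             "conditions", "need exactly 2 distinct conditions")
  for (f in c("baseline_log_sd", "noise_sd", "de_effect"))
    .cfg_check(get(f) >= 0, f, "scale parameters must be non-negative")
  .cfg_check(is.list(module_specs), "module_specs", "must be a list")
  for (m in module_specs) {
    .cfg_check(is.numeric(m$size) && m$size >= 0 && m$size == round(m$size),
               "module_specs", "module sizes must be non-negative integers")
    .cfg_check(length(m$pattern) == length(timepoints),
               "module_specs", "pattern length must match timepoints")
  }
  .cfg_check(sum(vapply(module_specs, `[[`, 0, "size")) <= n_tfs,
             "module_specs", "module sizes must sum to at most n_tfs")
  if (is.null(de_shapes)) de_shapes <- .shape_library(length(timepoints))
  for (s in de_shapes)
    .cfg_check(length(s) == length(timepoints), "de_shapes",
               "shape length must match timepoints")
  .cfg_check(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
             "seed", "seed must be a single integer")
  structure(list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 n_mirnas = as.integer(n_mirnas),
                 timepoints = as.character(timepoints),
                 conditions = as.character(conditions),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd, noise_sd = noise_sd,
                 module_specs = module_specs,
                 frac_de_genes = frac_de_genes, de_effect = de_effect,
                 de_shapes = de_shapes,
                 n_tf_target_pairs = as.integer(n_tf_target_pairs),
                 n_mirna_target_pairs = as.integer(n_mirna_target_pairs),
                 n_suppression_pairs = as.integer(n_suppression_pairs),
                 frac_cv = frac_cv,
                 frac_positive_regulation = frac_positive_regulation,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# sample() that never falls into the sample.int trap for length-1 vectors
.resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Simulate an expression dataset with ground truth
#'
#' Generates linear-scale, strictly positive intensity matrices for both
#' conditions at every time point, plus interaction tables and a ground
#' truth record of everything planted. All randomness flows from
#' `config$seed`; the caller's RNG state is restored on exit.
#'
#' @param config A [simulation_config].
#' @return A list of class `simulation` with elements `dataset` (an
#'   [expression_dataset]), `truth` (class `ground_truth`: `de_labels`
#'   integer matrix of planted signed labels, `module_of` named integer
#'   vector, `tf_target_pairs` / `mirna_target_pairs` planted regulation
#'   data frames, `suppression_events` data frame), `tables` (full
#'   interaction tables including decoy rows) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed)

  tps <- config$timepoints
  nt <- length(tps)
  tf_ids <- sprintf("TF%03d", seq_len(config$n_tfs))
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  mirna_ids <- sprintf("miR-%03d", seq_len(config$n_mirnas))

  eff_tf <- matrix(0, config$n_tfs, nt, dimnames = list(tf_ids, tps))
  eff_gene <- matrix(0, config$n_genes, nt, dimnames = list(gene_ids, tps))
  eff_mir <- matrix(0, config$n_mirnas, nt, dimnames = list(mirna_ids, tps))

  # planted TF modules occupy the first TFs in blocks
  module_of <- integer(0)
  pos <- 0L
  for (m in seq_along(config$module_specs)) {
    spec <- config$module_specs[[m]]
    if (spec$size == 0) next
    members <- tf_ids[pos + seq_len(spec$size)]
    pos <- pos + spec$size
    eff_tf[members, ] <- matrix(spec$pattern, spec$size, nt, byrow = TRUE)
    module_of[members] <- m
  }
  module_tfs <- names(module_of)

  # planted suppression: miRNA up at the time points where its target TF's
  # planted effect is not positive; if the TF is up everywhere, withhold
  # its effect at the weakest time point so the rule has a ground truth
  sup_events <- data.frame(mirna = character(), tf = character(),
                           timepoint = character(), stringsAsFactors = FALSE)
  sup_pairs <- data.frame(regulator = character(), target = character(),
                          stringsAsFactors = FALSE)
  n_sup <- min(config$n_suppression_pairs, config$n_mirnas)
  if (n_sup > 0 && length(module_tfs)) {
    sup_mirnas <- .resample(mirna_ids, n_sup)
    sup_tfs <- .resample(module_tfs, n_sup, replace = TRUE)
    for (i in seq_len(n_sup)) {
      pat <- eff_tf[sup_tfs[i], ]
      ev <- which(pat <= 0)
      if (!length(ev)) {
        ev <- which.min(pat)
        eff_tf[sup_tfs[i], ev] <- 0
      }
      eff_mir[sup_mirnas[i], ev] <- config$de_effect
      sup_events <- rbind(sup_events,
                          data.frame(mirna = sup_mirnas[i], tf = sup_tfs[i],
                                     timepoint = tps[ev],
                                     stringsAsFactors = FALSE))
    }
    sup_pairs <- unique(data.frame(regulator = sup_mirnas, target = sup_tfs,
                                   stringsAsFactors = FALSE))
  } else sup_mirnas <- character(0)

  shapes <- config$de_shapes
  plant_shape <- function() {
    s <- shapes[[.resample(seq_along(shapes), 1)]]
    sgn <- .resample(c(1, -1), 1)
    sgn * config$de_effect * s
  }

  # planted DE miRNAs (suppressors excluded; their pattern is fixed above)
  free_mirnas <- setdiff(mirna_ids, sup_mirnas)
  n_de_mir <- min(round(config$frac_de_genes * config$n_mirnas),
                  length(free_mirnas))
  de_mirnas <- .resample(free_mirnas, n_de_mir)
  for (m in de_mirnas) eff_mir[m, ] <- plant_shape()

  # planted TF -> target regulation: target inherits the TF's pattern
  # (sign flipped for negative regulation)
  available <- gene_ids
  tf_real <- data.frame(regulator = character(), target = character(),
                        stringsAsFactors = FALSE)
  n_tf_real <- if (length(module_tfs))
    min(ceiling(config$n_tf_target_pairs / 2), length(available)) else 0L
  if (n_tf_real > 0) {
    regs <- .resample(module_tfs, n_tf_real, replace = TRUE)
    targs <- .resample(available, n_tf_real)
    available <- setdiff(available, targs)
    sgn <- ifelse(stats::runif(n_tf_real) < config$frac_positive_regulation,
                  1, -1)
    for (i in seq_len(n_tf_real))
      eff_gene[targs[i], ] <- sgn[i] * eff_tf[regs[i], ]
    tf_real <- data.frame(regulator = regs, target = targs,
                          stringsAsFactors = FALSE)
  }

  # planted miRNA -> target regulation: target mirrors the miRNA's pattern
  mir_real <- data.frame(regulator = character(), target = character(),
                         stringsAsFactors = FALSE)
  n_mir_real <- if (length(de_mirnas))
    min(ceiling(config$n_mirna_target_pairs / 2), length(available)) else 0L
  if (n_mir_real > 0) {
    regs <- .resample(de_mirnas, n_mir_real, replace = TRUE)
    targs <- .resample(available, n_mir_real)
    available <- setdiff(available, targs)
    for (i in seq_len(n_mir_real))
      eff_gene[targs[i], ] <- -eff_mir[regs[i], ]
    mir_real <- data.frame(regulator = regs, target = targs,
                           stringsAsFactors = FALSE)
  }

  # independent planted DE genes
  n_de <- min(round(config$frac_de_genes * config$n_genes), length(available))
  de_genes <- .resample(available, n_de)
  available <- setdiff(available, de_genes)
  for (g in de_genes) eff_gene[g, ] <- plant_shape()

  # decoy interaction rows among unplanted genes
  decoy <- function(regulators, n) {
    n <- min(n, length(available))
    if (n <= 0) return(data.frame(regulator = character(),
                                  target = character(),
                                  stringsAsFactors = FALSE))
    data.frame(regulator = .resample(regulators, n, replace = TRUE),
               target = .resample(available, n), stringsAsFactors = FALSE)
  }
  tf_table <- rbind(tf_real,
                    decoy(tf_ids, config$n_tf_target_pairs - nrow(tf_real)))
  mir_table <- rbind(sup_pairs, mir_real,
                     decoy(mirna_ids, config$n_mirna_target_pairs -
                             nrow(mir_real) - nrow(sup_pairs)))
  ord <- function(d) {
    d <- d[order(d$regulator, d$target, method = "radix"), , drop = FALSE]
    rownames(d) <- NULL
    d
  }

  # intensities: shared per-feature baseline, treatment-only effects,
  # independent per-cell noise of SD noise_sd/sqrt(2) per condition
  cell_sd <- config$noise_sd / sqrt(2)
  build <- function(eff) {
    nfeat <- nrow(eff)
    if (!nfeat) {
      m <- matrix(numeric(), 0, 2 * nt)
      colnames(m) <- .sample_names(config$conditions, tps)
      return(m)
    }
    base <- stats::rnorm(nfeat, config$baseline_log_mean,
                         config$baseline_log_sd)
    ctrl <- base + matrix(stats::rnorm(nfeat * nt, 0, cell_sd), nfeat, nt)
    trt <- base + eff + matrix(stats::rnorm(nfeat * nt, 0, cell_sd),
                               nfeat, nt)
    m <- 2^cbind(ctrl, trt)
    dimnames(m) <- list(rownames(eff), .sample_names(config$conditions, tps))
    m
  }
  genes_mat <- build(rbind(eff_tf, eff_gene))
  mirna_mat <- build(eff_mir)

  all_gene_ids <- c(tf_ids, gene_ids)
  cv_genes <- sort(.resample(all_gene_ids,
                             round(config$frac_cv * length(all_gene_ids))),
                   method = "radix")

  dataset <- expression_dataset(genes = genes_mat, mirnas = mirna_mat,
                                tf_genes = tf_ids, cv_genes = cv_genes,
                                timepoints = tps,
                                conditions = config$conditions)
  labels <- rbind(eff_tf, eff_gene, eff_mir)
  sup_events <- sup_events[order(sup_events$mirna, sup_events$tf,
                                 match(sup_events$timepoint, tps),
                                 method = "radix"), , drop = FALSE]
  rownames(sup_events) <- NULL
  truth <- structure(list(
    de_labels = matrix(as.integer(sign(labels)), nrow(labels),
                       dimnames = dimnames(labels)),
    module_of = module_of,
    tf_target_pairs = ord(tf_real),
    mirna_target_pairs = ord(rbind(sup_pairs, mir_real)),
    suppression_events = sup_events), class = "ground_truth")
  structure(list(dataset = dataset, truth = truth,
                 tables = list(tf_target = ord(tf_table),
                               mirna_target = ord(mir_table)),
                 config = config),
            class = "simulation")
}

#' Write a simulated dataset to a directory
#'
#' Emits the full set of pipeline input files: expression TSVs for genes
#' and miRNAs, feature-class lists, interaction tables, a GMT annotation
#' file derived from the planted module programs, and the ground truth as
#' JSON. Output is deterministic: two calls with identical inputs produce
#' byte-identical files.
#'
#' @param simulation A `simulation` object from [simulate_dataset] (or a
#'   list with compatible `dataset`, `truth`, `tables`).
#' @param directory Output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_dataset <- function(simulation, directory) {
  dataset <- simulation$dataset
  truth <- simulation$truth
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(directory, f)
  write_expression_tsv(dataset$genes, p("genes.tsv"))
  write_expression_tsv(dataset$mirnas, p("mirnas.tsv"))
  write_feature_list(dataset$tf_genes, p("tf_genes.txt"))
  write_feature_list(dataset$cv_genes, p("cv_genes.txt"))
  write_pair_table(simulation$tables$tf_target, p("tf_target_pairs.tsv"))
  write_pair_table(simulation$tables$mirna_target, p("mirna_target_pairs.tsv"))
  sets <- .truth_annotation_sets(truth, dataset)
  write_gmt(sets, p("annotation_sets.gmt"))
  .write_json(list(
    de_labels = list(features = rownames(truth$de_labels),
                     timepoints = colnames(truth$de_labels),
                     labels = unname(apply(truth$de_labels, 1L, c,
                                           simplify = FALSE))),
    module_of = as.list(truth$module_of),
    tf_target_pairs = truth$tf_target_pairs,
    mirna_target_pairs = truth$mirna_target_pairs,
    suppression_events = truth$suppression_events),
    p("ground_truth.json"))
  invisible(c(genes = p("genes.tsv"), mirnas = p("mirnas.tsv"),
              tf_genes = p("tf_genes.txt"), cv_genes = p("cv_genes.txt"),
              tf_target = p("tf_target_pairs.tsv"),
              mirna_target = p("mirna_target_pairs.tsv"),
              annotation_sets = p("annotation_sets.gmt"),
              ground_truth = p("ground_truth.json")))
}

# Annotation sets derived from the planted structure: one term per module
# (members: module TFs plus their planted targets) and one CV term, so the
# enrichment stage has signal to find.
.truth_annotation_sets <- function(truth, dataset) {
  sets <- list()
  desc <- character(0)
  for (m in sort(unique(truth$module_of))) {
    tfs <- names(truth$module_of)[truth$module_of == m]
    targets <- truth$tf_target_pairs$target[
      truth$tf_target_pairs$regulator %in% tfs]
    term <- sprintf("MODULE%d_PROGRAM", m)
    sets[[term]] <- sort(unique(c(tfs, targets)), method = "radix")
    desc[term] <- sprintf("planted regulatory program of TF module %d", m)
  }
  if (length(dataset$cv_genes)) {
    sets[["CV_ASSOCIATED"]] <- dataset$cv_genes
    desc["CV_ASSOCIATED"] <- "cardiovascular-associated gene set"
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Read a simulated dataset back from a directory
#'
#' Inverse of [write_dataset]; reconstructs the `expression_dataset`, the
#' interaction tables and the ground truth.
#'
#' @param directory Directory written by [write_dataset].
#' @param conditions Condition labels (control first).
#' @return A list with `dataset`, `truth`, `tables`.
#' @export
read_dataset <- function(directory, conditions = c("sham", "TAB")) {
  p <- function(f) file.path(directory, f)
  genes <- read_expression_tsv(p("genes.tsv"), conditions)
  tps <- sub(paste0("^", conditions[1], "_"), "",
             grep(paste0("^", conditions[1], "_"), colnames(genes),
                  value = TRUE))
  mirnas <- read_expression_tsv(p("mirnas.tsv"), conditions, tps)
  dataset <- expression_dataset(
    genes = genes, mirnas = mirnas,
    tf_genes = read_feature_list(p("tf_genes.txt")),
    cv_genes = read_feature_list(p("cv_genes.txt")),
    timepoints = tps, conditions = conditions)
  gt <- jsonlite::read_json(p("ground_truth.json"), simplifyVector = TRUE)
  labels <- gt$de_labels$labels
  if (is.list(labels)) labels <- do.call(rbind, labels)
  dimnames(labels) <- list(gt$de_labels$features, gt$de_labels$timepoints)
  empty_pairs <- data.frame(regulator = character(), target = character(),
                            stringsAsFactors = FALSE)
  empty_events <- data.frame(mirna = character(), tf = character(),
                             timepoint = character(), stringsAsFactors = FALSE)
  as_df <- function(x, empty) if (is.data.frame(x) && nrow(x)) x else empty
  truth <- structure(list(
    de_labels = matrix(as.integer(labels), nrow(labels),
                       dimnames = dimnames(labels)),
    module_of = unlist(gt$module_of),
    tf_target_pairs = as_df(gt$tf_target_pairs, empty_pairs),
    mirna_target_pairs = as_df(gt$mirna_target_pairs, empty_pairs),
    suppression_events = as_df(gt$suppression_events, empty_events)),
    class = "ground_truth")
  list(dataset = dataset, truth = truth,
       tables = list(tf_target = read_pair_table(p("tf_target_pairs.tsv")),
                     mirna_target = read_pair_table(p("mirna_target_pairs.tsv"))))
}
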