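#' Pipeline configuration
#'
#' Bundles the input file paths, thresholds and mode flags of
#' [run_pipeline]. Threshold defaults carry the analysis constants: PCC
#' threshold 0.9 for co-expression, 2-SD fold-change envelope for DE calls,
#' 1-SD unresponsive band and 1% extreme-intensity cut for the transition
#' filter, minimum module size 10 for bridge bisection, FDR 0.05 for
#' enrichment.
#'
#' @param genes,mirnas Paths to the expression TSVs (see
#'   [read_expression_tsv]).
#' @param tf_genes,cv_genes Paths to one-symbol-per-line lists.
#' @param tf_target,mirna_target Paths to interaction tables (see
#'   [read_pair_table]).
#' @param annotation_sets Optional path to a GMT file; enables the
#'   enrichment stage.
#' @param transcription_exclusion Optional path to a gene list removed from
#'   the enrichment background in TF mode.
#' @param conditions Length-2 condition labels, control first.
#' @param pcc_threshold,de_sd_multiplier,pcc_filter_sd,percentile_cut,min_module_size,fdr
#'   Analysis constants (see Description).
#' @param de_center,sd_kind Passed to [call_de] as `center` / `sd_method`.
#' @param treatment_specific_tf_edges Passed to [tf_target_edges].
#' @param quantile_normalization Apply between-sample quantile
#'   normalization during preprocessing (default `TRUE`).
#' @param k_tf,k_mirna Hub list sizes per time point.
#' @param seed Echoed into the run manifest (the pipeline itself is
#'   deterministic).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(genes, mirnas, tf_genes, cv_genes,
                            tf_target, mirna_target,
                            annotation_sets = NULL,
                            transcription_exclusion = NULL,
                            conditions = c("sham", "TAB"),
                            pcc_threshold = 0.9, de_sd_multiplier = 2,
                            pcc_filter_sd = 1, percentile_cut = 0.01,
                            min_module_size = 10, fdr = 0.05,
                            de_center = "mean", sd_kind = "sample",
                            treatment_specific_tf_edges = FALSE,
                            quantile_normalization = TRUE,
                            k_tf = 5, k_mirna = 3, seed = 1L) {
  paths <- list(genes = genes, mirnas = mirnas, tf_genes = tf_genes,
                cv_genes = cv_genes, tf_target = tf_target,
                mirna_target = mirna_target,
                annotation_sets = annotation_sets,
                transcription_exclusion = transcription_exclusion)
  for (nm in names(paths))
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]]))
      stop(sprintf("input path '%s' (%s) is not readable", paths[[nm]], nm))
  for (nm in c("pcc_threshold", "de_sd_multiplier", "pcc_filter_sd",
               "min_module_size", "fdr"))
    if (get(nm) <= 0) stop(sprintf("'%s' must be positive", nm))
  if (percentile_cut <= 0 || percentile_cut >= 0.5)
    stop("'percentile_cut' must lie in (0, 0.5)")
  structure(c(paths, list(
    conditions = conditions, pcc_threshold = pcc_threshold,
    de_sd_multiplier = de_sd_multiplier, pcc_filter_sd = pcc_filter_sd,
    percentile_cut = percentile_cut, min_module_size = min_module_size,
    fdr = fdr, de_center = de_center, sd_kind = sd_kind,
    treatment_specific_tf_edges = treatment_specific_tf_edges,
    quantile_normalization = quantile_normalization,
    k_tf = k_tf, k_mirna = k_mirna, seed = as.integer(seed))),
    class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

.write_calls_tsv <- function(calls, fc, path) {
  tps <- colnames(calls$labels)
  out <- data.frame(
    feature = rep(rownames(calls$labels), times = length(tps)),
    timepoint = rep(tps, each = nrow(calls$labels)),
    fold_change = as.vector(fc),
    label = as.vector(calls$labels), stringsAsFactors = FALSE)
  con <- file(path, "wb"); on.exit(close(con))
  writeLines("feature\ttimepoint\tfold_change\tlabel", con)
  writeLines(paste(out$feature, out$timepoint,
                   format(out$fold_change, trim = TRUE, digits = 15),
                   out$label, sep = "\t"), con)
  invisible(path)
}

.write_df_tsv <- function(df, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(x)
      if (is.numeric(x) && !is.integer(x))
        format(x, trim = TRUE, digits = 15) else as.character(x))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing (low-intensity filter, optional quantile
#' normalization), fold changes, DE calling (genes and miRNAs separately),
#' first-emergence classification, cross-condition correlation transition
#' profiling, the DE-TF co-expression network and its bridge-bisection
#' partition, miRNA suppression inference, the integrated regulatory
#' network with hub ranking and CV-gene enrichment, and (when an
#' annotation GMT is configured) over-representation analysis of the DE
#' genes. Every stage's tables are written as TSV/JSON into `out_dir`
#' together with a machine-readable run manifest; given identical inputs
#' the outputs are byte-identical.
#'
#' @param config A [pipeline_config].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results (`dataset`,
#'   `calls`, `emergence`, `transition`, `network_tf`, `partition`,
#'   `suppression`, `network`, `hubs`, `enrichment`, `paths`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  dataset <- .stage("read_inputs", {
    genes <- read_expression_tsv(config$genes, config$conditions)
    tps <- sub(paste0("^", config$conditions[1], "_"), "",
               grep(paste0("^", config$conditions[1], "_"), colnames(genes),
                    value = TRUE))
    mirnas <- read_expression_tsv(config$mirnas, config$conditions, tps)
    expression_dataset(genes, mirnas,
                       tf_genes = read_feature_list(config$tf_genes),
                       cv_genes = read_feature_list(config$cv_genes),
                       timepoints = tps, conditions = config$conditions)
  })
  tf_table <- .stage("read_inputs", read_pair_table(config$tf_target))
  mirna_table <- .stage("read_inputs", read_pair_table(config$mirna_target))

  dataset <- .stage("preprocess", {
    norm <- function(m) {
      m <- m[rowSums(m < 1) == 0L, , drop = FALSE]
      if (config$quantile_normalization) quantile_normalize(m) else m
    }
    genes_n <- norm(dataset$genes)
    expression_dataset(genes_n, norm(dataset$mirnas),
                       tf_genes = intersect(dataset$tf_genes,
                                            rownames(genes_n)),
                       cv_genes = dataset$cv_genes,
                       timepoints = dataset$timepoints,
                       conditions = dataset$conditions)
  })

  fc_gene <- .stage("fold_changes", fold_changes(dataset, "gene"))
  fc_mirna <- .stage("fold_changes", fold_changes(dataset, "mirna"))

  calls <- .stage("differential_expression", {
    list(gene = call_de(fc_gene, k = config$de_sd_multiplier,
                        center = config$de_center,
                        sd_method = config$sd_kind),
         mirna = call_de(fc_mirna, k = config$de_sd_multiplier,
                         center = config$de_center,
                         sd_method = config$sd_kind))
  })
  emergence <- .stage("differential_expression",
                      lapply(calls, classify_emergence))
  .write_calls_tsv(calls$gene, fc_gene, p("de_calls_genes.tsv"))
  .write_calls_tsv(calls$mirna, fc_mirna, p("de_calls_mirnas.tsv"))
  classes <- feature_classes(dataset)
  .write_json(list(genes = de_summary(calls$gene, emergence$gene, classes),
                   mirnas = de_summary(calls$mirna, emergence$mirna)),
              p("de_summary.json"))

  transition <- .stage("transition", transition_profile(
    dataset, percentile = config$percentile_cut,
    sd_mult = config$pcc_filter_sd))
  .write_df_tsv(transition, p("transition.tsv"))
  .write_json(list(argmin = as.list(attr(transition, "argmin"))),
              p("transition.json"))

  de_tfs <- intersect(de_features(calls$gene), dataset$tf_genes)
  trt <- config$conditions[2]
  net_tf <- .stage("modules", build_tf_network(
    intensity_matrix(dataset, "tf", trt)[de_tfs, , drop = FALSE],
    threshold = config$pcc_threshold))
  partition <- .stage("modules",
                      bisect_network(net_tf, config$min_module_size))
  .write_df_tsv(cbind(net_tf$edges[, c("from", "to")],
                      pcc = net_tf$edges$pcc), p("tf_network_edges.tsv"))
  .write_df_tsv(data.frame(node = names(partition$membership),
                           module = unname(partition$membership),
                           stringsAsFactors = FALSE),
                p("module_partition.tsv"))
  if (length(de_tfs))
    .write_df_tsv(module_regulation_summary(partition, calls$gene),
                  p("module_regulation.tsv"))

  mirna_tf_table <- mirna_table[mirna_table$target %in% dataset$tf_genes, ,
                                drop = FALSE]
  suppression <- .stage("suppression", suppressWarnings(
    infer_suppression(calls$mirna, calls$gene, mirna_tf_table)))
  .write_df_tsv(suppression, p("suppression_events.tsv"))
  .write_json(suppression_counts(suppression, dataset$timepoints),
              p("suppression_counts.json"))

  network <- .stage("regulatory_network", {
    profiles_trt <- rbind(intensity_matrix(dataset, "gene", trt),
                          intensity_matrix(dataset, "mirna", trt))
    profiles_ctl <- rbind(intensity_matrix(dataset, "gene",
                                           config$conditions[1]),
                          intensity_matrix(dataset, "mirna",
                                           config$conditions[1]))
    de_all <- c(de_features(calls$gene), de_features(calls$mirna))
    de_mirnas <- de_features(calls$mirna)
    e_tf <- tf_target_edges(profiles_trt, de_all, tf_table,
                            config$pcc_threshold, profiles_ctl,
                            config$treatment_specific_tf_edges)
    e_mir <- mirna_target_edges(
      profiles_trt, de_all,
      mirna_table[!mirna_table$target %in% dataset$tf_genes, , drop = FALSE],
      config$pcc_threshold)
    e_tm <- tf_mirna_edges(
      profiles_trt[de_tfs, , drop = FALSE],
      profiles_trt[de_mirnas, , drop = FALSE],
      profiles_ctl[de_tfs, , drop = FALSE],
      profiles_ctl[de_mirnas, , drop = FALSE],
      config$pcc_threshold)
    combined_emergence <- structure(
      list(first_emergence = c(emergence$gene$first_emergence,
                               emergence$mirna$first_emergence)),
      class = "emergence_table")
    build_network(list(e_tf, e_mir, e_tm), classes,
                  cv_genes = dataset$cv_genes,
                  emergence = combined_emergence,
                  suppression_events = suppression)
  })
  write_edge_list(network$edges, p("network_edges.tsv"))
  .write_df_tsv(network$nodes, p("network_nodes.tsv"))

  hubs <- .stage("hubs", rank_hubs(network, dataset$timepoints,
                                   k_tf = config$k_tf,
                                   k_mirna = config$k_mirna, calls = calls))
  .write_df_tsv(hubs, p("hubs.tsv"))

  cv_res <- .stage("cv_enrichment", {
    targets <- unique(network$edges$target[
      network$edges$type %in% c("tf_target", "mirna_target")])
    targets <- intersect(targets, rownames(dataset$genes))
    if (length(targets))
      cv_enrichment(targets, dataset$cv_genes, rownames(dataset$genes))
    else list(proportion = NA, p_value = NA,
              counts = list(cv_in_targets = 0, target_size = 0))
  })
  .write_json(cv_res, p("cv_enrichment.json"))

  enrichment <- NULL
  if (!is.null(config$annotation_sets)) {
    enrichment <- .stage("enrichment", {
      sets <- read_gmt(config$annotation_sets)
      background <- rownames(dataset$genes)
      if (!is.null(config$transcription_exclusion))
        background <- background_excluding_transcription_terms(
          background, read_feature_list(config$transcription_exclusion))
      query <- intersect(de_features(calls$gene), background)
      enrich(query, sets, background, fdr = config$fdr)
    })
    .write_df_tsv(enrichment, p("enrichment.tsv"))
  }

  manifest <- list(
    package = "tcregnet",
    version = as.character(utils::packageVersion("tcregnet")),
    seed = config$seed,
    config = unclass(config),
    counts = list(
      genes = nrow(dataset$genes), mirnas = nrow(dataset$mirnas),
      de_genes = length(de_features(calls$gene)),
      de_mirnas = length(de_features(calls$mirna)),
      de_tfs = length(de_tfs),
      tf_network_edges = nrow(net_tf$edges),
      modules = sum(names(partition$modules) != "0"),
      module_sizes = unname(lengths(partition$modules)),
      suppression_events = nrow(suppression),
      network_nodes = nrow(network$nodes),
      network_edges = nrow(network$edges)))
  .write_json(manifest, p("manifest.json"))

  invisible(list(dataset = dataset, calls = calls, emergence = emergence,
                 transition = transition, network_tf = net_tf,
                 partition = partition, suppression = suppression,
                 network = network, hubs = hubs, enrichment = enrichment,
                 cv_enrichment = cv_res,
                 paths = list(out_dir = out_dir)))
}
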