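# End-to-end orchestration: simulate (or load) counts -> normalize -> DE ->
# contrast sets -> network -> motifs -> enrichment, writing a deterministic,
# re-loadable bundle of plain-text outputs.

#' Pipeline configuration
#'
#' Thresholds default to the reference protocol: log2FC > 1 and Bonferroni
#' padj < .05 for up-regulation calls, top-5 TFs per target, hypoxia-subgraph
#' degree >= 10, network gene filter (>= 10 samples at expression >= 3) and
#' TF expression filter (>= 3 samples with count > 10).
#'
#' @param sim A [sim_config()]; used unless `counts_file` is given.
#' @param counts_file,metadata_file Optional paths to a counts TSV and
#'   metadata TSV to analyse instead of simulating.
#' @param lfc_min,alpha Up-regulation call thresholds.
#' @param k Top-k edges per target.
#' @param min_degree Minimum hypoxia targets per TF in the subgraph.
#' @param net_min_samples,net_min_value Network gene filter.
#' @param tf_min_samples,tf_min_count TF expression filter.
#' @param n_trees Random-forest trees per target.
#' @param network_targets `"planted"` (default; the planted-edge targets plus
#'   the hypoxia set, keeping runtime modest), or `"all"` filtered genes.
#' @param upstream_len Simulated upstream window length.
#' @param seed Seed forwarded to every stochastic stage.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(), counts_file = NULL,
                            metadata_file = NULL, lfc_min = 1, alpha = 0.05,
                            k = 5, min_degree = 10, net_min_samples = 10,
                            net_min_value = 3, tf_min_samples = 3,
                            tf_min_count = 10, n_trees = 1000,
                            network_targets = c("planted", "all"),
                            upstream_len = 1000, seed = sim$seed) {
  stopifnot(lfc_min > 0, alpha > 0, k >= 1, min_degree >= 1, n_trees >= 1)
  structure(list(sim = sim, counts_file = counts_file,
                 metadata_file = metadata_file, lfc_min = lfc_min,
                 alpha = alpha, k = k, min_degree = min_degree,
                 net_min_samples = net_min_samples,
                 net_min_value = net_min_value,
                 tf_min_samples = tf_min_samples,
                 tf_min_count = tf_min_count, n_trees = n_trees,
                 network_targets = match.arg(network_targets),
                 upstream_len = upstream_len, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage on simulated (or loaded) data and writes a
#' deterministic bundle under `out_dir`: counts/metadata/ground truth, one
#' TSV per contrast, set TSVs and a set-size JSON, the thresholded edge list
#' and r-squared table, the TF classification table, motif presence tables,
#' the degron census, enrichment tables, a planted-class recovery report, and
#' a run log with thresholds and seed. Two runs with the same configuration
#' produce byte-identical bundles.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)

  # --- stage: data ---------------------------------------------------------
  if (!is.null(config$counts_file)) {
    sim <- run_stage("load", {
      counts <- read_counts_tsv(config$counts_file)
      metadata <- read_metadata_tsv(config$metadata_file)
      list(counts = counts, metadata = metadata, truth = NULL)
    })
  } else {
    sim <- run_stage("simulate", simulate_counts(config$sim))
    write_counts_tsv(sim$counts, p("counts.tsv"))
    write_metadata_tsv(sim$metadata, p("metadata.tsv"))
    write_ground_truth_json(sim$truth, p("ground_truth.json"))
  }

  # --- stage: normalize + pooled DE ---------------------------------------
  de <- run_stage("differential_expression", {
    counts <- drop_all_zero_genes(sim$counts)
    sf <- estimate_size_factors(counts)
    norm <- normalize_counts(counts, sf)
    tables <- treatment_contrast_tables(norm, sim$metadata)
    list(counts = counts, size_factors = sf, norm = norm, tables = tables)
  })
  utils::write.table(
    data.frame(sample = names(de$size_factors),
               size_factor = unname(de$size_factors)),
    p("size_factors.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(de$tables)) {
    utils::write.table(de$tables[[nm]], p(paste0("contrast_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- stage: contrast sets -----------------------------------------------
  sets <- run_stage("contrast_sets", {
    hyp <- hypoxia_sets(de$tables, config$lfc_min, config$alpha)
    tr <- time_resolved_sets(de$norm, sim$metadata,
                             lfc_min = config$lfc_min, alpha = config$alpha)
    list(hypoxia = hyp, time_resolved = tr)
  })
  write_gene_sets_tsv(sets$hypoxia, p("hypoxia_sets.tsv"))
  write_gene_sets_tsv(stats::setNames(sets$time_resolved$n_degron,
    paste0("n_degron_m", names(sets$time_resolved$n_degron))),
    p("n_degron_sets.tsv"))
  write_gene_sets_tsv(stats::setNames(sets$time_resolved$ethylene,
    paste0("ethylene_m", names(sets$time_resolved$ethylene))),
    p("ethylene_sets.tsv"))
  jsonlite::write_json(sets$time_resolved$sizes, p("set_sizes.json"),
                       dataframe = "columns", pretty = TRUE)

  # --- stage: network ------------------------------------------------------
  net <- run_stage("network", {
    filtered <- filter_network_genes(de$norm, config$net_min_samples,
                                     config$net_min_value)
    tf_candidates <- if (!is.null(sim$truth)) sim$truth$tf_ids else
      rownames(filtered)
    tfs <- filter_expressed_tfs(de$counts, tf_candidates,
                                config$tf_min_samples, config$tf_min_count)
    tfs <- intersect(tfs, rownames(filtered))
    targets <- if (config$network_targets == "all") rownames(filtered) else {
      tg <- union(sets$hypoxia$hypoxia_all,
                  if (!is.null(sim$truth)) sim$truth$planted_edges$target)
      intersect(rownames(filtered), tg)
    }
    full <- infer_network(filtered, tfs, targets = targets,
                          n_trees = config$n_trees, seed = config$seed)
    top <- threshold_top_k(full, config$k)
    sub <- extract_hypoxia_subgraph(top, sets$hypoxia$hypoxia_all,
                                    config$min_degree)
    cls <- classify_tfs(tf_target_counts(sub, sets$hypoxia$hypoxia_all,
                                         union(sets$hypoxia$ca_only,
                                               sets$hypoxia$mcpca_only)))
    list(tfs = tfs, top = top, subgraph = sub, tf_classes = cls)
  })
  write_edges_tsv(net$top, p("network_top_edges.tsv"))
  write_edges_tsv(net$subgraph, p("network_hypoxia_subgraph.tsv"))
  utils::write.table(
    data.frame(gene = names(net$top$r2), r2 = unname(net$top$r2)),
    p("network_r2.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$tf_classes, p("tf_classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage: motifs -------------------------------------------------------
  motifs <- if (!is.null(sim$truth)) run_stage("motifs", {
    seqs <- simulate_sequences(sim$truth, upstream_len = config$upstream_len,
                               seed = config$seed)
    presence <- motif_presence(seqs$upstream, HRPE_MOTIF)
    degron <- vapply(as.character(seqs$cds),
                     function(s) has_n_degron(translate_cds(s)), logical(1))
    list(seqs = seqs, presence = presence,
         degron = data.frame(gene_id = names(seqs$cds),
                             n_degron = unname(degron)))
  }) else NULL
  if (!is.null(motifs)) {
    write_fasta(motifs$seqs$upstream, p("upstream.fasta"))
    write_fasta(motifs$seqs$cds, p("cds.fasta"))
    utils::write.table(motifs$presence, p("hrpe_presence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(motifs$degron, p("degron_presence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- stage: enrichment ---------------------------------------------------
  enr <- if (!is.null(sim$truth)) run_stage("enrichment", {
    term_map <- split(names(sim$truth$gene_class),
                      unname(sim$truth$gene_class))
    enrich(intersect(sets$hypoxia$hypoxia_all, rownames(de$counts)),
           term_map, rownames(de$counts))
  }) else NULL
  if (!is.null(enr)) {
    utils::write.table(enr, p("enrichment_hypoxia_all.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- stage: recovery report ---------------------------------------------
  report <- if (!is.null(sim$truth)) run_stage("recovery", {
    planted_class_recovery(sim$truth, sets, net, config)
  }) else NULL
  if (!is.null(report)) {
    jsonlite::write_json(report, p("recovery_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
  }

  log <- c(paste0("applehypoxia ",
                  as.character(utils::packageVersion("applehypoxia"))),
           paste0("R ", R.version$major, ".", R.version$minor),
           paste0("seed ", config$seed),
           paste0("lfc_min ", config$lfc_min), paste0("alpha ", config$alpha),
           paste0("k ", config$k), paste0("min_degree ", config$min_degree),
           paste0("n_trees ", config$n_trees))
  writeLines(log, p("run_log.txt"))

  invisible(list(sim = sim, de = de, sets = sets, network = net,
                 motifs = motifs, enrichment = enr, report = report))
}

#' Sensitivity/precision of the recovered sets and network against the
#' planted ground truth
#'
#' @param truth Ground truth from [simulate_counts()].
#' @param sets Contrast-set results (as produced inside [run_pipeline()]).
#' @param net Network results (as produced inside [run_pipeline()]).
#' @param config The [pipeline_config()] in force.
#' @return Nested list of recovery statistics.
#' @keywords internal
planted_class_recovery <- function(truth, sets, net, config) {
  classes <- truth$gene_class
  sustained <- names(classes)[classes == "ndegron_sustained"]
  ethylene <- names(classes)[classes == "ethylene_late"]

  nd_sens <- vapply(sets$time_resolved$n_degron, function(s)
    length(intersect(s, sustained)) / length(sustained), 0)
  eth_in_nd <- vapply(sets$time_resolved$n_degron, function(s)
    length(intersect(s, ethylene)), 0)

  planted <- paste(truth$planted_edges$tf, truth$planted_edges$target)
  kept <- paste(net$top$edges$tf, net$top$edges$target)
  list(
    n_degron_sensitivity = as.list(nd_sens),
    ethylene_genes_in_n_degron = as.list(eth_in_nd),
    ethylene_set_sizes = as.list(lengths(sets$time_resolved$ethylene)),
    hypoxia_all_size = length(sets$hypoxia$hypoxia_all),
    edge_recovery = if (length(planted) > 0)
      mean(planted %in% kept) else NA_real_)
}
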