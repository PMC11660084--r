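#!/usr/bin/env Rscript
# Stage 4: GENIE3-style TF regulatory network.
#
# Filters (genes: >= 10 samples at normalized expression >= 3; TFs: >= 3
# samples with raw count > 10), then one random-forest regression per target
# (1000 trees, mtry = sqrt(#TFs)) over the hypoxia gene set and the planted
# targets. Edges are thresholded to the top 5 TFs per target, the hypoxia
# subgraph keeps TFs with >= 10 hypoxia targets, and each TF is classified as
# "standard" or "ethylene-mediated" by which compartment dominates its
# targets relative to the normalized dividing line y = (max y / max x) * x.
# Finally, the degron-carrying TFs (the ERF VII stand-ins) get a focal
# subnetwork with target-pool overlaps.

suppressMessages(library(applehypoxia))

counts <- drop_all_zero_genes(read_counts_tsv("results/data/counts.tsv"))
truth <- read_ground_truth_json("results/data/ground_truth.json")
norm <- normalize_counts(counts, estimate_size_factors(counts))
hyp <- read.table("results/de/hypoxia_sets.tsv", header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
hypoxia_all <- hyp$gene_id[hyp$set == "hypoxia_all"]
eth_subsets <- hyp$gene_id[hyp$set %in% c("ca_only", "mcpca_only")]

filtered <- filter_network_genes(norm)
tf_list <- readLines("results/data/tf_list.txt")
tfs <- filter_expressed_tfs(counts, tf_list)
cat(sprintf("network filter kept %d of %d genes; %d of %d TFs expressed\n",
            nrow(filtered), nrow(norm), length(tfs), length(tf_list)))

targets <- intersect(rownames(filtered),
                     union(hypoxia_all, truth$planted_edges$target))
net <- infer_network(filtered, tfs, targets = targets, seed = 1)
top <- threshold_top_k(net, 5)

dir.create("results/network", recursive = TRUE, showWarnings = FALSE)
write_edges_tsv(top, "results/network/top5_edges.tsv")
write.table(data.frame(gene = names(top$r2), r2 = unname(top$r2)),
            "results/network/target_r2.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

planted <- paste(truth$planted_edges$tf, truth$planted_edges$target)
kept <- paste(top$edges$tf, top$edges$target)
cat(sprintf("planted-edge recovery after top-5 thresholding: %.0f%% (%d/%d)\n",
            100 * mean(planted %in% kept), sum(planted %in% kept),
            length(planted)))
cat(sprintf("median out-of-bag r2 over targets: %.2f\n", median(top$r2)))

sub <- extract_hypoxia_subgraph(top, hypoxia_all, min_degree = 10)
write_edges_tsv(sub, "results/network/hypoxia_subgraph.tsv")
cat(sprintf("hypoxia subgraph: %d TFs regulating >= 10 of %d hypoxia genes\n",
            length(unique(sub$edges$tf)), length(hypoxia_all)))

cls <- classify_tfs(tf_target_counts(top, hypoxia_all, eth_subsets))
write.table(cls, "results/network/tf_classification.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("TF roles:\n"); print(table(cls$label))

focal <- intersect(truth$degron_tfs, unique(top$edges$tf))
if (length(focal) >= 2) {
  fsub <- focal_tf_subnetwork(top, focal, annotate_set = hypoxia_all)
  write_edges_tsv(structure(list(edges = fsub$edges), class = "grn"),
                  "results/network/degron_tf_subnetwork.tsv")
  write.table(fsub$overlap, "results/network/degron_tf_overlap.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("degron-TF focal subnetwork: %d TFs, %d targets, all-TF overlap %d\n",
              length(focal), nrow(fsub$targets),
              length(fsub$intersection_all)))
}
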