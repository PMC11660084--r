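#!/usr/bin/env Rscript
# Stage 3: per-timepoint "n-degron" and "ethylene" response sets.
#
# At each long-term storage month, genes up in both CA and MCPCA vs MCP form
# the "n-degron" set (hypoxia response independent of ethylene perception);
# genes up in CA vs both MCP and MCPCA form the "ethylene" set (hypoxia
# response requiring ethylene perception). Their sizes over time are the
# machine-readable twin of the study's two response curves: the n-degron
# count starts high and declines, the ethylene count starts near zero and
# rises steeply late in storage.

suppressMessages(library(applehypoxia))

counts <- drop_all_zero_genes(read_counts_tsv("results/data/counts.tsv"))
metadata <- read_metadata_tsv("results/data/metadata.tsv")
truth <- read_ground_truth_json("results/data/ground_truth.json")
norm <- normalize_counts(counts, estimate_size_factors(counts))

tr <- time_resolved_sets(norm, metadata)
dir.create("results/sets", recursive = TRUE, showWarnings = FALSE)
write_gene_sets_tsv(setNames(tr$n_degron, paste0("n_degron_m", names(tr$n_degron))),
                    "results/sets/n_degron_sets.tsv")
write_gene_sets_tsv(setNames(tr$ethylene, paste0("ethylene_m", names(tr$ethylene))),
                    "results/sets/ethylene_sets.tsv")
jsonlite::write_json(tr$sizes, "results/sets/set_sizes.json",
                     dataframe = "columns", pretty = TRUE)

print(tr$sizes, row.names = FALSE)
cls <- truth$gene_class
sustained <- names(cls)[cls == "ndegron_sustained"]
ethylene <- names(cls)[cls == "ethylene_late"]
sens <- sapply(tr$n_degron, function(s) mean(sustained %in% s))
cat(sprintf("sustained-class sensitivity in n-degron sets: %.2f-%.2f\n",
            min(sens), max(sens)))
cat(sprintf("ethylene-class genes leaking into n-degron sets: %d\n",
            sum(sapply(tr$n_degron, function(s) sum(ethylene %in% s)))))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  df <- rbind(data.frame(month = tr$sizes$timepoint, set = "n-degron",
                         genes = tr$sizes$n_degron),
              data.frame(month = tr$sizes$timepoint, set = "ethylene",
                         genes = tr$sizes$ethylene))
  p <- ggplot(df, aes(month, genes, colour = set)) +
    geom_line() + geom_point() +
    labs(x = "months postharvest", y = "up-regulated genes",
         title = "Two waves of the long-term hypoxia response") +
    theme_minimal()
  dir.create("results/figures", showWarnings = FALSE)
  ggsave("results/figures/set_sizes.png", p, width = 6, height = 4, dpi = 150)
  cat("wrote results/figures/set_sizes.png\n")
}
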