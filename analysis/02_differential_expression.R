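#!/usr/bin/env Rscript
# Stage 2: normalization and pooled-by-treatment differential expression.
#
# Median-of-ratios size factors, then NB Wald contrasts of each hypoxic
# treatment (CA, MCPCA) against every other treatment with samples pooled
# across timepoints, and the hypoxia set logic: a gene is a hypoxia response
# gene when one hypoxic treatment beats ALL five normoxic treatments at
# log2FC > 1 and Bonferroni padj < .05; the CA-only and MCPCA-only subsets
# additionally require beating the other hypoxic treatment.

suppressMessages(library(applehypoxia))

counts <- drop_all_zero_genes(read_counts_tsv("results/data/counts.tsv"))
metadata <- read_metadata_tsv("results/data/metadata.tsv")
truth <- read_ground_truth_json("results/data/ground_truth.json")

sf <- estimate_size_factors(counts)
norm <- normalize_counts(counts, sf)
dir.create("results/de", recursive = TRUE, showWarnings = FALSE)
write.table(data.frame(sample = names(sf), size_factor = unname(sf)),
            "results/de/size_factors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_counts_tsv(norm, "results/de/normalized.tsv")

tables <- treatment_contrast_tables(norm, metadata)
for (nm in names(tables)) {
  write.table(tables[[nm]], sprintf("results/de/contrast_%s.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

sets <- hypoxia_sets(tables)
write_gene_sets_tsv(sets, "results/de/hypoxia_sets.tsv")

cls <- truth$gene_class
cat(sprintf("hypoxia-upregulated set: %d genes (CA-only %d, MCPCA-only %d)\n",
            length(sets$hypoxia_all), length(sets$ca_only),
            length(sets$mcpca_only)))
for (k in c("ndegron_sustained", "ndegron_transient", "ethylene_late")) {
  members <- names(cls)[cls == k]
  cat(sprintf("  %-18s %3d planted, %3d recovered in hypoxia set\n", k,
              length(members), sum(members %in% sets$hypoxia_all)))
}
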