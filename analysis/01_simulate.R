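#!/usr/bin/env Rscript
# Stage 1: generate the synthetic postharvest storage experiment.
#
# Emulates the 7-treatment design (PreTreat once at month 0; A1/A10/A20 over
# the first three months; MCP/CA/MCPCA at months 2,4,5,6,7,8,9; 3 biological
# replicates per cell) with ~2,000 genes, 100 TFs, planted response classes,
# 60 planted TF->target edges, and promoter/CDS sequences carrying planted
# HRPE and N-degron motifs. Everything downstream is validated against the
# ground truth written here.

suppressMessages(library(applehypoxia))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

config <- sim_config() # the study conditions; see ?sim_config
sim <- simulate_counts(config)
seqs <- simulate_sequences(sim$truth, upstream_len = 1000, seed = config$seed)

write_counts_tsv(sim$counts, file.path(out, "counts.tsv"))
write_metadata_tsv(sim$metadata, file.path(out, "metadata.tsv"))
write_ground_truth_json(sim$truth, file.path(out, "ground_truth.json"))
write_fasta(seqs$upstream, file.path(out, "upstream1000.fasta"))
write_fasta(seqs$cds, file.path(out, "cds.fasta"))
writeLines(sim$truth$tf_ids, file.path(out, "tf_list.txt"))

cat(sprintf("simulated %d genes x %d samples (%d TFs, %d planted edges)\n",
            nrow(sim$counts), ncol(sim$counts),
            length(sim$truth$tf_ids), nrow(sim$truth$planted_edges)))
print(table(sim$truth$gene_class))
cat("wrote", out, "\n")
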