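#!/usr/bin/env Rscript
# Stage 6: over-representation of the recovered sets in the planted classes.
#
# Uses the ground-truth class map as a term map (the synthetic counterpart of
# a GO annotation) and asks which classes are enriched in the recovered
# hypoxia set and in the month-9 ethylene set. The hypoxia set should be
# dominated by the two n-degron classes, the late ethylene set by the
# ethylene_late class.

suppressMessages(library(applehypoxia))

counts <- drop_all_zero_genes(read_counts_tsv("results/data/counts.tsv"))
truth <- read_ground_truth_json("results/data/ground_truth.json")
hyp <- read.table("results/de/hypoxia_sets.tsv", header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
eth <- read.table("results/sets/ethylene_sets.tsv", header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)

universe <- rownames(counts)
term_map <- split(names(truth$gene_class), unname(truth$gene_class))

dir.create("results/enrichment", recursive = TRUE, showWarnings = FALSE)

res_hyp <- enrich(intersect(hyp$gene_id[hyp$set == "hypoxia_all"], universe),
                  term_map, universe)
write.table(res_hyp, "results/enrichment/hypoxia_all_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("hypoxia set vs planted classes:\n")
print(res_hyp, row.names = FALSE, digits = 3)

last <- sort(unique(eth$set))[length(unique(eth$set))]
res_eth <- enrich(intersect(eth$gene_id[eth$set == last], universe),
                  term_map, universe)
write.table(res_eth, "results/enrichment/ethylene_last_month_classes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\n", last, "set vs planted classes:\n")
print(res_eth, row.names = FALSE, digits = 3)
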