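# Shared fixtures, built once per test run.

# default-configuration simulation, normalized, with pooled and per-timepoint
# contrast tables -- several suites exercise pieces of it
default_sim_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- simulate_counts(sim_config())
      counts <- drop_all_zero_genes(s$counts)
      sf <- estimate_size_factors(counts)
      norm <- normalize_counts(counts, sf)
      cache <<- list(sim = s, counts = counts, sf = sf, norm = norm)
    }
    cache
  }
})

# a tiny simulation for cheap structural checks
tiny_config <- function(seed = 5) {
  sim_config(n_genes = 120, n_tfs = 12, n_edges = 6, n_degron_tfs = 2,
             seed = seed)
}

# build a contrast table directly (for set-logic tests): named vectors of
# log2fc and padj over the same genes
fake_table <- function(genes, log2fc, padj) {
  data.frame(gene = genes, log2fc = log2fc, se = 1, p = padj, padj = padj,
             stringsAsFactors = FALSE)
}

# tables for all 12 hypoxia-logic contrasts where every gene is a clear null
null_hypoxia_tables <- function(genes) {
  prs <- hypoxia_contrast_pairs()
  out <- lapply(prs, function(pr) fake_table(genes, 0, 1))
  names(out) <- vapply(prs, function(pr) paste0(pr[1], "_vs_", pr[2]), "")
  out
}

# random tables for the fuzz tests: antisymmetric in the CA/MCPCA pair so the
# two orientations of that contrast are consistent
fuzz_hypoxia_tables <- function(genes) {
  prs <- hypoxia_contrast_pairs()
  out <- list()
  for (pr in prs) {
    nm <- paste0(pr[1], "_vs_", pr[2])
    out[[nm]] <- fake_table(genes, stats::rnorm(length(genes), 0, 2),
                            stats::runif(length(genes)))
  }
  rev_lfc <- -out[["CA_vs_MCPCA"]]$log2fc
  out[["MCPCA_vs_CA"]]$log2fc <- rev_lfc
  out[["MCPCA_vs_CA"]]$padj <- out[["CA_vs_MCPCA"]]$padj
  out
}
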