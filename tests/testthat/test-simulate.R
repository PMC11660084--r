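test_that("the design has the 7-treatment structure with full replication", {
  d <- simulate_design(sim_config())
  expect_setequal(unique(d$treatment),
                  c("PreTreat", "A1", "A10", "A20", "MCP", "CA", "MCPCA"))
  # long-term treatments contribute 7 months x 3 replicates = 21 samples
  for (trt in c("MCP", "CA", "MCPCA")) {
    expect_equal(sum(d$treatment == trt), 21)
    expect_setequal(unique(d$timepoint[d$treatment == trt]),
                    c(2, 4, 5, 6, 7, 8, 9))
  }
  expect_equal(unique(d$timepoint[d$treatment == "PreTreat"]), 0)
  expect_equal(max(table(paste(d$treatment, d$timepoint))), 3)
  expect_false(any(duplicated(d$sample)))

  d1 <- simulate_design(sim_config(n_reps = 1))
  expect_equal(max(table(paste(d1$treatment, d1$timepoint))), 1)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_tfs = 50, n_genes = 50), "smaller than n_genes")
  expect_error(sim_config(dispersion = -0.1), "dispersion")
  expect_error(sim_config(longterm_months = c(4, 2)), "strictly increasing")
  expect_error(sim_config(shortterm_months = numeric()), "non-empty")
  bad <- c(null = 0.5, ndegron_transient = 0.2, ndegron_sustained = 0.2,
           ethylene_late = 0.2, maturation = 0.2)
  expect_error(sim_config(class_fractions = bad), "sum to 1")
})

test_that("the same configuration reproduces byte-identical output", {
  cfg <- tiny_config()
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  q1 <- simulate_sequences(s1$truth, upstream_len = 200, seed = 3)
  q2 <- simulate_sequences(s2$truth, upstream_len = 200, seed = 3)
  expect_identical(as.character(q1$upstream), as.character(q2$upstream))
  expect_identical(as.character(q1$cds), as.character(q2$cds))
})

test_that("null-gene marginal moments match the negative binomial", {
  # one large cell: many replicates of the same treatment x timepoint
  cfg <- sim_config(n_genes = 400, n_tfs = 4, n_edges = 0, n_degron_tfs = 0,
                    class_fractions = c(null = 1, ndegron_transient = 0,
                                        ndegron_sustained = 0,
                                        ethylene_late = 0, maturation = 0),
                    n_reps = 200, longterm_months = 2, shortterm_months = 1,
                    dispersion = 0.1, seed = 8)
  s <- simulate_counts(cfg)
  cells <- s$metadata$sample[s$metadata$treatment == "MCP"]
  x <- s$counts[setdiff(rownames(s$counts), s$truth$tf_ids), cells]
  m <- rowMeans(x)
  v <- apply(x, 1, var)
  # var = mu + alpha mu^2, so pooled alpha-hat should recover 0.1
  alpha_hat <- median((v - m) / m^2)
  expect_equal(alpha_hat, 0.1, tolerance = 0.03)

  cfg0 <- sim_config(n_genes = 400, n_tfs = 4, n_edges = 0, n_degron_tfs = 0,
                     class_fractions = c(null = 1, ndegron_transient = 0,
                                         ndegron_sustained = 0,
                                         ethylene_late = 0, maturation = 0),
                     n_reps = 200, longterm_months = 2, shortterm_months = 1,
                     dispersion = 0, seed = 8)
  s0 <- simulate_counts(cfg0)
  x0 <- s0$counts[setdiff(rownames(s0$counts), s0$truth$tf_ids),
                  s0$metadata$sample[s0$metadata$treatment == "MCP"]]
  disp0 <- median(apply(x0, 1, var) / rowMeans(x0))
  expect_equal(disp0, 1, tolerance = 0.05) # Poisson limit
})

test_that("with no effects and no coupling, up-calls occur at the type-I
           rate only", {
  cfg <- sim_config(n_genes = 1000, effect_log2fc = 0, edge_strength = 0,
                    seed = 10)
  s <- simulate_counts(cfg)
  counts <- drop_all_zero_genes(s$counts)
  norm <- normalize_counts(counts, estimate_size_factors(counts))
  sets <- hypoxia_sets(treatment_contrast_tables(norm, s$metadata))
  expect_lte(length(sets$hypoxia_all), 2) # near zero at m = 1000
})

test_that("planted-edge targets carry more mutual information about their
           parent TF than about random TFs", {
  b <- default_sim_bundle()
  s <- b$sim
  norm <- b$norm
  mi <- function(x, y) {
    bx <- cut(x, breaks = stats::quantile(x, 0:4 / 4), include.lowest = TRUE)
    by <- cut(y, breaks = stats::quantile(y, 0:4 / 4), include.lowest = TRUE)
    tab <- table(bx, by) / length(x)
    px <- rowSums(tab); py <- colSums(tab)
    sum(tab * log(tab / outer(px, py)), na.rm = TRUE)
  }
  set.seed(11)
  edges <- s$truth$planted_edges[1:20, ]
  wins <- 0
  for (i in seq_len(nrow(edges))) {
    tgt <- log1p(norm[edges$target[i], ])
    parent_mi <- mi(tgt, log1p(norm[edges$tf[i], ]))
    decoys <- sample(setdiff(s$truth$tf_ids, edges$tf[i]), 5)
    decoy_mi <- vapply(decoys, function(tf) mi(tgt, log1p(norm[tf, ])), 0)
    wins <- wins + (parent_mi > max(decoy_mi))
  }
  expect_gte(wins, 18)
})

test_that("planted sequence motifs are exactly where the ground truth says", {
  cfg <- tiny_config()
  s <- simulate_counts(cfg)
  seqs <- simulate_sequences(s$truth, upstream_len = 300, seed = 2)
  pres <- motif_presence(seqs$upstream, HRPE_MOTIF)
  expect_setequal(pres$seq_id[pres$present], s$truth$motif_genes)
  # recorded offsets point at real matches
  for (g in s$truth$motif_genes) {
    off <- seqs$motif_offsets[[g]]
    hit <- scan_motif(as.character(seqs$upstream[[g]]), HRPE_MOTIF)
    expect_true(off %in% hit$offset)
  }
  # degron TFs translate to an MCGGAI/V N-terminus; no other gene does
  prot <- vapply(as.character(seqs$cds), translate_cds, "")
  has <- vapply(prot, has_n_degron, logical(1))
  expect_setequal(names(seqs$cds)[has], s$truth$degron_tfs)
  expect_true(all(substr(prot[s$truth$degron_tfs], 1, 6) %in%
                  c("MCGGAI", "MCGGAV")))
  expect_error(simulate_sequences(s$truth, upstream_len = 5), "at least")
})

test_that("every gene has exactly one class and planted edges start at TFs", {
  s <- simulate_counts(tiny_config())
  expect_equal(length(s$truth$gene_class), nrow(s$counts))
  expect_true(all(s$truth$gene_class %in%
    c("null", "ndegron_transient", "ndegron_sustained", "ethylene_late",
      "maturation")))
  expect_true(all(s$truth$planted_edges$tf %in% s$truth$tf_ids))
  expect_false(any(s$truth$planted_edges$target %in% s$truth$tf_ids))
  expect_true(all(s$counts >= 0))
})
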