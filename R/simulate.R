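# Synthetic postharvest storage experiment.
#
# Emulates the 7-treatment design (PreTreat; air-stored A1/A10/A20; 1-MCP
# treated MCP; controlled-atmosphere CA; and MCPCA = 1-MCP + CA) with
# negative-binomial counts, planted gene response classes, planted TF->target
# regulatory edges, and promoter/CDS sequences carrying planted motifs, so
# every downstream stage can be validated against known ground truth.

TREATMENTS <- c("PreTreat", "A1", "A10", "A20", "MCP", "CA", "MCPCA")
NORMOXIC_TREATMENTS <- c("PreTreat", "A1", "A10", "A20", "MCP")
HYPOXIC_TREATMENTS <- c("CA", "MCPCA")
LONGTERM_TREATMENTS <- c("MCP", "CA", "MCPCA")
SHORTTERM_TREATMENTS <- c("A1", "A10", "A20")
GENE_CLASSES <- c("null", "ndegron_transient", "ndegron_sustained",
                  "ethylene_late", "maturation")

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic storage experiment.
#' Defaults describe the study conditions the rest of the package is tested
#' against: roughly 2,000 genes of which 100 are transcription factors,
#' three biological replicates per treatment x timepoint cell, long-term
#' treatments (MCP, CA, MCPCA) sampled at months 2, 4, 5, 6, 7, 8 and 9, and
#' short-term air treatments sampled over the first three months.
#'
#' Gene response classes:
#' \describe{
#'   \item{null}{no treatment effect.}
#'   \item{ndegron_transient}{induced in CA and MCPCA at the start of
#'     long-term storage, decaying back to baseline over the storage window.}
#'   \item{ndegron_sustained}{constitutively induced in CA and MCPCA
#'     throughout long-term storage.}
#'   \item{ethylene_late}{induced only in CA (requires ethylene perception),
#'     rising from baseline early in storage to full strength at the final
#'     month.}
#'   \item{maturation}{induced in the air treatments (A1/A10/A20) only;
#'     provides true negatives for the CA-only/MCPCA-only logic.}
#' }
#'
#' @param n_genes Number of genes.
#' @param n_tfs Number of genes flagged as transcription factors
#'   (`n_tfs < n_genes`).
#' @param class_fractions Named proportions over the five gene classes,
#'   summing to 1.
#' @param base_mean_log_range Interval (natural log scale) from which
#'   per-gene baseline means are drawn uniformly.
#' @param effect_log2fc Induction magnitude at full strength, in log2 units.
#' @param dispersion Negative-binomial dispersion alpha >= 0
#'   (`var = mu + alpha * mu^2`); 0 gives Poisson counts.
#' @param n_reps Replicates per treatment x timepoint cell.
#' @param longterm_months Ordered sampling months for MCP/CA/MCPCA.
#' @param shortterm_months Ordered sampling months for A1/A10/A20.
#' @param n_edges Number of planted TF -> target edges (one parent TF per
#'   target; targets are drawn from null-class non-TF genes).
#' @param edge_strength Coupling coefficient: contribution of the parent TF's
#'   standardized latent activity to the target's natural-log mean.
#' @param n_degron_tfs Number of TFs whose CDS is given an N-terminal
#'   MCGGAI/V degron.
#' @param seed Integer seed; the same configuration reproduces byte-identical
#'   output.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000, n_tfs = 100,
                       class_fractions = c(null = 0.8,
                                           ndegron_transient = 0.05,
                                           ndegron_sustained = 0.05,
                                           ethylene_late = 0.05,
                                           maturation = 0.05),
                       base_mean_log_range = c(log(100), log(2000)),
                       effect_log2fc = 2, dispersion = 0.05, n_reps = 3,
                       longterm_months = c(2, 4, 5, 6, 7, 8, 9),
                       shortterm_months = c(0.25, 1, 2, 3),
                       n_edges = 60, edge_strength = 0.7,
                       n_degron_tfs = 5, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              class_fractions = class_fractions,
              base_mean_log_range = base_mean_log_range,
              effect_log2fc = effect_log2fc, dispersion = dispersion,
              n_reps = as.integer(n_reps),
              longterm_months = longterm_months,
              shortterm_months = shortterm_months,
              n_edges = as.integer(n_edges), edge_strength = edge_strength,
              n_degron_tfs = as.integer(n_degron_tfs),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes > 0, cfg$n_tfs > 0, cfg$n_reps >= 1,
            cfg$n_edges >= 0, cfg$n_degron_tfs >= 0)
  if (cfg$n_tfs >= cfg$n_genes) stop("n_tfs must be smaller than n_genes")
  if (!setequal(names(cfg$class_fractions), GENE_CLASSES)) {
    stop("class_fractions must be named over: ", paste(GENE_CLASSES, collapse = ", "))
  }
  if (abs(sum(cfg$class_fractions) - 1) > 1e-9) {
    stop("class_fractions must sum to 1")
  }
  if (any(cfg$class_fractions < 0)) stop("class_fractions must be non-negative")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (length(cfg$base_mean_log_range) != 2 ||
      diff(cfg$base_mean_log_range) < 0) {
    stop("base_mean_log_range must be an interval c(lo, hi)")
  }
  for (tp in list(cfg$longterm_months, cfg$shortterm_months)) {
    if (length(tp) == 0) stop("timepoint lists must be non-empty")
    if (any(diff(tp) <= 0)) stop("timepoint lists must be strictly increasing")
  }
  if (cfg$n_degron_tfs > cfg$n_tfs) stop("n_degron_tfs must be <= n_tfs")
  invisible(cfg)
}

#' Sample design table for the storage experiment
#'
#' One row per RNA-seq sample. PreTreat is sampled once at month 0; the
#' short-term air treatments follow `shortterm_months` and the long-term
#' treatments (MCP, CA, MCPCA) follow `longterm_months`; every cell has
#' `n_reps` replicates.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `sample`, `treatment`, `timepoint`,
#'   `replicate`.
#' @export
simulate_design <- function(config) {
  validate_sim_config(config)
  cell <- function(treatment, months) {
    expand.grid(treatment = treatment, timepoint = months,
                replicate = seq_len(config$n_reps),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  design <- rbind(
    cell("PreTreat", 0),
    cell(SHORTTERM_TREATMENTS, config$shortterm_months),
    cell(LONGTERM_TREATMENTS, config$longterm_months))
  design <- design[order(match(design$treatment, TREATMENTS),
                         design$timepoint, design$replicate), ]
  design$sample <- sprintf("%s_T%s_R%d", design$treatment,
                           design$timepoint, design$replicate)
  rownames(design) <- NULL
  design[, c("sample", "treatment", "timepoint", "replicate")]
}

# log2 induction multiplier for one gene class across the design
class_log2_multiplier <- function(class, design, config) {
  t <- design$timepoint
  trt <- design$treatment
  lt <- config$longterm_months
  span <- max(lt) - min(lt)
  eff <- config$effect_log2fc
  out <- numeric(nrow(design))
  if (class == "ndegron_transient") {
    sel <- trt %in% HYPOXIC_TREATMENTS
    out[sel] <- eff * (max(lt) - t[sel]) / span
  } else if (class == "ndegron_sustained") {
    out[trt %in% HYPOXIC_TREATMENTS] <- eff
  } else if (class == "ethylene_late") {
    sel <- trt == "CA"
    out[sel] <- eff * (t[sel] - min(lt)) / span
  } else if (class == "maturation") {
    out[trt %in% SHORTTERM_TREATMENTS] <- eff
  }
  out
}

#' Simulate the count matrix with planted ground truth
#'
#' Counts are negative binomial with per-gene baseline means, class-specific
#' treatment/time induction (see [sim_config()]), and a log-linear TF
#' coupling: each TF carries a standardized latent activity (iid standard
#' normal per sample) that enters each planted target's natural-log mean
#' scaled by `edge_strength` and the TF's own log mean at half that coupling
#' (so the measured TF expression is an informative but noisy readout of its
#' activity, and `edge_strength = 0` leaves all genes exchangeable nulls).
#' Response classes are planted on non-TF genes only.
#'
#' @param config A [sim_config()].
#' @return A list of class `"apple_sim"` with elements
#' \describe{
#'   \item{counts}{integer gene x sample matrix.}
#'   \item{metadata}{the design table from [simulate_design()].}
#'   \item{truth}{ground truth: `gene_class` (named character),
#'     `planted_edges` (data frame `tf`, `target`), `motif_genes` (genes whose
#'     upstream sequence will carry an HRPE), `degron_tfs` (TFs whose CDS will
#'     encode MCGGAI/V), `tf_ids`.}
#' }
#' @export
simulate_counts <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  design <- simulate_design(config)
  n_samples <- nrow(design)
  gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
  tf_ids <- gene_ids[seq_len(config$n_tfs)]

  # class assignment: fixed counts per class, shuffled across the non-TF
  # genes. TFs are regulators, not responders: their variation is carried by
  # the latent activity below, and planting response classes on them would
  # confound treatment effects with regulatory noise.
  non_tf <- setdiff(gene_ids, tf_ids)
  n_per_class <- floor(config$class_fractions * config$n_genes)
  n_per_class["null"] <- length(non_tf) -
    sum(n_per_class[names(n_per_class) != "null"])
  if (n_per_class["null"] < 0) {
    stop("class fractions leave no room for the TF genes; reduce n_tfs or ",
         "the non-null fractions")
  }
  gene_class <- stats::setNames(rep("null", config$n_genes), gene_ids)
  gene_class[non_tf] <- sample(rep(names(n_per_class), times = n_per_class))

  base_mean <- exp(stats::runif(config$n_genes,
                                config$base_mean_log_range[1],
                                config$base_mean_log_range[2]))

  log_mu <- matrix(log(base_mean), nrow = config$n_genes, ncol = n_samples)
  dimnames(log_mu) <- list(gene_ids, design$sample)
  for (cl in setdiff(GENE_CLASSES, "null")) {
    sel <- gene_class == cl
    if (any(sel)) {
      add <- log(2) * class_log2_multiplier(cl, design, config)
      log_mu[sel, ] <- log_mu[sel, , drop = FALSE] +
        matrix(add, nrow = sum(sel), ncol = n_samples, byrow = TRUE)
    }
  }

  # TF latent activities drive the TFs themselves and their planted targets.
  # The TF's own expression reflects its latent at half the target coupling;
  # both scale with edge_strength so edge_strength = 0 leaves every gene an
  # exchangeable null. The latent is centered within each treatment x
  # timepoint cell (then rescaled to unit variance), making regulatory
  # co-variation orthogonal to treatment effects: planted edges are
  # recoverable by the network stage without ever masquerading as
  # differential expression.
  latent <- matrix(stats::rnorm(config$n_tfs * n_samples),
                   nrow = config$n_tfs, dimnames = list(tf_ids, design$sample))
  if (config$n_reps > 1) {
    cell <- paste(design$treatment, design$timepoint)
    for (cl in unique(cell)) {
      cols <- which(cell == cl)
      latent[, cols] <- (latent[, cols, drop = FALSE] -
                           rowMeans(latent[, cols, drop = FALSE])) *
        sqrt(config$n_reps / (config$n_reps - 1))
    }
  }
  log_mu[tf_ids, ] <- log_mu[tf_ids, , drop = FALSE] +
    0.5 * config$edge_strength * latent

  null_nontf <- setdiff(gene_ids[gene_class == "null"], tf_ids)
  n_edges <- min(config$n_edges, length(null_nontf))
  planted_edges <- if (n_edges > 0) {
    targets <- sample(null_nontf, n_edges)
    parents <- sample(tf_ids, n_edges, replace = TRUE)
    for (i in seq_len(n_edges)) {
      log_mu[targets[i], ] <- log_mu[targets[i], ] +
        config$edge_strength * latent[parents[i], ]
    }
    data.frame(tf = parents, target = targets, stringsAsFactors = FALSE)
  } else {
    data.frame(tf = character(), target = character(), stringsAsFactors = FALSE)
  }

  mu <- exp(log_mu)
  counts <- if (config$dispersion == 0) {
    stats::rpois(length(mu), lambda = mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }
  counts <- matrix(as.integer(counts), nrow = config$n_genes,
                   dimnames = dimnames(mu))

  truth <- list(
    gene_class = gene_class,
    planted_edges = planted_edges,
    motif_genes = sort(gene_ids[gene_class == "ndegron_sustained"]),
    degron_tfs = tf_ids[seq_len(config$n_degron_tfs)],
    tf_ids = tf_ids)
  structure(list(counts = counts, metadata = design, truth = truth,
                 config = config), class = "apple_sim")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One concrete realization of an IUPAC consensus
realize_iupac <- function(pattern) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(letters, function(l) sample(IUPAC_CODES[[l]], 1), ""),
        collapse = "")
}

motif_free_dna <- function(n, motif, max_tries = 100) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(n)
    if (nrow(scan_motif(s, motif, both_strands = TRUE)) == 0L) return(s)
  }
  stop("failed to draw a motif-free sequence") # ~never at these lengths
}

# Degron-encoding CDS prefix: ATG TGY GGN GGN GCN + Ile/Val codon
degron_prefix <- function() {
  aa6 <- sample(c("I", "V"), 1)
  codon6 <- if (aa6 == "I") paste0("AT", sample(c("A", "C", "T"), 1)) else
    paste0("GT", sample(c("A", "C", "G", "T"), 1))
  paste0("ATG",
         paste0("TG", sample(c("C", "T"), 1)),
         paste0("GG", sample(c("A", "C", "G", "T"), 1)),
         paste0("GG", sample(c("A", "C", "G", "T"), 1)),
         paste0("GC", sample(c("A", "C", "G", "T"), 1)),
         codon6)
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

random_cds_body <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

#' Simulate promoter and coding sequences with planted motifs
#'
#' Generates a 1000-bp (configurable) upstream sequence and a CDS for every
#' gene in the ground truth. Genes in `truth$motif_genes` receive at least one
#' exact HRPE instance (random realization of the V/Y positions) at a random
#' recorded offset; all other upstream sequences are HRPE-free by rejection
#' sampling on both strands. TFs in `truth$degron_tfs` get a CDS starting with
#' an MCGGAI/V-encoding prefix; all other CDS are checked to not start with
#' the degron.
#'
#' @param truth Ground truth list from [simulate_counts()].
#' @param upstream_len Upstream window length (>= motif length).
#' @param cds_codons Number of codons in each simulated CDS body.
#' @param seed Integer seed.
#' @return List with `upstream` and `cds` ([Biostrings::DNAStringSet], named
#'   by gene), and `motif_offsets` (named integer vector of planted 0-based
#'   HRPE offsets).
#' @export
simulate_sequences <- function(truth, upstream_len = 1000, cds_codons = 120,
                               seed = 1) {
  motif <- HRPE_MOTIF
  L <- nchar(motif)
  if (upstream_len < L) {
    stop("upstream_len must be at least the motif length (", L, ")")
  }
  set.seed(seed)
  gene_ids <- names(truth$gene_class)
  upstream <- character(length(gene_ids))
  names(upstream) <- gene_ids
  offsets <- integer(0)
  for (g in gene_ids) {
    s <- motif_free_dna(upstream_len, motif)
    if (g %in% truth$motif_genes) {
      off <- sample.int(upstream_len - L + 1L, 1L) - 1L # 0-based
      substr(s, off + 1L, off + L) <- realize_iupac(motif)
      offsets[g] <- off
    }
    upstream[g] <- s
  }

  cds <- character(length(gene_ids))
  names(cds) <- gene_ids
  for (g in gene_ids) {
    if (g %in% truth$degron_tfs) {
      cds[g] <- paste0(degron_prefix(), random_cds_body(cds_codons), "TAA")
    } else {
      repeat {
        s <- paste0("ATG", random_cds_body(cds_codons), "TAA")
        if (!has_n_degron(translate_cds(s))) break
      }
      cds[g] <- s
    }
  }
  list(upstream = Biostrings::DNAStringSet(upstream),
       cds = Biostrings::DNAStringSet(cds),
       motif_offsets = offsets)
}
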