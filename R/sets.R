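# Contrast-set logic for the hypoxia response.
#
# Three analyses mirror the study design: (1) pooled-by-treatment contrasts
# defining the hypoxia-upregulated set (a gene must be up in CA and/or MCPCA
# against every normoxic treatment); (2) the CA-only and MCPCA-only subsets
# (up against all six other treatments); (3) per-timepoint contrasts within
# the long-term treatments defining the "n-degron" set (up in both CA and
# MCPCA vs MCP: hypoxia response independent of ethylene perception) and the
# "ethylene" set (up in CA vs both MCP and MCPCA: hypoxia response requiring
# ethylene perception).

contrast_name <- function(a, b) paste0(a, "_vs_", b)

samples_for <- function(metadata, treatment, timepoint = NULL) {
  sel <- metadata$treatment == treatment
  if (!is.null(timepoint)) sel <- sel & metadata$timepoint == timepoint
  metadata$sample[sel]
}

#' Pooled treatment contrast tables
#'
#' Runs [nb_wald_contrast()] for each requested pair of treatments, pooling
#' all timepoints within a treatment.
#'
#' @param norm_counts Normalized gene x sample matrix.
#' @param metadata Sample metadata (`sample`, `treatment`, `timepoint`).
#' @param pairs List of `c(groupA, groupB)` treatment pairs; default is every
#'   hypoxic treatment (CA, MCPCA) against every other treatment, which is
#'   what [hypoxia_sets()] needs.
#' @param pseudocount Passed to [nb_wald_contrast()].
#' @return Named list of contrast tables, keyed `"A_vs_B"`.
#' @export
treatment_contrast_tables <- function(norm_counts, metadata,
                                      pairs = hypoxia_contrast_pairs(),
                                      pseudocount = 0.5) {
  out <- lapply(pairs, function(pr) {
    nb_wald_contrast(norm_counts,
                     samples_for(metadata, pr[1]),
                     samples_for(metadata, pr[2]),
                     pseudocount = pseudocount)
  })
  names(out) <- vapply(pairs, function(pr) contrast_name(pr[1], pr[2]), "")
  out
}

#' Treatment pairs needed for the hypoxia set logic
#'
#' The ten hypoxic-vs-normoxic pairs plus the two orientations of the
#' CA/MCPCA pair (needed for the exclusive subsets).
#' @return List of `c(groupA, groupB)` character pairs.
#' @export
hypoxia_contrast_pairs <- function() {
  pairs <- list()
  for (h in HYPOXIC_TREATMENTS) {
    for (n in NORMOXIC_TREATMENTS) pairs[[length(pairs) + 1]] <- c(h, n)
  }
  pairs[[length(pairs) + 1]] <- c("CA", "MCPCA")
  pairs[[length(pairs) + 1]] <- c("MCPCA", "CA")
  pairs
}

require_tables <- function(tables, needed) {
  missing <- setdiff(needed, names(tables))
  if (length(missing) > 0) {
    stop("missing contrast table(s): ", paste(missing, collapse = ", "))
  }
}

#' Hypoxia-upregulated gene set and its exclusive subsets
#'
#' `hypoxia_all` contains every gene up-regulated (per [call_upregulated()])
#' in at least one hypoxic treatment H (CA or MCPCA) against *every* normoxic
#' treatment (PreTreat, A1, A10, A20, MCP) — the "exists H, for all N"
#' reading of the set definition. With `rule = "any_pair"` a single
#' significant hypoxic-vs-normoxic pair suffices instead. `ca_only` and
#' `mcpca_only` contain the genes up in the focal hypoxic treatment against
#' all six other treatments; they are disjoint by construction (the CA/MCPCA
#' pair cannot exceed +1 log2FC in both directions).
#'
#' @param tables Named contrast tables covering [hypoxia_contrast_pairs()].
#' @param lfc_min,alpha Thresholds for [call_upregulated()].
#' @param rule `"exists_all"` (default) or `"any_pair"` for `hypoxia_all`.
#' @return List with sorted gene-id vectors `hypoxia_all`, `ca_only`,
#'   `mcpca_only`.
#' @export
hypoxia_sets <- function(tables, lfc_min = 1, alpha = 0.05,
                         rule = c("exists_all", "any_pair")) {
  rule <- match.arg(rule)
  needed <- vapply(hypoxia_contrast_pairs(), function(pr)
    contrast_name(pr[1], pr[2]), "")
  require_tables(tables, needed)
  up <- lapply(tables, call_upregulated, lfc_min = lfc_min, alpha = alpha)

  per_hypoxic <- lapply(HYPOXIC_TREATMENTS, function(h) {
    sets <- lapply(NORMOXIC_TREATMENTS, function(n) up[[contrast_name(h, n)]])
    if (rule == "exists_all") Reduce(intersect, sets) else Reduce(union, sets)
  })
  hypoxia_all <- sort(Reduce(union, per_hypoxic))

  list(hypoxia_all = hypoxia_all,
       ca_only = exclusive_subset(tables, "CA", lfc_min, alpha),
       mcpca_only = exclusive_subset(tables, "MCPCA", lfc_min, alpha))
}

#' Exclusive hypoxia subset for one hypoxic treatment
#'
#' Genes up-regulated in the focal hypoxic treatment compared to all six
#' other treatments.
#'
#' @param tables Named contrast tables (focal vs each other treatment).
#' @param focal `"CA"` or `"MCPCA"`.
#' @inheritParams hypoxia_sets
#' @return Sorted character vector of gene ids.
#' @export
exclusive_subset <- function(tables, focal, lfc_min = 1, alpha = 0.05) {
  if (!focal %in% HYPOXIC_TREATMENTS) {
    stop("focal treatment must be hypoxic (CA or MCPCA), got '", focal, "'")
  }
  others <- setdiff(TREATMENTS, focal)
  needed <- contrast_name(focal, others)
  require_tables(tables, needed)
  sets <- lapply(needed, function(nm)
    call_upregulated(tables[[nm]], lfc_min = lfc_min, alpha = alpha))
  sort(Reduce(intersect, sets))
}

#' Per-timepoint contrast tables among the long-term treatments
#'
#' At one storage timepoint, contrasts CA vs MCP, MCPCA vs MCP and CA vs
#' MCPCA with samples matched on timepoint.
#'
#' @inheritParams treatment_contrast_tables
#' @param timepoint A long-term storage month present in all of MCP, CA and
#'   MCPCA.
#' @return Named list of three contrast tables.
#' @export
timepoint_contrast_tables <- function(norm_counts, metadata, timepoint,
                                      pseudocount = 0.5) {
  for (trt in LONGTERM_TREATMENTS) {
    if (length(samples_for(metadata, trt, timepoint)) == 0) {
      stop("timepoint ", timepoint, " is not a long-term timepoint ",
           "(no ", trt, " samples)")
    }
  }
  pairs <- list(c("CA", "MCP"), c("MCPCA", "MCP"), c("CA", "MCPCA"))
  out <- lapply(pairs, function(pr) {
    nb_wald_contrast(norm_counts,
                     samples_for(metadata, pr[1], timepoint),
                     samples_for(metadata, pr[2], timepoint),
                     pseudocount = pseudocount)
  })
  names(out) <- vapply(pairs, function(pr) contrast_name(pr[1], pr[2]), "")
  out
}

#' "n-degron" gene set at one timepoint
#'
#' Genes up-regulated in both CA vs MCP and MCPCA vs MCP at the given
#' timepoint: a hypoxia response expressed whether or not ethylene can be
#' perceived, hence attributed to the oxygen-sensing N-degron pathway.
#'
#' @param tables Timepoint tables from [timepoint_contrast_tables()].
#' @inheritParams hypoxia_sets
#' @return Sorted character vector of gene ids.
#' @export
n_degron_set <- function(tables, lfc_min = 1, alpha = 0.05) {
  require_tables(tables, c("CA_vs_MCP", "MCPCA_vs_MCP"))
  sort(intersect(
    call_upregulated(tables[["CA_vs_MCP"]], lfc_min, alpha),
    call_upregulated(tables[["MCPCA_vs_MCP"]], lfc_min, alpha)))
}

#' "ethylene" gene set at one timepoint
#'
#' Genes up-regulated in CA vs MCP and in CA vs MCPCA at the given timepoint:
#' a hypoxia response present only when ethylene perception is intact.
#'
#' @inheritParams n_degron_set
#' @return Sorted character vector of gene ids.
#' @export
ethylene_set <- function(tables, lfc_min = 1, alpha = 0.05) {
  require_tables(tables, c("CA_vs_MCP", "CA_vs_MCPCA"))
  sort(intersect(
    call_upregulated(tables[["CA_vs_MCP"]], lfc_min, alpha),
    call_upregulated(tables[["CA_vs_MCPCA"]], lfc_min, alpha)))
}

#' Time-resolved "n-degron" and "ethylene" sets
#'
#' Runs the per-timepoint contrasts at every long-term storage month and
#' collects both set families plus a set-size table (the machine-readable
#' twin of the set-size-versus-time curves).
#'
#' @inheritParams treatment_contrast_tables
#' @param timepoints Months to analyse; default: all timepoints shared by
#'   MCP, CA and MCPCA in the metadata.
#' @inheritParams hypoxia_sets
#' @return List with `n_degron` and `ethylene` (named lists of gene-id
#'   vectors keyed by timepoint) and `sizes` (data frame `timepoint`,
#'   `n_degron`, `ethylene`).
#' @export
time_resolved_sets <- function(norm_counts, metadata, timepoints = NULL,
                               lfc_min = 1, alpha = 0.05, pseudocount = 0.5) {
  if (is.null(timepoints)) {
    tps <- lapply(LONGTERM_TREATMENTS, function(trt)
      unique(metadata$timepoint[metadata$treatment == trt]))
    timepoints <- sort(Reduce(intersect, tps))
  }
  if (length(timepoints) == 0) stop("no shared long-term timepoints")
  nd <- list(); et <- list()
  for (t in timepoints) {
    tables <- timepoint_contrast_tables(norm_counts, metadata, t,
                                        pseudocount = pseudocount)
    key <- as.character(t)
    nd[[key]] <- n_degron_set(tables, lfc_min, alpha)
    et[[key]] <- ethylene_set(tables, lfc_min, alpha)
  }
  list(n_degron = nd, ethylene = et,
       sizes = data.frame(timepoint = timepoints,
                          n_degron = lengths(nd),
                          ethylene = lengths(et),
                          row.names = NULL))
}
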