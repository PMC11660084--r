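# GENIE3-style transcription-factor network inference.
#
# For every target gene, a random-forest regression of its expression on the
# candidate TFs (the target excluded from its own predictor set) yields
# impurity-reduction importances as directed edge weights, and the
# out-of-bag r-squared records how predictable the target is from TFs alone.
# Forest settings follow the reference protocol: 1000 trees and
# mtry = sqrt(number of TFs). Downstream, edges are thresholded to the top 5
# TFs per target, the hypoxia subgraph keeps TFs regulating at least 10
# hypoxia genes, and TFs are classified by which response compartment
# dominates their target pool.

#' Filter genes for network inference
#'
#' Keeps genes with at least `min_samples` samples at a normalized expression
#' of at least `min_value` (both bounds inclusive).
#'
#' @param norm_counts Normalized gene x sample matrix.
#' @param min_samples Minimum number of qualifying samples (default 10).
#' @param min_value Minimum expression value (default 3).
#' @return The filtered matrix.
#' @export
filter_network_genes <- function(norm_counts, min_samples = 10, min_value = 3) {
  norm_counts[rowSums(norm_counts >= min_value) >= min_samples, , drop = FALSE]
}

#' Filter TFs by detectable expression
#'
#' Keeps TFs with at least `min_samples` samples whose raw count strictly
#' exceeds `min_count`. TF ids absent from the count matrix are skipped with
#' a warning.
#'
#' @param raw_counts Raw gene x sample count matrix.
#' @param tf_list Candidate TF gene ids.
#' @param min_samples Minimum qualifying samples (default 3).
#' @param min_count Count threshold, strict (default 10).
#' @return Character vector of expressed TF ids (input order preserved).
#' @export
filter_expressed_tfs <- function(raw_counts, tf_list, min_samples = 3,
                                 min_count = 10) {
  unknown <- setdiff(tf_list, rownames(raw_counts))
  if (length(unknown) > 0) {
    warning("skipping TF id(s) not in count matrix: ",
            paste(unknown, collapse = ", "))
    tf_list <- setdiff(tf_list, unknown)
  }
  if (length(tf_list) == 0) return(character())
  keep <- rowSums(raw_counts[tf_list, , drop = FALSE] > min_count) >= min_samples
  tf_list[keep]
}

# Deterministic per-target seed from the global seed and the target id, so
# inference does not depend on the order targets are visited in.
target_seed <- function(seed, id) {
  h <- 0
  for (v in utf8ToInt(id)) h <- (h * 31 + v) %% 2147483629
  as.integer((seed + h) %% 2147483629 + 1)
}

#' Infer a TF -> target regulatory network
#'
#' Fits one random-forest regression per target gene and records each TF's
#' importance as a directed edge weight. When the target is itself a TF it is
#' excluded from its own predictor set. TF predictors are put in lexicographic
#' order and each target gets a seed derived from `(seed, target id)`, so the
#' result is independent of input row order. A constant target yields zero
#' importances and an r-squared of 0.
#'
#' @param expr Filtered expression matrix (genes x samples); rows must cover
#'   all TFs and targets.
#' @param tfs Candidate TF gene ids (at least 2).
#' @param targets Target gene ids (default: all rows of `expr`).
#' @param n_trees Trees per forest (default 1000).
#' @param mtry `"sqrt"` (default: `floor(sqrt(#predictors))`) or an integer.
#' @param importance `"impurity"` (default) or `"permutation"` (negative
#'   permutation importances are clamped at zero).
#' @param seed Global seed.
#' @return Object of class `"grn"`: list with `edges` (data frame `tf`,
#'   `target`, `importance`, ranked per target by decreasing importance with
#'   ties broken by TF id) and `r2` (named numeric, out-of-bag r-squared per
#'   target).
#' @export
infer_network <- function(expr, tfs, targets = NULL, n_trees = 1000,
                          mtry = "sqrt", importance = c("impurity", "permutation"),
                          seed = 1) {
  importance <- match.arg(importance)
  tfs <- sort(unique(tfs))
  if (length(tfs) < 2) stop("need at least 2 candidate TFs")
  missing <- setdiff(tfs, rownames(expr))
  if (length(missing) > 0) {
    stop("TF(s) absent from expression matrix: ", paste(missing, collapse = ", "))
  }
  if (is.null(targets)) targets <- rownames(expr)
  X <- t(expr[tfs, , drop = FALSE])

  edge_list <- vector("list", length(targets))
  r2 <- stats::setNames(numeric(length(targets)), targets)
  for (i in seq_along(targets)) {
    g <- targets[i]
    predictors <- setdiff(tfs, g)
    y <- expr[g, ]
    if (stats::var(y) == 0) {
      imp <- stats::setNames(rep(0, length(predictors)), predictors)
      r2[g] <- 0
    } else {
      m <- if (identical(mtry, "sqrt")) {
        max(1L, floor(sqrt(length(predictors))))
      } else as.integer(mtry)
      fit <- ranger::ranger(
        x = X[, predictors, drop = FALSE], y = y,
        num.trees = n_trees, mtry = m, importance = importance,
        seed = target_seed(seed, g), num.threads = 1)
      imp <- pmax(fit$variable.importance, 0)
      r2[g] <- fit$r.squared
    }
    ord <- order(-imp, names(imp))
    edge_list[[i]] <- data.frame(tf = names(imp)[ord], target = g,
                                 importance = unname(imp[ord]),
                                 stringsAsFactors = FALSE)
  }
  structure(list(edges = do.call(rbind, edge_list), r2 = r2), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("GENIE3-style regulatory network\n")
  cat("  edges:  ", nrow(x$edges), "\n")
  cat("  TFs:    ", length(unique(x$edges$tf)), "\n")
  cat("  targets:", length(unique(x$edges$target)), "\n")
  invisible(x)
}

#' Keep the top-k incoming edges per target
#'
#' Retains, for each target, the `k` highest-importance TF edges. Ties at the
#' cutoff are broken deterministically: higher importance first, then
#' lexicographically smaller TF id.
#'
#' @param network A `"grn"` object.
#' @param k Edges to keep per target (default 5, >= 1).
#' @return Thresholded `"grn"` object.
#' @export
threshold_top_k <- function(network, k = 5) {
  if (k < 1) stop("k must be >= 1")
  e <- network$edges
  ord <- order(e$target, -e$importance, e$tf)
  e <- e[ord, , drop = FALSE]
  rank_in_target <- stats::ave(seq_len(nrow(e)), e$target, FUN = seq_along)
  e <- e[rank_in_target <= k, , drop = FALSE]
  rownames(e) <- NULL
  structure(list(edges = e, r2 = network$r2), class = "grn")
}

#' Extract the hypoxia subgraph
#'
#' Restricts targets to the hypoxia gene set, then drops TFs regulating fewer
#' than `min_degree` of the remaining targets. An empty hypoxia set yields an
#' empty subgraph. The operation is idempotent.
#'
#' @param network A (typically thresholded) `"grn"` object.
#' @param hypoxia_genes Character vector of hypoxia gene ids.
#' @param min_degree Minimum number of hypoxia targets per TF (default 10).
#' @return Subgraph as a `"grn"` object.
#' @export
extract_hypoxia_subgraph <- function(network, hypoxia_genes, min_degree = 10) {
  e <- network$edges[network$edges$target %in% hypoxia_genes, , drop = FALSE]
  deg <- table(e$tf)
  keep_tfs <- names(deg)[deg >= min_degree]
  e <- e[e$tf %in% keep_tfs, , drop = FALSE]
  rownames(e) <- NULL
  structure(list(edges = e, r2 = network$r2[names(network$r2) %in% e$target]),
            class = "grn")
}

#' Per-TF target counts in the two hypoxia compartments
#'
#' For each TF in the network: `x` counts its targets among the "standard
#' hypoxia" genes (hypoxia set minus the ethylene-mediated subsets) and `y`
#' its targets among the ethylene-mediated subsets (CA-only union
#' MCPCA-only).
#'
#' @param network A `"grn"` object.
#' @param hypoxia_all Full hypoxia-upregulated gene set.
#' @param ethylene_subsets Union of the CA-only and MCPCA-only subsets.
#' @return Data frame `tf`, `x`, `y`.
#' @export
tf_target_counts <- function(network, hypoxia_all, ethylene_subsets) {
  standard <- setdiff(hypoxia_all, ethylene_subsets)
  tf_targets <- split(network$edges$target, network$edges$tf)
  data.frame(
    tf = names(tf_targets),
    x = vapply(tf_targets, function(tg) length(intersect(tg, standard)), 0L),
    y = vapply(tf_targets, function(tg) length(intersect(tg, ethylene_subsets)), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify a TF as standard or ethylene-mediated
#'
#' A TF whose point (x, y) lies strictly above the line `y = slope * x` is
#' classified `"ethylene_mediated"`; on or below the line it is
#' `"standard"`. The slope normalizes for the different compartment sizes;
#' the reference analysis used `24/143`, the ratio of the maximal per-TF
#' target counts in the two compartments.
#'
#' @param x,y Non-negative integer target counts (vectorized).
#' @param slope Positive slope of the dividing line.
#' @return Character vector of labels.
#' @export
classify_tf <- function(x, y, slope) {
  if (!is.finite(slope) || slope <= 0) stop("slope must be positive")
  ifelse(y > slope * x, "ethylene_mediated", "standard")
}

#' Classify all TFs in a target-count table
#'
#' The default slope is `max(y) / max(x)` over the table's TFs. In the
#' degenerate case `max(x) = 0`, any TF with `y > 0` is ethylene-mediated.
#'
#' @param counts Data frame from [tf_target_counts()].
#' @param slope Dividing-line slope; default `max(y) / max(x)`.
#' @return The input with a `label` column appended.
#' @export
classify_tfs <- function(counts, slope = NULL) {
  stopifnot(all(c("tf", "x", "y") %in% names(counts)))
  if (nrow(counts) == 0) return(cbind(counts, label = character()))
  if (is.null(slope)) {
    if (max(counts$x) == 0) {
      counts$label <- ifelse(counts$y > 0, "ethylene_mediated", "standard")
      return(counts)
    }
    slope <- max(counts$y) / max(counts$x)
    if (slope == 0) slope <- .Machine$double.xmin # all y zero: nothing above
  }
  counts$label <- classify_tf(counts$x, counts$y, slope)
  counts
}

#' Focal-TF subnetwork and target-overlap analysis
#'
#' Restricts the network to a set of focal TFs (e.g. the ERF VII family) and
#' tabulates the pairwise and all-focal overlaps of their target pools, with
#' targets flagged when they belong to an annotation set (e.g. the hypoxia
#' gene set).
#'
#' @param network A (thresholded) `"grn"` object.
#' @param focal_tf_ids TF ids to keep; all must be TFs of the network.
#' @param annotate_set Gene ids to flag among targets.
#' @return List with `edges`, `overlap` (data frame `tf1`, `tf2`, `overlap`),
#'   `intersection_all` (targets shared by every focal TF), and `targets`
#'   (data frame `target`, `n_regulators`, `annotated`).
#' @export
focal_tf_subnetwork <- function(network, focal_tf_ids,
                                annotate_set = character()) {
  net_tfs <- unique(network$edges$tf)
  unknown <- setdiff(focal_tf_ids, net_tfs)
  if (length(unknown) > 0) {
    stop("focal id(s) not TFs in the network: ", paste(unknown, collapse = ", "))
  }
  e <- network$edges[network$edges$tf %in% focal_tf_ids, , drop = FALSE]
  rownames(e) <- NULL
  pools <- lapply(stats::setNames(focal_tf_ids, focal_tf_ids),
                  function(tf) unique(e$target[e$tf == tf]))
  overlap <- if (length(focal_tf_ids) >= 2) {
    prs <- utils::combn(focal_tf_ids, 2)
    data.frame(tf1 = prs[1, ], tf2 = prs[2, ],
               overlap = apply(prs, 2, function(pr)
                 length(intersect(pools[[pr[1]]], pools[[pr[2]]]))),
               stringsAsFactors = FALSE)
  } else {
    data.frame(tf1 = character(), tf2 = character(), overlap = integer())
  }
  targets <- sort(unique(e$target))
  list(edges = e, overlap = overlap,
       intersection_all = sort(Reduce(intersect, pools)),
       targets = data.frame(
         target = targets,
         n_regulators = vapply(targets, function(tg) sum(e$target == tg), 0L),
         annotated = targets %in% annotate_set,
         row.names = NULL, stringsAsFactors = FALSE))
}
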