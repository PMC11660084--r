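# Hypergeometric over-representation test for gene sets against a
# user-supplied term -> gene map, with Benjamini-Hochberg correction across
# the tested terms.

#' Gene-set over-representation test
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least the realized overlap between the selected set and the term's genes,
#' drawing `|selected|` genes from the universe. Term genes outside the
#' universe are ignored; selected genes outside the universe are an error.
#'
#' @param selected Character vector of selected gene ids (subset of
#'   `universe`).
#' @param term_map Named list mapping term id -> character vector of gene
#'   ids, or a two-column data frame (`term`, `gene`).
#' @param universe Character vector: the gene universe (e.g. all expressed
#'   genes after filtering).
#' @return Data frame sorted by p: `term`, `term_size`, `overlap`, `p`,
#'   `padj` (BH across the tested terms).
#' @examples
#' enrich(c("g1", "g2"), list(T1 = c("g1", "g2", "g3")), paste0("g", 1:10))
#' @export
enrich <- function(selected, term_map, universe) {
  selected <- unique(selected)
  universe <- unique(universe)
  offenders <- setdiff(selected, universe)
  if (length(offenders) > 0) {
    stop("selected genes outside the universe: ",
         paste(offenders, collapse = ", "))
  }
  if (is.data.frame(term_map)) {
    stopifnot(ncol(term_map) >= 2)
    term_map <- split(as.character(term_map[[2]]), as.character(term_map[[1]]))
  }
  N <- length(universe)
  n <- length(selected)
  res <- lapply(names(term_map), function(term) {
    genes <- intersect(unique(term_map[[term]]), universe)
    K <- length(genes)
    k <- length(intersect(selected, genes))
    data.frame(term = term, term_size = K, overlap = k,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
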