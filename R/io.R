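# Plain-text readers/writers for the pipeline's interchange formats:
# counts and metadata as TSV, gene sets as TSV, ground truth as JSON,
# sequences as 60-column wrapped FASTA.

#' Write a count (or normalized expression) matrix as TSV
#'
#' Genes as rows; first column `gene_id`, remaining columns the sample ids.
#' @param counts Gene x sample matrix with dimnames.
#' @param path Output file.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a count matrix written by [write_counts_tsv()]
#' @param path TSV file.
#' @return Numeric matrix with gene ids as rownames.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write sample metadata as TSV
#' @param metadata Data frame (`sample`, `treatment`, `timepoint`,
#'   `replicate`).
#' @param path Output file.
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read sample metadata written by [write_metadata_tsv()]
#' @param path TSV file.
#' @export
read_metadata_tsv <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write named gene sets as a two-column TSV (gene_id, set)
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @export
write_gene_sets_tsv <- function(sets, path) {
  df <- do.call(rbind, lapply(names(sets), function(nm) {
    if (length(sets[[nm]]) == 0) return(NULL)
    data.frame(gene_id = sort(sets[[nm]]), set = nm, stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- data.frame(gene_id = character(), set = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write sequences as wrapped FASTA
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60)
}

#' Read a DNA FASTA file
#' @param path FASTA file.
#' @return [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  Biostrings::readDNAStringSet(path)
}

#' Write ground truth as JSON
#' @param truth Ground truth list from [simulate_counts()].
#' @param path Output file.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    gene_class = as.list(truth$gene_class),
    planted_edges = truth$planted_edges,
    motif_genes = truth$motif_genes,
    degron_tfs = truth$degron_tfs,
    tf_ids = truth$tf_ids), path, auto_unbox = TRUE, pretty = TRUE)
}

#' Read ground truth written by [write_ground_truth_json()]
#' @param path JSON file.
#' @export
read_ground_truth_json <- function(path) {
  if (!file.exists(path)) stop("ground truth file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$gene_class <- unlist(x$gene_class)
  x
}

#' Write a network edge list as TSV (tf, target, importance)
#' @param network A `"grn"` object.
#' @param path Output file.
#' @export
write_edges_tsv <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
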