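# IUPAC consensus motif scanning and N-degron detection.
#
# The HRPE (hypoxia-responsive promoter element) consensus GCCVCYGGTTTY and the
# N-terminal MCGGAI/V degron signature are both short, fully specified IUPAC
# consensus strings, so presence/absence is decided by exact degenerate-letter
# matching rather than PWM scoring.

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Hypoxia-responsive promoter element consensus
#'
#' The IUPAC consensus of the HRPE cis-element bound by ERF VII transcription
#' factors (V = A/C/G, Y = C/T).
#' @export
HRPE_MOTIF <- "GCCVCYGGTTTY"

#' Expand an IUPAC nucleotide code
#'
#' @param code Single IUPAC nucleotide letter.
#' @return Character vector of the unambiguous bases the code stands for,
#'   e.g. `"V"` expands to `c("A", "C", "G")`.
#' @examples
#' expand_iupac("Y")
#' @export
expand_iupac <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L) {
    stop("'code' must be a single IUPAC letter")
  }
  code <- toupper(code)
  if (is.null(IUPAC_CODES[[code]])) {
    stop("invalid IUPAC code: '", code, "'")
  }
  IUPAC_CODES[[code]]
}

validate_iupac_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) == 0L) {
    stop("motif pattern must be a non-empty string")
  }
  pattern <- toupper(pattern)
  letters <- strsplit(pattern, "")[[1]]
  bad <- setdiff(letters, names(IUPAC_CODES))
  if (length(bad) > 0L) {
    stop("invalid IUPAC code(s) in pattern: ", paste(unique(bad), collapse = ", "))
  }
  pattern
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

empty_hits <- function() {
  data.frame(seq_id = character(), offset = integer(), strand = character(),
             matched = character(), stringsAsFactors = FALSE)
}

# Match positions (0-based offsets) of an IUPAC pattern on one strand of a
# plain ACGT(N) string. A subject N only matches a pattern N.
scan_one_strand <- function(seq_chars, pattern_letters) {
  L <- length(pattern_letters)
  n <- length(seq_chars)
  if (n < L) return(integer())
  idx <- seq_len(n - L + 1L)
  ok <- rep(TRUE, length(idx))
  for (j in seq_len(L)) {
    allowed <- IUPAC_CODES[[pattern_letters[j]]]
    if (pattern_letters[j] == "N") allowed <- c(allowed, "N")
    ok <- ok & (seq_chars[idx + j - 1L] %in% allowed)
  }
  idx[ok] - 1L
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Reports every position where the motif matches exactly under IUPAC
#' degeneracy. Soft-masked (lowercase) bases are uppercased first; an `N` in
#' the input sequence never satisfies a non-`N` pattern position. With
#' `both_strands = TRUE` the reverse complement is also scanned and hits are
#' reported in forward coordinates with strand `"-"`; overlapping hits are all
#' reported.
#'
#' @param sequence A single DNA sequence (character string or
#'   [Biostrings::DNAString]).
#' @param motif IUPAC consensus pattern, e.g. [HRPE_MOTIF].
#' @param both_strands Scan the reverse complement as well (default `TRUE`).
#' @param seq_id Identifier recorded in the `seq_id` column.
#' @return A data frame with one row per hit: `seq_id`, `offset` (0-based
#'   start on the forward strand), `strand` (`"+"`/`"-"`), and `matched` (the
#'   matched word as read 5'->3' on the hit strand).
#' @examples
#' scan_motif("GCCACTGGTTTC", HRPE_MOTIF)
#' @export
scan_motif <- function(sequence, motif, both_strands = TRUE, seq_id = NA_character_) {
  if (methods::is(sequence, "DNAString")) sequence <- as.character(sequence)
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("'sequence' must be a single string")
  }
  pattern <- validate_iupac_pattern(motif)
  sequence <- toupper(sequence)
  L <- nchar(pattern)
  n <- nchar(sequence)
  if (n < L) return(empty_hits())

  pat <- strsplit(pattern, "")[[1]]
  chars <- strsplit(sequence, "")[[1]]

  fwd <- scan_one_strand(chars, pat)
  hits <- if (length(fwd) > 0L) {
    data.frame(seq_id = seq_id, offset = fwd, strand = "+",
               matched = substring(sequence, fwd + 1L, fwd + L),
               stringsAsFactors = FALSE)
  } else empty_hits()

  if (both_strands) {
    rc <- revcomp(sequence)
    rc_chars <- strsplit(rc, "")[[1]]
    rev_off <- scan_one_strand(rc_chars, pat)
    if (length(rev_off) > 0L) {
      # offset on the forward strand of the L-mer whose revcomp matched
      fwd_off <- n - (rev_off + L)
      hits <- rbind(hits, data.frame(
        seq_id = seq_id, offset = fwd_off, strand = "-",
        matched = substring(rc, rev_off + 1L, rev_off + L),
        stringsAsFactors = FALSE))
    }
  }
  hits[order(hits$offset, hits$strand), , drop = FALSE]
}

#' Scan a set of sequences for a motif
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param motif IUPAC consensus pattern.
#' @param both_strands Scan both strands (default `TRUE`).
#' @return Data frame of hits across all sequences (see [scan_motif()]).
#' @export
scan_sequences <- function(seqs, motif, both_strands = TRUE) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) stop("'seqs' must be named")
  out <- lapply(names(seqs), function(id) {
    scan_motif(seqs[[id]], motif, both_strands = both_strands, seq_id = id)
  })
  do.call(rbind, c(out, list(empty_hits())))
}

#' Per-sequence motif presence summary
#'
#' @inheritParams scan_sequences
#' @return Data frame with `seq_id`, `n_hits` and logical `present`, one row
#'   per input sequence.
#' @export
motif_presence <- function(seqs, motif, both_strands = TRUE) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  hits <- scan_sequences(seqs, motif, both_strands = both_strands)
  n_hits <- table(factor(hits$seq_id, levels = names(seqs)))
  data.frame(seq_id = names(seqs), n_hits = as.integer(n_hits),
             present = as.integer(n_hits) > 0L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Translate a coding sequence
#'
#' Codon-by-codon translation under the standard genetic code. Translation
#' stops at the first stop codon (the stop is not included) and a trailing
#' partial codon is ignored. Codons containing `N` translate to `X`.
#'
#' @param cds Coding sequence (character string or [Biostrings::DNAString]),
#'   length >= 3, alphabet ACGTN.
#' @return The protein sequence as a character string.
#' @examples
#' translate_cds("ATGTGCGGAGGAGCTATT")
#' @export
translate_cds <- function(cds) {
  if (methods::is(cds, "DNAString")) cds <- as.character(cds)
  if (!is.character(cds) || length(cds) != 1L) stop("'cds' must be a single string")
  cds <- toupper(cds)
  if (nchar(cds) < 3L) stop("coding sequence must be at least one codon (3 nt)")
  if (grepl("[^ACGTN]", cds)) stop("coding sequence contains non-ACGTN characters")
  n_codons <- nchar(cds) %/% 3L
  starts <- (seq_len(n_codons) - 1L) * 3L + 1L
  codons <- substring(cds, starts, starts + 2L)
  aas <- ifelse(grepl("N", codons), "X",
                unname(Biostrings::GENETIC_CODE[codons]))
  stop_at <- which(aas == "*")
  if (length(stop_at) > 0L) aas <- aas[seq_len(stop_at[1] - 1L)]
  paste(aas, collapse = "")
}

#' Test for the N-terminal MCGGAI/V degron
#'
#' The oxygen-dependent degron signature of ERF VII proteins: the first six
#' residues must be exactly `MCGGAI` or `MCGGAV`. Proteins shorter than six
#' residues return `FALSE`.
#'
#' @param protein Protein sequence (character string).
#' @return Logical scalar.
#' @export
has_n_degron <- function(protein) {
  if (!is.character(protein) || length(protein) != 1L || nchar(protein) == 0L) {
    stop("'protein' must be a non-empty string")
  }
  nchar(protein) >= 6L && substr(protein, 1L, 6L) %in% c("MCGGAI", "MCGGAV")
}

#' Extract fixed-length upstream promoter windows
#'
#' Returns the `n` bases immediately 5' of each gene's translational start,
#' strand-aware: for minus-strand genes the window 3'-adjacent in genome
#' coordinates is taken and reverse-complemented. Windows running off a contig
#' edge are truncated with a warning. Coordinates are 1-based inclusive, as in
#' GFF3.
#'
#' @param genome Named [Biostrings::DNAStringSet] of contigs.
#' @param annotation Data frame with columns `gene_id`, `seqnames`, `start`,
#'   `end`, `strand`, or a [GenomicRanges::GRanges] with a `gene_id` metadata
#'   column.
#' @param n Window length in bp (default 1000).
#' @return [Biostrings::DNAStringSet] named by `gene_id`.
#' @export
extract_upstream <- function(genome, annotation, n = 1000) {
  if (!methods::is(genome, "DNAStringSet")) stop("'genome' must be a DNAStringSet")
  if (methods::is(annotation, "GRanges")) {
    annotation <- data.frame(
      gene_id = GenomicRanges::mcols(annotation)$gene_id,
      seqnames = as.character(GenomicRanges::seqnames(annotation)),
      start = GenomicRanges::start(annotation),
      end = GenomicRanges::end(annotation),
      strand = as.character(GenomicRanges::strand(annotation)),
      stringsAsFactors = FALSE)
  }
  req <- c("gene_id", "seqnames", "start", "end", "strand")
  if (!all(req %in% names(annotation))) {
    stop("annotation must provide columns: ", paste(req, collapse = ", "))
  }
  out <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    contig <- annotation$seqnames[i]
    if (!contig %in% names(genome)) {
      stop("gene ", annotation$gene_id[i], ": contig '", contig,
           "' absent from genome")
    }
    clen <- length(genome[[contig]])
    if (annotation$strand[i] == "-") {
      from <- annotation$end[i] + 1L
      to <- annotation$end[i] + n
      if (to > clen) {
        warning("gene ", annotation$gene_id[i],
                ": upstream window truncated at contig end")
        to <- clen
      }
      seq <- if (from > to) Biostrings::DNAString("") else
        Biostrings::reverseComplement(
          Biostrings::subseq(genome[[contig]], from, to))
    } else {
      from <- annotation$start[i] - n
      to <- annotation$start[i] - 1L
      if (from < 1L) {
        warning("gene ", annotation$gene_id[i],
                ": upstream window truncated at contig start")
        from <- 1L
      }
      seq <- if (from > to) Biostrings::DNAString("") else
        Biostrings::subseq(genome[[contig]], from, to)
    }
    out[[i]] <- as.character(seq)
  }
  res <- Biostrings::DNAStringSet(unlist(out))
  names(res) <- annotation$gene_id
  res
}
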