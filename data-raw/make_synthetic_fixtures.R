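# Builds the synthetic stand-in sequence fixtures under inst/extdata/.
#
# The real upstream/CDS sequences of the apple PCO and ERF VII genes are not
# redistributed here; these synthetic stand-ins carry the published
# presence/absence pattern on random backbones:
#   - the five B-type PCO genes (hypoxia-inducible) each carry >= 1 exact
#     HRPE (GCCVCYGGTTTY) in their 1000-bp upstream window; the five A-type
#     PCO genes (constitutive) carry none;
#   - the HRE2-like ERF VII gene MD11G1306500 carries an HRPE; the other four
#     ERF VII upstream windows are HRPE-free;
#   - all five ERF VII coding sequences start with an MCGGAI/V-encoding
#     N-degron; none of the PCO coding sequences do.
#
# Run from the package root: Rscript data-raw/make_synthetic_fixtures.R

devtools::load_all(".", quiet = TRUE)

A_TYPE_PCO <- c("MD06G1208200", "MD14G1218600", "MD09G1236500",
                "MD15G1373300", "MD17G1266100")
B_TYPE_PCO <- c("MD14G1006600", "MD12G1009100", "MD09G1048100",
                "MD12G1009200", "MD17G1048300")
ERF_VII <- c("MD09G1174400", "MD17G1152400", "MD13G1163300",
             "MD16G1162900", "MD11G1306500")

genes <- c(A_TYPE_PCO, B_TYPE_PCO, ERF_VII)
truth <- list(
  gene_class = stats::setNames(rep("null", length(genes)), genes),
  motif_genes = c(B_TYPE_PCO, "MD11G1306500"),
  degron_tfs = ERF_VII)

seqs <- simulate_sequences(truth, upstream_len = 1000, cds_codons = 110,
                           seed = 20240101)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_fasta(seqs$upstream, "inst/extdata/synthetic_pco_erfvii_upstream1000.fasta")
write_fasta(seqs$cds, "inst/extdata/synthetic_pco_erfvii_cds.fasta")

pres <- motif_presence(seqs$upstream, HRPE_MOTIF)
stopifnot(identical(sort(pres$seq_id[pres$present]), sort(truth$motif_genes)))
deg <- vapply(as.character(seqs$cds),
              function(s) has_n_degron(translate_cds(s)), logical(1))
stopifnot(identical(sort(names(seqs$cds)[deg]), sort(ERF_VII)))
cat("fixtures written and verified\n")
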