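# applehypoxia

Analysis of the long-term hypoxia transcriptome response of apple fruit in
postharvest storage.

Commercial apples are stored for months under controlled atmosphere (CA,
~2% O₂ at 1 °C), a deliberately hypoxic regime, often combined with the
ethylene-perception inhibitor 1-MCP. The low-oxygen response runs through the
N-degron pathway — ERF VII transcription factors carrying the N-terminal
MCGGAI/V degron are degraded when plant cysteine oxidases (PCOs) can oxidize
their exposed cysteine, and stabilized under hypoxia, where they activate
promoters carrying the hypoxia-responsive promoter element (HRPE,
`GCCVCYGGTTTY`) — and through ethylene signaling, which 1-MCP blocks. A
seven-treatment time-course design (PreTreat; air at 1/10/20 °C; MCP; CA;
MCPCA = 1-MCP + CA) lets contrast logic split the hypoxia response into an
ethylene-independent ("n-degron") and an ethylene-dependent ("ethylene")
component.

The package provides, as tested, reusable functions:

* **Normalization and DE** — median-of-ratios size factors
  (`estimate_size_factors()`), a simplified negative-binomial Wald contrast
  with pooled method-of-moments dispersion and Bonferroni control
  (`nb_wald_contrast()`), strict up-regulation calls at log2FC > 1 and
  padj < .05 (`call_upregulated()`).
* **Contrast-set logic** — the hypoxia-upregulated set (a gene must beat
  *every* normoxic treatment in CA or MCPCA), its CA-only / MCPCA-only
  subsets, and the per-month "n-degron" (up in CA *and* MCPCA vs MCP) and
  "ethylene" (up in CA vs MCP *and* vs MCPCA) sets
  (`hypoxia_sets()`, `time_resolved_sets()`).
* **Network inference** — GENIE3-style random-forest regulation
  (`infer_network()`: 1000 trees, mtry = √#TFs, impurity importances,
  out-of-bag r²), expression filters, top-5 edge thresholding, the
  degree-≥10 hypoxia subgraph, the TF-role classifier around the normalized
  line y = (max y / max x)·x, and focal-TF subnetworks with target overlaps.
* **Motif annotation** — exact IUPAC consensus scanning on both strands
  (`scan_motif()`), CDS translation and MCGGAI/V N-degron detection
  (`translate_cds()`, `has_n_degron()`), strand-aware upstream-window
  extraction (`extract_upstream()`).
* **Enrichment** — hypergeometric over-representation with BH correction
  (`enrich()`).
* **Synthetic data** — `simulate_counts()` / `simulate_sequences()` generate
  the full seven-treatment design with planted response classes, planted
  TF→target edges and planted motifs, so the whole pipeline is validated
  against known ground truth (`sim_config()` documents the study
  conditions).

## Worked example

The `analysis/` directory is the narrative workflow; each script reads the
previous stage's output under `results/`:

```sh
Rscript analysis/01_simulate.R                 # counts, metadata, truth, FASTA
Rscript analysis/02_differential_expression.R  # size factors, contrasts, hypoxia sets
Rscript analysis/03_time_course_sets.R         # n-degron / ethylene sets per month
Rscript analysis/04_network.R                  # GENIE3-style network + TF roles
Rscript analysis/05_motifs.R                   # HRPE scan + degron census
Rscript analysis/06_enrichment.R               # sets vs planted classes
```

Stage 2 prints, for the default simulation (2,000 genes, 102 samples):

```
hypoxia-upregulated set: 172 genes (CA-only 55, MCPCA-only 0)
  ndegron_sustained  100 planted, 100 recovered in hypoxia set
  ndegron_transient  100 planted,  17 recovered in hypoxia set
  ethylene_late      100 planted,  55 recovered in hypoxia set
```

Every sustained-response gene is recovered; transient genes are mostly
missed by the *pooled* contrasts because their induction averages out over
the storage window — which is exactly why the study design adds per-month
contrasts. Stage 3 prints the two response waves:

```
 timepoint n_degron ethylene
         2      198        0
         4      145        0
         5      115        2
         6      103       18
         7      100       59
         8      100       95
         9       98       99
sustained-class sensitivity in n-degron sets: 0.98-1.00
ethylene-class genes leaking into n-degron sets: 0
```

The n-degron count starts high and declines (the transient class fades)
while the ethylene count rises from zero to ~100 — the two opposite curves
the design is built to separate. Stage 4 reports

```
planted-edge recovery after top-5 thresholding: 100% (60/60)
hypoxia subgraph: 25 TFs regulating >= 10 of 172 hypoxia genes
```

and stage 5 the motif censuses on the simulated sequences (100/2000 genes
with an HRPE, 5/2000 CDS with the degron — exactly the planted truth) and on
the bundled synthetic PCO/ERF VII panel: the five B-type PCO upstream
sequences carry an HRPE, the five A-type carry none, and exactly the five
ERF VII coding sequences start with MCGGAI/V.

`run_pipeline(pipeline_config(), "out_dir")` runs the same stages as one
deterministic call (byte-identical bundles for identical configurations).

## Data notes

`inst/extdata/synthetic_pco_erfvii_*.fasta` are synthetic stand-ins for the
apple PCO / ERF VII sequence panel: published GDDH13 gene identifiers on
random sequence backbones carrying the published motif presence/absence
pattern (see `data-raw/make_synthetic_fixtures.R`). They exist to validate
the scanning logic. The methods vignette (`vignettes/methods.Rmd`) documents
the statistical model, the generator's design and its limitations.
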