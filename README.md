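# riboprof

Tissue-specific ribosome profiling analysis and read simulation in R.

Measuring translation in a specific tissue of an intact animal means
combining three sequencing readouts of the same cells: **transcriptional
profiling** (total RNA-seq), **translational profiling** (TRAP —
sequencing full-length mRNAs co-purified with epitope-tagged ribosomes),
and **ribosome profiling** (sequencing the ~30–45 nt mRNA footprints that
ribosomes protect from RNase T1 digestion). riboprof is for researchers
who have such libraries aligned to transcript coordinates — or who want to
prototype the analysis before having any data — and need the standard
downstream battery: filtered counting, RPKM, translation-efficiency
estimation and classification, metagene occupancy, and the differential
tests used to call transcriptional and translational regulation between
genotypes.

At its core:

* **Translation efficiency** per gene,
  `TE = RPKM_ribo / RPKM_transcription`, classified high (TE > 2),
  medium, or low (TE < 0.5), with a percent-sensitivity conversion
  `(2^|mean log2 ratio| − 1) × 100` for method comparisons.
* A **weighted t-type test** for differential expression between
  replicate library groups on the proportion scale: replicate variance is
  binomial sampling variance plus a shared between-replicate component
  estimated by method of moments, the group proportion is the
  variance-minimizing weighted mean, and the statistic is referred to a t
  distribution with Welch–Satterthwaite degrees of freedom.
* A **two-criteria translational-regulation caller**: ≥ 2-fold TE
  increase (Student t on log2 replicate TEs, p < 0.05) *and* a
  significant ribosome-profiling increase (weighted t-type test,
  p < 0.05).
* A **global-shift analysis**: per-gene fold-change distribution,
  its mean, and a Kolmogorov–Smirnov test against a variance-matched
  control-replicate-split null.
* A **read simulator** with known truth — negative-binomial replicate
  noise, RNase T1 footprint digestion (cut 3' of G) with 30–45 nt gel
  size selection, ribosome pause sites, and genotype perturbations
  (locus deletion with residual remnants, UTR-swapped transgenes, global
  TE multipliers) — so every stage of the pipeline is testable offline.

## Worked example

```r
library(riboprof)

# simulate a wild-type and a globally shifted genotype, then analyze
cfg <- sim_config(seed = 42, n_genes = 200, library_size = 1e5)
tr  <- generate_transcriptome(cfg)
ann <- data.frame(gene_id = tr$gene_id, utr5_len = tr$utr5_len,
                  cds_len = tr$cds_len, utr3_len = tr$utr3_len)
wt    <- simulate_assays(tr, cfg, genotype = "WT")
shift <- simulate_assays(tr, cfg,
                         genotype = genotype_spec("TorOE_like",
                                                  global_te_multiplier = 1.6))

tab   <- count_reads(wt, ann)
expr  <- compute_rpkm(tab)
genes <- filter_joint(tab)        # detected in both assays, all replicates
te    <- te_table(expr, genes)
table(te$category)
#>   high    low medium
#>     68     36     96

head(te[order(te$te_ribo), c("gene_id", "te_ribo", "category")], 3)
#>     gene_id    te_ribo category
#> 6     g0006 0.04797995      low
#> 108   g0108 0.07105233      low
#> 10    g0010 0.07577372      low

replicate_correlation(expr, "footprint", 1, 2, genes = genes)
#> [1] 0.9757927

tab_shift <- count_reads(shift, ann)
global_shift_counts(tab_shift, tab)
#> Global shift over 200 genes: mean FC 1.593 (null 1.020), KS D = 0.865, p = 0
```

Reading the output: of 200 simulated genes, 36 fall in the low-TE class
(the simulator plants a translationally suppressed, ribosomal-protein-like
group near TE 0.09, and the three lowest estimates above sit right on
it); footprint replicates agree at r² ≈ 0.98; and the 1.6× global TE
multiplier is recovered as a mean per-gene fold change of 1.59 against a
null split centered at 1.02, with an overwhelming KS separation.

The same pipeline runs from files:
`run_pipeline(pipeline_config(seed = 1, out_dir = "run"))` simulates,
quantifies, writes every table as TSV, and records a manifest that
suffices to reproduce the run; point `fragments_path`/`annotation_path`
at your own BED-like fragment TSV and annotation to analyze real data.

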