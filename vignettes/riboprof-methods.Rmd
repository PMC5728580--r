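---
title: "riboprof: models, statistics, and the read simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboprof: models, statistics, and the read simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboprof)
```

riboprof analyzes three kinds of sequencing libraries from the same tissue,
all expressed in transcript coordinates: **transcriptional profiling**
(total RNA-seq), **translational profiling** (TRAP — sequencing of
full-length mRNAs co-purified with tagged ribosomes), and **ribosome
profiling** (sequencing of ~30–45 nt mRNA footprints protected from
nuclease digestion by bound ribosomes). The package quantifies all three,
estimates per-gene translation efficiency, and provides the differential
statistics used to call transcriptional and translational regulation
between genotypes. A read simulator with known truth backs every stage, so
the whole pipeline is testable without any external dataset.

# Quantification

Fragments are assigned to genes by transcript id; multi-mapping and
isoform deconvolution are out of scope (inputs are already in transcript
coordinates). For each assay and replicate, `count_reads()` records
per-gene unique-exon counts and the total mapped fragments.

**Detection filter.** A gene is "reliably detected" when it has at least
`min_reads = 10` counts in *every* replicate of an assay
(`filter_expressed()`). Replicate variability rises sharply below roughly
10 reads, so weaker genes are excluded rather than modeled. The threshold
sits at ≥ 10 (not > 10): the boundary case is ambiguous in prose
descriptions of such filters, so the convention here is the inclusive one,
and it is configurable. Joint analyses (TE, regulation calls) further drop
genes detected only transcriptionally (`filter_joint()`), since
transcription without any ribosome-footprint signal usually reflects
contaminating RNA from other cell types rather than a translated message.

**RPKM.** Expression is reads per kilobase of exon per million mapped
reads:

$$\mathrm{RPKM}_{g,r} = \frac{x_{g,r}}{(L_g/10^3)\,(N_r/10^6)}$$

with $x_{g,r}$ the count of gene $g$ in replicate $r$, $L_g$ the exonic
(here: full transcript) length, and $N_r$ that replicate's total mapped
reads. Totals are per replicate, not pooled — replicates are sequenced
separately and carry their own depths. Replicate agreement is summarized
as $r^2$ of the least-squares fit between two replicates' log10 RPKM
(`replicate_correlation()`; the log transform matches how such scatter is
always displayed, and is optional).

**Region analysis.** `region_coverage_fractions()` splits a gene's
per-base coverage mass into 5'UTR/CDS/3'UTR fractions.
`region_partition_expression()` compares a case against a reference
condition region by region: per-base density per region, divided by the
library size of that condition, case over reference. The reference against
itself is exactly 1 in every region; a region with zero reference density
is reported `NA` rather than a division artifact.

# Translation efficiency

$$\mathrm{TE}_g = \frac{\text{ribosome-profiling RPKM}_g}
                       {\text{transcriptional RPKM}_g}$$

The headline TE divides replicate-*mean* RPKM by replicate-mean RPKM
(`te_table()`): the ratio of means is more stable than a mean of ratios at
three replicates. Per-replicate TE ratios are still computed and carried
along (attribute `te_reps`) because the TE Student test needs them.

**Categories.** TE > 2 is *high*, TE < 0.5 is *low*, and everything
between — boundaries included — is *medium* (`classify_te()`). The
boundaries are exclusive for the extreme classes by convention ("between
0.5 and 2" defines medium).

**Method sensitivity.** `sensitivity_comparison()` contrasts
footprint-based TE with TRAP-based TE per gene. Genes are categorized by
the *average* of the two measurements (either alone would bias the
grouping toward its own extremes), then each category's mean
$\log_2(\mathrm{TE}_{\text{ribo}}/\mathrm{TE}_{\text{TRAP}})$ is
converted to a percent sensitivity difference,
$(2^{|m|}-1)\times 100$ (`percent_sensitivity()`); the sign is reported
separately as a direction. A mean log2 ratio of −1.25 in a low-TE group,
for example, converts to a 138% greater sensitivity of ribosome profiling
in detecting low TE.

**Metagene profiles.** `metagene_profile()` aligns genes at the start
codon (offset 0 = first nucleotide of the AUG) or stop codon (offset 0 =
first nucleotide 3' of the stop), normalizes each gene's per-base coverage
in the window by that gene's mean coverage over the window, and averages
across genes — so every gene contributes equally regardless of expression,
and the profile is invariant to rescaling coverage. Genes whose window
does not fit inside the transcript, or with fewer than `min_reads`
overlapping fragments, are excluded. The default window is 50 nt on each
side. No P-site offsetting or codon-periodicity analysis is attempted.

# Differential statistics

## The weighted t-type test

`weighted_t_test()` compares two genotypes on the *proportion* scale:
replicate count over replicate total, $p_i = x_i/n_i$. Each replicate's
variance is modeled as binomial sampling variance plus a shared
between-replicate component:

$$v_i = \frac{\hat p(1-\hat p)}{n_i} + \sigma_b^2 .$$

The group proportion $\hat p$ is the variance-minimizing weighted mean
($w_i = 1/v_i$), $\sigma_b^2$ is estimated by method of moments — the
excess of the observed scatter of the $p_i$ over the average binomial
variance, clamped at zero — and the two updates are iterated to
convergence (tolerance 1e-10, at most 50 iterations; convergence is
typically immediate). The statistic is the difference of group estimates
over the root of summed squared standard errors, referred to a t
distribution.

**Degrees of freedom.** Welch–Satterthwaite, with one refinement: the
binomial component of the variance is a plug-in quantity, not estimated
from replicate scatter, so only the $\sigma_b^2$ component carries its
$k-1$ degrees of freedom. Per group,
$\mathrm{df} = (k-1)\,(\bar v/\sigma_b^2)^2$, infinite when
$\sigma_b^2 = 0$ (the statistic is then a z-score, as it should be when
the variance is known). Treating the whole variance as estimated with
$k-1$ df makes the test noticeably conservative at three replicates;
with the refinement, the null rejection rate at $\alpha = 0.05$ measures
between 0.04 and 0.07 across simulation regimes
(`wtt_calibration_study()`), and the test remains mildly conservative for
genes with very low counts, where the known binomial term dominates.

Degenerate inputs: all-zero counts in both groups return statistic 0,
p = 1; a group whose pooled proportion estimate is exactly 0 or 1 has its
variance proportion floored at $0.5/\sum n_i$ so the test never claims
infinite precision.

The calibration study draws expected counts log-uniformly between 300 and
10,000 per replicate — the depth regime of reliably detected genes in deep
bulk libraries, where the between-replicate component the test exists to
model actually matters.

## TE test and the two-criteria regulation caller

`te_student_test()` is a two-sided pooled-variance Student t on
per-replicate TE values, log2-transformed by default (TE is a ratio; the
log scale stabilizes its variance and makes increases and decreases
symmetric). A raw-scale option exists. Constant inputs with equal means
return p = 1 directly.

`call_translational_regulation()` flags a gene as translationally
up-regulated only when **both** criteria hold: (1) TE increases at least
2-fold with Student-test p < 0.05, and (2) the ribosome-profiling signal
itself increases significantly (weighted t-type test p < 0.05, in the
increasing direction). The second criterion removes apparent TE changes
that are really transcriptional changes with a lagging footprint signal.

`call_differential()` applies the conventional threshold rule — fold
change above `fold_min` (default 3; 1.5 and 2 are common alternatives)
and p < 0.05 — symmetrically for up and down. Raw p-values are the
default, matching the rule's usual statement; Benjamini–Hochberg
adjustment (`bh_adjust()`, a validated wrapper over the standard step-up
procedure) is available behind the `adjust` flag.

`ddct_fold_change()` is the qPCR companion utility,
$2^{-\Delta\Delta C_t}$.

## Global translational shifts

`global_shift()` takes per-gene expression for case, control, and a null
contrast; it reports the arithmetic mean of per-gene fold changes (the
geometric mean is also returned, labeled), a binned log2 fold-change
histogram (0.25-wide bins), and a two-sample Kolmogorov–Smirnov test of
the case-vs-control log2 fold-change distribution against the null's.

Two design points deserve emphasis:

* **Compositional identifiability.** Under per-sample total-count
  normalization, a perfectly uniform translational shift cancels: every
  count scales, so does the total, and RPKM is unchanged. The simulator
  therefore calibrates expected fragment yield against the *unperturbed*
  transcriptome (the normalization constants are stored when the
  transcriptome is generated and deliberately not updated by
  `apply_genotype()`), which models library preparation normalized to
  input material; and `global_shift_counts()` compares depth-matched raw
  counts rather than per-sample RPKM. With real data, detecting a uniform
  shift requires the same property — spike-in normalization or a
  dominant unshifted background — and this limitation is inherent to the
  analysis, not to this implementation.
* **Variance-matched null.** The null contrast must have the same
  distribution as the case contrast when nothing is shifted. Comparing
  3-replicate means against a 2-vs-1 replicate split fails this — the KS
  test would detect the difference in spread alone. `global_shift_counts()`
  therefore forms every fold change as a ratio of two single replicates:
  case replicate *i* over control replicate *i* for the case (with *i*
  rotating deterministically across genes), and two distinct control
  replicates for the null. Under the null both are ratios of independent
  single replicates, so the marginals match exactly. A consequence worth
  knowing: the mean per-gene fold change of a null contrast sits slightly
  above 1 (a ratio of noisy positives has expectation $1 + \mathrm{CV}^2$
  approximately); the case and null means are reported side by side for
  that reason.

# The read simulator

`generate_transcriptome()` draws, per gene: segment lengths (log-normal;
5'UTR ≈ 150 nt, CDS ≈ 1200 nt in whole codons, 3'UTR ≈ 300 nt by
default), a nucleotide sequence with uniform base composition (so G — the
RNase T1 cut site — occurs at about one position in four), an abundance
(log-normal over ~2 decades), a true TE, and a ribosome pause profile
over the 5'UTR+CDS (unit baseline with a few exponentially sized pause
sites, normalized to mean 1).

**TE mixture.** TE is log-normal (median 1, sdlog 0.75) with a
low-TE spike component (12% of genes, centered near TE 0.09) mimicking
the coherently translationally suppressed ribosomal-protein class; the
mixture spans both category extremes. When
`transcription_te_anticorrelation` is set (the default), TE is coupled to
abundance through a noisy reversed rank, reproducing the inverse trend
between transcriptional output and translation efficiency. Because TE is
dimensionless and an RPKM-ratio estimator measures density *relative to
the library average*, drawn TEs are rescaled so the abundance-weighted
mean TE is exactly 1; without this calibration, truth and estimate sit on
different scales and category recovery is meaningless. Degenerate
zero-variance mixtures are left untouched.

**Counts.** Per replicate and gene, fragment counts are Poisson-Gamma
(negative binomial): expected count proportional to abundance (total RNA)
or abundance × TE (TRAP, footprints), scaled to the configured library
size, with a Gamma factor of squared CV `dispersion` (default 0.01, i.e.
10% between-replicate variation — typical of good biological replicates).
Expected counts are *not* length-dependent; this keeps the
count-to-truth mapping transparent, and length normalization cancels in
every TE ratio regardless.

**Footprints.** A ribosome position is drawn over the 5'UTR+CDS weighted
by the pause profile (footprints occupy the 5'UTR and CDS and are absent
from the 3'UTR — scanning/initiation is not modeled separately). A 30 nt
protected core centered on that position is extended outward on each side
to the nearest cut boundary: RNase T1 cuts 3' of G residues, and
transcript (or remnant-source) ends also terminate fragments. Whether
real footprint 5' ends also require a G cut is not observable in the
data this models; the simulator applies the cut rule at both ends, and
the core/window parameters are configurable. The fragment is kept only if
its final length falls within the 30–45 nt size-selection window —
discarded, not redrawn, so per-gene footprint yield is sequence-dependent
exactly as gel selection makes it. A consequence of the centered core:
footprints can reach at most `max − core/2` nt (15 nt at defaults, plus
the rare G-extension up to 29) past the stop codon, and under default
settings less than 1% of footprint base-mass falls in 3'UTRs.

**Full-length assays.** Total-RNA and TRAP fragments are 75 nt (the
read length of a typical 75-cycle single-end run), positioned uniformly
over the transcript.

**Genotypes.** `genotype_spec()` describes perturbations: *deletions*
zero the parent gene's transcription (the full-length transcript is gone)
and mask the interval against any read; *residual fragments* add
remnant emission sources restricted to an interval of the parent's
coordinates with their own transcription and TE multipliers (an internal
promoter driving the undeleted 3' portion of a locus, for example);
*transgene variants* add new transcript entries sharing the parent CDS
with freshly drawn UTR sequences of chosen lengths; a *global TE
multiplier* scales every gene; and a *boosted gene set* receives an extra
TE factor (default 2), a TOP-mRNA-like response. Deterministic seeds are
derived per assay from the configuration seed, so identical configuration
and seed give byte-identical fragment sets.

**What the simulator does not model** — and what passing tests therefore
do not demonstrate about real data: sequencing errors and quality,
alignment and multi-mapping, splicing and isoforms, codon-level
periodicity or P-site geometry, rRNA contamination, batch effects,
length-dependent count bias, or TRAP's compressed dynamic range — the
simulator gives TRAP the same true TE as footprints, so the two methods'
sensitivity difference is near zero by construction and the
sensitivity-comparison machinery is exercised on structure, not on an
emulated assay bias. The simulator's role is to verify that each
analysis stage recovers the statistical structure it assumes, at known
truth; it is not a generative model of a sequencer.

# Validation studies and sizes

The exported `*_study()` functions run the pipeline end to end under
known truth, at sizes chosen to give stable estimates on a single CPU in
seconds to a couple of minutes each:

* `te_recovery_study()`: 300 genes, 3 replicates, 2×10^5 fragments per
  library. Spearman correlation of estimated vs true TE is expected
  above 0.9 (measured ≈ 0.99), and category accuracy above 90% for genes
  whose true TE is outside narrow gray zones around the cutoffs
  ([0.4, 0.6] and [1.8, 2.2]) — finite depth cannot classify a gene
  arbitrarily close to a boundary.
* `wtt_calibration_study()`: 2000 null genes, beta-binomial replicate
  noise with squared CV 0.01, 3 vs 3. Fraction of p < 0.05 expected in
  [0.03, 0.07].
* `global_shift_study()`: 2000 genes, a 1.6× global TE multiplier;
  recovered mean fold change within 10% of 1.6 and KS p < 0.001, while a
  deletion-only genotype stays null (KS p > 0.01).
* `footprint_geometry_study()`: 100 genes at 10^5 fragments; 100% size
  window compliance, < 1% 3'UTR base mass, stop-codon metagene density
  beyond +15 nt below 5% of upstream density.
* `deletion_partition_study()`: a fully deleted locus reads exactly 0 in
  every region in both assays; the reference against itself reads
  exactly 1.
* `null_regulation_study()`: ten runs of two identically parameterized
  genotypes; a calibrated pipeline makes zero translational-regulation
  calls in at least nine.

# Numerical conventions

Coordinates are 0-based, half-open, transcript-relative everywhere.
Files are TSV with headers (FASTA for sequences); fold changes are
case/control; TE ranking ties break lexicographically by gene id so
extreme-gene lists are stable; RPKM equality checks tolerate 1e-9
relative error; the weighted test iterates to 1e-10. Every random stage
takes an explicit seed, and the pipeline manifest (seed, configuration
echo, package version, per-stage counts) suffices to reproduce a run.

# Known limitations

Single-isoform genes only; no shrinkage or GLM-based differential
framework (by design — the point is the weighted t-type test and the
threshold rules); the global-shift analysis assumes depth-matched
libraries and inherits the compositional caveat above; and the TE Student
test at three replicates has little power below ~2-fold changes, which is
precisely why the regulation caller pairs it with a fold-change floor.
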