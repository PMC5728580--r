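# Self-contained simulation studies that exercise the pipeline end to end
# under known truth. They back the package's validation suite and the
# reproduction script, and are exported so users can rerun them at other
# sizes or seeds.

#' Translation-efficiency recovery study
#'
#' Simulates total-RNA and footprint libraries for one transcriptome,
#' quantifies them, and compares the estimated per-gene TE against the
#' simulation truth.
#'
#' @param seed Master seed.
#' @param n_genes,library_size,n_replicates Study size (defaults 300 genes,
#'   2e5 fragments, 3 replicates).
#' @param gray_zones Two intervals of true TE excluded from the category
#'   accuracy measure (genes arbitrarily close to a cutoff cannot be
#'   classified reliably at finite depth): default `[0.4, 0.6]` and
#'   `[1.8, 2.2]` around the 0.5 and 2 cutoffs.
#' @return List: `spearman` (rank correlation of estimated vs true TE),
#'   `category_accuracy` (fraction of clear-zone genes whose estimated
#'   category matches the category of their true TE), `n_genes` evaluated.
#' @export
te_recovery_study <- function(seed = 1L, n_genes = 300L, library_size = 2e5,
                              n_replicates = 3L,
                              gray_zones = list(c(0.4, 0.6), c(1.8, 2.2))) {
  cfg <- sim_config(seed = seed, n_genes = n_genes,
                    library_size = library_size, n_replicates = n_replicates)
  tr <- generate_transcriptome(cfg)
  fr <- rbind(simulate_reads(tr, cfg, "total_rna"),
              simulate_reads(tr, cfg, "footprint"))
  ann <- data.frame(gene_id = tr$gene_id, utr5_len = tr$utr5_len,
                    cds_len = tr$cds_len, utr3_len = tr$utr3_len,
                    stringsAsFactors = FALSE)
  tab <- count_reads(fr, ann)
  te <- te_table(compute_rpkm(tab), filter_joint(tab), trap_assay = NULL)
  truth <- stats::setNames(tr$true_te, tr$gene_id)[te$gene_id]
  clear <- !vapply(truth, function(v) {
    any(vapply(gray_zones, function(z) v >= z[1] & v <= z[2], logical(1)))
  }, logical(1))
  acc <- mean(classify_te(te$te_ribo[clear]) == classify_te(truth[clear]))
  list(spearman = stats::cor(te$te_ribo, truth, method = "spearman"),
       category_accuracy = acc, n_genes = nrow(te))
}

#' Null calibration study of the weighted t-type test
#'
#' Simulates genes with equal beta-binomial proportions in two groups
#' (replicate proportions drawn from a Beta with squared coefficient of
#' variation `dispersion`) and reports the fraction of tests significant at
#' `alpha` — nominally `alpha` for a calibrated test.
#'
#' Expected per-replicate counts are drawn log-uniformly over
#' `count_range`, the depth regime of reliably detected genes where the
#' between-replicate variance component matters.
#'
#' @param seed Master seed.
#' @param n_genes Null genes to simulate (default 2000).
#' @param dispersion Squared between-replicate CV of the proportion
#'   (default 0.01).
#' @param n_replicates Replicates per group (default 3).
#' @param library_size Total mapped reads per replicate (default 1e6, with
#'   10 percent uniform jitter).
#' @param count_range Expected count range per gene (default 300 to 10000).
#' @param alpha Significance level measured (default 0.05).
#' @return List: `fraction_significant`, `n_genes`.
#' @export
wtt_calibration_study <- function(seed = 1L, n_genes = 2000L,
                                  dispersion = 0.01, n_replicates = 3L,
                                  library_size = 1e6,
                                  count_range = c(300, 10000),
                                  alpha = 0.05) {
  set.seed(seed)
  k <- n_replicates
  pvals <- vapply(seq_len(n_genes), function(g) {
    p0 <- exp(stats::runif(1, log(count_range[1]), log(count_range[2]))) /
      library_size
    tot <- round(stats::runif(2 * k, 0.9 * library_size, 1.1 * library_size))
    ab <- (1 - p0) / (dispersion * p0) - 1
    p_i <- stats::rbeta(2 * k, p0 * ab, (1 - p0) * ab)
    x <- stats::rbinom(2 * k, tot, p_i)
    weighted_t_test(x[seq_len(k)], tot[seq_len(k)],
                    x[k + seq_len(k)], tot[k + seq_len(k)])[["p_value"]]
  }, numeric(1))
  list(fraction_significant = mean(pvals < alpha), n_genes = n_genes)
}

#' Global translational shift study
#'
#' Simulates a control genotype and a case genotype carrying a global TE
#' multiplier (or, with `multiplier = 1` and a supplied `genotype`, any
#' other perturbation), quantifies footprint libraries at equal nominal
#' depth, and runs [global_shift_counts()].
#'
#' @param seed Master seed.
#' @param multiplier Global TE multiplier of the case genotype (default
#'   1.6).
#' @param n_genes,library_size Study size (defaults 2000 genes, 2e5).
#' @param genotype Optional [genotype_spec()] overriding the default
#'   global-shift case.
#' @return The [global_shift()] result.
#' @export
global_shift_study <- function(seed = 1L, multiplier = 1.6, n_genes = 2000L,
                               library_size = 2e5, genotype = NULL) {
  cfg <- sim_config(seed = seed, n_genes = n_genes,
                    library_size = library_size)
  tr <- generate_transcriptome(cfg)
  ann <- data.frame(gene_id = tr$gene_id, utr5_len = tr$utr5_len,
                    cds_len = tr$cds_len, utr3_len = tr$utr3_len,
                    stringsAsFactors = FALSE)
  if (is.null(genotype)) {
    genotype <- genotype_spec("shift", global_te_multiplier = multiplier)
  }
  tab_ctrl <- count_reads(simulate_reads(tr, cfg, "footprint", "WT"), ann)
  tab_case <- count_reads(simulate_reads(tr, cfg, "footprint", genotype), ann)
  global_shift_counts(tab_case, tab_ctrl, "footprint")
}

#' Footprint geometry and 3'UTR exclusion study
#'
#' Simulates footprint libraries and measures: compliance with the size
#' selection window, the fraction of footprint base-mass falling in 3'UTRs,
#' and the stop-codon metagene ratio of mean density beyond
#' `downstream_from` nt after the stop codon to mean upstream density.
#'
#' @param seed Master seed.
#' @param n_genes,library_size Study size (defaults 100 genes, 1e5).
#' @param downstream_from Offset beyond which downstream density is averaged
#'   (default 15 nt after the stop codon).
#' @return List: `length_compliance` (fraction of fragments within the
#'   window), `utr3_fraction` (base-mass fraction in 3'UTRs),
#'   `metagene_downstream_ratio`, `n_fragments`.
#' @export
footprint_geometry_study <- function(seed = 1L, n_genes = 100L,
                                     library_size = 1e5,
                                     downstream_from = 15L) {
  cfg <- sim_config(seed = seed, n_genes = n_genes,
                    library_size = library_size)
  tr <- generate_transcriptome(cfg)
  ann <- data.frame(gene_id = tr$gene_id, utr5_len = tr$utr5_len,
                    cds_len = tr$cds_len, utr3_len = tr$utr3_len,
                    stringsAsFactors = FALSE)
  fp <- simulate_reads(tr, cfg, "footprint")
  len <- fp$end - fp$start
  compliance <- mean(len >= cfg$footprint_len_range[1] &
                       len <= cfg$footprint_len_range[2])
  l5c <- stats::setNames(tr$utr5_len + tr$cds_len, tr$gene_id)
  utr3_mass <- sum(pmax(fp$end - l5c[fp$transcript_id], 0))
  mg <- metagene_profile(fp, ann, "stop_codon",
                         window = c(50L, downstream_from + 15L))
  dn <- mean(mg$density[mg$offsets > downstream_from])
  up <- mean(mg$density[mg$offsets < 0])
  list(length_compliance = compliance,
       utr3_fraction = utr3_mass / sum(len),
       metagene_downstream_ratio = dn / up,
       n_fragments = nrow(fp))
}

#' Deletion region-partition study
#'
#' Simulates a genotype fully deleting one gene and verifies the
#' region-partitioned expression of the deleted locus: zero in the deleted
#' gene for both total RNA and footprints, and unity for the reference
#' against itself.
#'
#' @param seed Master seed.
#' @param n_genes,library_size Study size (defaults 30 genes, 5e4).
#' @return List: `deleted_total_rna`, `deleted_footprint` (mean region value
#'   over the deleted gene's regions), `self_reference` (mean absolute
#'   deviation from 1 of reference-vs-itself values).
#' @export
deletion_partition_study <- function(seed = 1L, n_genes = 30L,
                                     library_size = 5e4) {
  cfg <- sim_config(seed = seed, n_genes = n_genes,
                    library_size = library_size)
  tr <- generate_transcriptome(cfg)
  g <- tr$gene_id[1]
  u5 <- tr$utr5_len[1]; cds <- tr$cds_len[1]; u3 <- tr$utr3_len[1]
  L <- u5 + cds + u3
  del <- genotype_spec("del", deletions = data.frame(gene_id = g, start = 0L,
                                                     end = L))
  regions <- data.frame(label = c("utr5", "cds", "utr3"),
                        start = c(0L, u5, u5 + cds), end = c(u5, u5 + cds, L))
  out <- list()
  for (assay in c("total_rna", "footprint")) {
    wt <- simulate_reads(tr, cfg, assay, "WT")
    mut <- simulate_reads(tr, cfg, assay, del)
    use <- if (assay == "footprint") regions[regions$label != "utr3", ] else
      regions
    vals <- region_partition_expression(
      mut[mut$transcript_id == g, ], wt[wt$transcript_id == g, ], use,
      c(case = nrow(mut), reference = nrow(wt)))$value
    self <- region_partition_expression(
      wt[wt$transcript_id == g, ], wt[wt$transcript_id == g, ], use,
      c(case = nrow(wt), reference = nrow(wt)))$value
    out[[paste0("deleted_", assay)]] <- mean(vals)
    out[[paste0("self_", assay)]] <- mean(abs(self - 1))
  }
  out
}

#' Null end-to-end regulation study
#'
#' Simulates two genotypes from identical parameters (different seeds) and
#' counts genes called translationally regulated at default thresholds; a
#' calibrated pipeline calls none in the vast majority of runs.
#'
#' @param seed Master seed.
#' @param n_runs Number of independent runs (default 10).
#' @param n_genes,library_size Per-run study size (defaults 150 genes, 5e4).
#' @return List: `runs_with_zero_calls`, `n_runs`, `calls_per_run`.
#' @export
null_regulation_study <- function(seed = 1L, n_runs = 10L, n_genes = 150L,
                                  library_size = 5e4) {
  calls <- integer(n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- sim_config(seed = seed + 7919L * r, n_genes = n_genes,
                      library_size = library_size)
    tr <- generate_transcriptome(cfg)
    ann <- data.frame(gene_id = tr$gene_id, utr5_len = tr$utr5_len,
                      cds_len = tr$cds_len, utr3_len = tr$utr3_len,
                      stringsAsFactors = FALSE)
    sim_gt <- function(label, offset) {
      rbind(simulate_reads(tr, cfg, "total_rna", label,
                           seed = cfg$seed + offset),
            simulate_reads(tr, cfg, "footprint", label,
                           seed = cfg$seed + offset + 1L))
    }
    tab_a <- count_reads(sim_gt("A", 11L), ann)
    tab_b <- count_reads(sim_gt("B", 211L), ann)
    rc <- regulation_calls(compute_rpkm(tab_a), compute_rpkm(tab_b),
                           tab_a, tab_b)
    calls[r] <- sum(rc$translational_regulation)
  }
  list(runs_with_zero_calls = sum(calls == 0L), n_runs = n_runs,
       calls_per_run = calls)
}
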