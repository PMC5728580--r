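test_that("transcriptome generation is seeded, structured, and valid", {
  cfg <- small_config(seed = 1, n_genes = 100)
  tr1 <- generate_transcriptome(cfg)
  tr2 <- generate_transcriptome(cfg)
  expect_identical(tr1, tr2)
  expect_equal(nrow(tr1), 100)
  expect_true(all(nchar(tr1$sequence) ==
                    tr1$utr5_len + tr1$cds_len + tr1$utr3_len))
  expect_true(all(tr1$cds_len >= 3 & tr1$cds_len %% 3 == 0))
  expect_true(all(grepl("^[ACGU]+$", tr1$sequence)))
  pp_means <- vapply(tr1$pause_profile, mean, numeric(1))
  expect_true(all(abs(pp_means - 1) < 1e-9))
  expect_true(all(vapply(tr1$pause_profile, function(p) all(p > 0),
                         logical(1))))
  # the TE mixture spans both category extremes
  expect_gt(sum(tr1$true_te > 2), 0)
  expect_gt(sum(tr1$true_te < 0.5), 0)
  expect_equal(nrow(generate_transcriptome(small_config(n_genes = 0))), 0)
})

test_that("degenerate TE mixture and anticorrelation flag behave", {
  cfg1 <- small_config(n_genes = 60,
                       te_mixture = list(meanlog = 0, sdlog = 0,
                                         spike_prob = 0, spike_meanlog = 0,
                                         spike_sdlog = 0),
                       transcription_te_anticorrelation = FALSE)
  tr <- generate_transcriptome(cfg1)
  expect_true(all(tr$true_te == 1))
  cfg2 <- small_config(seed = 5, n_genes = 200,
                       transcription_te_anticorrelation = TRUE)
  tr2 <- generate_transcriptome(cfg2)
  expect_lt(cor(tr2$true_transcription, tr2$true_te, method = "spearman"), 0)
  expect_error(sim_config(footprint_len_range = c(45, 30)), "footprint_len_range")
})

test_that("footprints obey the size window and the RNase T1 cut rule", {
  cfg <- small_config(seed = 3, n_genes = 30, library_size = 1e4)
  tr <- generate_transcriptome(cfg)
  fp <- simulate_reads(tr, cfg, "footprint")
  len <- fp$end - fp$start
  expect_true(all(len >= 30 & len <= 45))
  seqs <- setNames(tr$sequence, tr$gene_id)
  tlen <- setNames(tr$utr5_len + tr$cds_len + tr$utr3_len, tr$gene_id)
  final_base <- substr(seqs[fp$transcript_id], fp$end, fp$end)
  expect_true(all(final_base == "G" | fp$end == tlen[fp$transcript_id]))
  # 5' end likewise abuts a cut site or the transcript start
  prev_base <- ifelse(fp$start == 0, "G",
                      substr(seqs[fp$transcript_id], fp$start, fp$start))
  expect_true(all(prev_base == "G"))
})

test_that("a G-free transcript yields no footprints within the size window", {
  seq_gfree <- paste(rep("ACU", 100), collapse = "")  # 300 nt, no G
  tr <- manual_transcriptome(seq_gfree, 50, 210, 40)
  cfg <- small_config(n_genes = 1, library_size = 2e3)
  fp <- simulate_reads(tr, cfg, "footprint")
  expect_equal(nrow(fp), 0)
  # but a short G-free transcript within the window survives as an
  # end-to-end fragment
  tr2 <- manual_transcriptome(paste(rep("ACU", 14), collapse = ""), 6, 30, 6)
  fp2 <- simulate_reads(tr2, cfg, "footprint")
  expect_gt(nrow(fp2), 0)
  expect_true(all(fp2$start == 0 & fp2$end == 42))
})

test_that("footprint coverage stays out of the 3'UTR", {
  cfg <- small_config(seed = 9, n_genes = 50, library_size = 5e4)
  tr <- generate_transcriptome(cfg)
  fp <- simulate_reads(tr, cfg, "footprint")
  ann <- annotation_of(tr)
  # base-mass bound: with a centered protected core, a footprint can extend
  # past the CDS end by at most footprint_max - core/2 nt
  l5c <- setNames(tr$utr5_len + tr$cds_len, tr$gene_id)
  over <- fp$end - l5c[fp$transcript_id]
  expect_true(all(over <= cfg$footprint_len_range[2] -
                    cfg$protected_core_len %/% 2))
  mass_utr3 <- sum(pmax(over, 0))
  expect_lt(mass_utr3 / sum(fp$end - fp$start), 0.01)
})

test_that("replicate counts are overdispersed and track transcription * TE", {
  cfg <- small_config(seed = 2, n_genes = 150, library_size = 1e5,
                      dispersion = 0.05)
  tr <- generate_transcriptome(cfg)
  fp <- simulate_reads(tr, cfg, "footprint")
  cnt <- table(factor(fp$transcript_id, levels = tr$gene_id), fp$replicate)
  vm <- apply(cnt, 1, var) / pmax(rowMeans(cnt), 1e-9)
  expect_gt(mean(vm[rowMeans(cnt) > 50], na.rm = TRUE), 1)
  expect_gt(cor(rowMeans(cnt), tr$true_transcription * tr$true_te,
                method = "spearman"), 0.95)
})

test_that("identity genotype leaves the transcriptome unchanged", {
  tr <- generate_transcriptome(small_config(n_genes = 20))
  gt <- genotype_spec("null_gt", global_te_multiplier = 1)
  tr2 <- apply_genotype(tr, gt)
  expect_equal(tr2$true_te, tr$true_te)
  expect_equal(tr2$true_transcription, tr$true_transcription)
  expect_equal(tr2$gene_id, tr$gene_id)
})

test_that("full deletion silences a gene in every assay", {
  cfg <- small_config(seed = 4, n_genes = 10, library_size = 1e4)
  tr <- generate_transcriptome(cfg)
  L <- tr$utr5_len[1] + tr$cds_len[1] + tr$utr3_len[1]
  gt <- genotype_spec("del", deletions = data.frame(
    gene_id = tr$gene_id[1], start = 0L, end = L))
  for (assay in c("total_rna", "trap", "footprint")) {
    fr <- simulate_reads(tr, cfg, assay, genotype = gt)
    expect_false(tr$gene_id[1] %in% fr$transcript_id)
    expect_gt(nrow(fr), 0)
  }
  expect_error(apply_genotype(tr, genotype_spec("bad", deletions = data.frame(
    gene_id = "nope", start = 0L, end = 10L))), "unknown gene_id")
})

test_that("residual fragments re-express only their interval", {
  cfg <- small_config(seed = 6, n_genes = 5, library_size = 2e4)
  tr <- generate_transcriptome(cfg)
  g <- tr$gene_id[2]
  L <- tr$utr5_len[2] + tr$cds_len[2] + tr$utr3_len[2]
  cut <- as.integer(floor(L / 2))
  gt <- genotype_spec("partial",
    deletions = data.frame(gene_id = g, start = 0L, end = cut),
    residual_fragments = data.frame(gene_id = g, start = cut, end = L,
                                    tx_mult = 0.5, te_mult = 1))
  fr <- simulate_reads(tr, cfg, "total_rna", genotype = gt)
  hit <- fr[fr$transcript_id == g, ]
  expect_gt(nrow(hit), 0)
  expect_true(all(hit$start >= cut & hit$end <= L))
})

test_that("a 100x transgene raises CDS coverage about 100-fold", {
  cfg <- small_config(seed = 8, n_genes = 6, library_size = 5e4,
                      dispersion = 0)
  tr <- generate_transcriptome(cfg)
  g <- tr$gene_id[3]
  gt <- genotype_spec("tg", transgene_variants = data.frame(
    gene_id = g, utr5_len = 80L, utr3_len = 120L, tx_mult = 100,
    te_mult = 1))
  base <- simulate_reads(tr, cfg, "total_rna", genotype = "WT")
  pert <- simulate_reads(tr, cfg, "total_rna", genotype = gt)
  tg_id <- paste0(g, "_tg1")
  expect_true(tg_id %in% pert$transcript_id)
  # brute-force per-base coverage sums over the CDS of parent vs transgene
  cds_mass <- function(fr, id, u5, cds, len) {
    cov <- brute_coverage(fr[fr$transcript_id == id, ], len)
    sum(cov[(u5 + 1):(u5 + cds)])
  }
  u5 <- tr$utr5_len[3]; cds <- tr$cds_len[3]
  L <- u5 + cds + tr$utr3_len[3]
  m_base <- cds_mass(base, g, u5, cds, L)
  m_tg <- cds_mass(pert, tg_id, 80L, cds, 80L + cds + 120L)
  expect_gt(m_base, 0)
  ratio <- m_tg / m_base
  # fragment counts are length-independent, so per-base CDS mass scales as
  # 100x times the ratio of eligible start positions
  flen <- cfg$rna_fragment_len
  expected <- 100 * (L - flen + 1) / ((80 + cds + 120) - flen + 1)
  expect_gt(ratio / expected, 0.7)
  expect_lt(ratio / expected, 1.4)
})

test_that("read simulation is deterministic given config and seed", {
  cfg <- small_config(seed = 12, n_genes = 15, library_size = 5e3)
  tr <- generate_transcriptome(cfg)
  for (assay in c("total_rna", "footprint")) {
    expect_identical(simulate_reads(tr, cfg, assay),
                     simulate_reads(tr, cfg, assay))
  }
  empty <- simulate_reads(generate_transcriptome(small_config(n_genes = 0)),
                          cfg, "footprint")
  expect_equal(nrow(empty), 0)
})
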