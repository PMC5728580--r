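test_that("count_reads tallies per gene and conserves totals", {
  ann <- toy_annotation()
  fr <- rbind(frag("gA", 0, 50)[rep(1, 7), ], frag("gB", 10, 60)[rep(1, 3), ])
  tab <- count_reads(fr, ann)
  cc <- setNames(tab$counts$count, tab$counts$gene_id)
  expect_equal(unname(cc[c("gA", "gB", "gC")]), c(7, 3, 0))
  expect_equal(tab$total_mapped$total, 10)
  # empty input
  tab0 <- count_reads(fr[0, ], ann)
  expect_equal(sum(tab0$counts$count), 0)
  expect_equal(sum(tab0$total_mapped$total), 0)
  expect_error(count_reads(frag("gZ", 0, 10), ann), "gZ")
})

test_that("counts match an independent tally on simulator output", {
  cfg <- small_config(seed = 21, n_genes = 20, library_size = 5e3)
  tr <- generate_transcriptome(cfg)
  fr <- rbind(simulate_reads(tr, cfg, "total_rna"),
              simulate_reads(tr, cfg, "footprint"))
  tab <- count_reads(fr, annotation_of(tr))
  # brute force: loop over fragment records
  for (i in seq_len(nrow(tab$counts))) {
    row <- tab$counts[i, ]
    n <- 0L
    for (j in seq_len(nrow(fr))) {
      if (fr$transcript_id[j] == row$gene_id && fr$assay[j] == row$assay &&
          fr$replicate[j] == row$replicate) n <- n + 1L
    }
    expect_identical(row$count, n)
  }
  sums <- tapply(tab$counts$count,
                 paste(tab$counts$assay, tab$counts$replicate), sum)
  tots <- setNames(tab$total_mapped$total,
                   paste(tab$total_mapped$assay, tab$total_mapped$replicate))
  expect_equal(as.vector(sums[names(tots)]), unname(tots))
})

test_that("the detection filter requires min_reads in every replicate", {
  ann <- toy_annotation()
  mk <- function(counts_by_rep) {
    do.call(rbind, lapply(seq_along(counts_by_rep), function(r) {
      n <- counts_by_rep[r]
      if (n == 0) return(NULL)
      frag("gA", 0, 30, replicate = r)[rep(1, n), ]
    }))
  }
  filler <- do.call(rbind, lapply(1:3, function(r) frag("gB", 0, 30, replicate = r)))
  tab1 <- count_reads(rbind(mk(c(10, 12, 15)), filler), ann)
  expect_true("gA" %in% filter_expressed(tab1, "total_rna", 10))
  tab2 <- count_reads(rbind(mk(c(9, 50, 50)), filler), ann)
  expect_false("gA" %in% filter_expressed(tab2, "total_rna", 10))
  expect_false("gB" %in% filter_expressed(tab2, "total_rna", 10))
  tab3 <- count_reads(filler[0, ], ann)
  expect_equal(filter_expressed(tab3, "total_rna"), character())
  # monotone: raising the threshold never adds genes
  for (m in c(1, 5, 10, 20)) {
    expect_true(all(filter_expressed(tab2, "total_rna", m + 1) %in%
                      filter_expressed(tab2, "total_rna", m)))
  }
})

test_that("RPKM matches its formula and is depth-scale invariant", {
  ann <- data.frame(gene_id = "g1", utr5_len = 0L, cds_len = 1000L,
                    utr3_len = 0L)
  tab <- list(counts = data.frame(gene_id = "g1", assay = "total_rna",
                                  replicate = 1L, count = 1000L),
              total_mapped = data.frame(assay = "total_rna", replicate = 1L,
                                        total = 1e6),
              annotation = ann)
  class(tab) <- "count_table"
  expect_equal(compute_rpkm(tab)$rpkm$rpkm, 1000)
  tab$counts$count <- 0L
  expect_equal(compute_rpkm(tab)$rpkm$rpkm, 0)
  tab$total_mapped$total <- 0
  expect_error(compute_rpkm(tab), "total_mapped")

  # random table vs cell-by-cell formula evaluation
  set.seed(42)
  cfg <- small_config(seed = 22, n_genes = 15, library_size = 4e3)
  tr <- generate_transcriptome(cfg)
  tab2 <- count_reads(simulate_reads(tr, cfg, "trap"), annotation_of(tr))
  expr <- compute_rpkm(tab2)
  exlen <- setNames(tr$utr5_len + tr$cds_len + tr$utr3_len, tr$gene_id)
  tots <- setNames(tab2$total_mapped$total, tab2$total_mapped$replicate)
  manual <- expr$rpkm$count /
    ((exlen[expr$rpkm$gene_id] / 1000) *
       (tots[as.character(expr$rpkm$replicate)] / 1e6))
  expect_equal(expr$rpkm$rpkm, unname(manual), tolerance = 1e-9)
  # doubling all counts and totals leaves RPKM unchanged
  tab3 <- tab2
  tab3$counts$count <- tab3$counts$count * 2L
  tab3$total_mapped$total <- tab3$total_mapped$total * 2L
  expect_equal(compute_rpkm(tab3)$rpkm$rpkm, expr$rpkm$rpkm)
})

test_that("region coverage fractions partition the transcript", {
  ann <- toy_annotation()  # gA: utr5 100, cds 300, utr3 100
  expect_equal(region_coverage_fractions(frag("gA", 150, 250), ann, "gA"),
               c(utr5 = 0, cds = 1, utr3 = 0))
  expect_equal(region_coverage_fractions(frag("gA", 80, 120), ann, "gA"),
               c(utr5 = 0.5, cds = 0.5, utr3 = 0))
  fr <- rbind(frag("gA", 0, 37), frag("gA", 390, 460), frag("gA", 210, 260))
  expect_equal(sum(region_coverage_fractions(fr, ann, "gA")), 1,
               tolerance = 1e-9)
  expect_warning(out <- region_coverage_fractions(frag("gB", 0, 10), ann, "gA"),
                 "undefined")
  expect_true(all(is.na(out)))
})

test_that("region-partitioned expression normalizes against the reference", {
  regions <- data.frame(label = c("r1", "r2"), start = c(0L, 200L),
                        end = c(200L, 500L))
  ref <- rbind(frag("gA", 0, 100)[rep(1, 5), ], frag("gA", 300, 400)[rep(1, 5), ])
  idn <- region_partition_expression(ref, ref, regions,
                                     c(case = 10, reference = 10))
  expect_equal(idn$value, c(1, 1))
  # a case with no reads in r1 (deletion-like)
  case <- frag("gA", 300, 400)[rep(1, 5), ]
  del <- region_partition_expression(case, ref, regions,
                                     c(case = 5, reference = 10))
  expect_equal(del$value[1], 0)
  # zero reference density is undefined
  ref2 <- frag("gA", 0, 100)[rep(1, 5), ]
  und <- region_partition_expression(ref, ref2, regions,
                                     c(case = 10, reference = 5))
  expect_true(is.na(und$value[2]))
  expect_error(region_partition_expression(ref, ref, data.frame(
    label = c("a", "b"), start = c(0L, 100L), end = c(150L, 200L)),
    c(case = 1, reference = 1)), "disjoint")
})

test_that("replicate correlation detects identity, scaling, and noise", {
  cfg <- small_config(seed = 23, n_genes = 60, library_size = 2e4)
  tr <- generate_transcriptome(cfg)
  tab <- count_reads(simulate_reads(tr, cfg, "total_rna"), annotation_of(tr))
  expr <- compute_rpkm(tab)
  # identical replicate
  expr_dup <- expr
  r1 <- expr_dup$rpkm$replicate == 1
  dup <- expr_dup$rpkm[r1, ]
  dup$replicate <- 99L
  expr_dup$rpkm <- rbind(expr_dup$rpkm, dup)
  expect_equal(replicate_correlation(expr_dup, "total_rna", 1, 99), 1)
  # scaled replicate: perfect linear relation
  dup2 <- dup; dup2$replicate <- 98L; dup2$rpkm <- dup2$rpkm * 2
  expr_dup$rpkm <- rbind(expr_dup$rpkm, dup2)
  expect_equal(replicate_correlation(expr_dup, "total_rna", 1, 98), 1)
  # independent expression vectors are uncorrelated
  set.seed(7)
  n <- 1000
  fake <- list(rpkm = data.frame(
    gene_id = rep(sprintf("x%04d", 1:n), 2),
    assay = "total_rna", replicate = rep(1:2, each = n),
    count = 1L, rpkm = rlnorm(2 * n)),
    rpkm_mean = data.frame(gene_id = character(), assay = character(),
                           mean_rpkm = numeric()))
  class(fake) <- "expression_table"
  expect_lt(replicate_correlation(fake, "total_rna", 1, 2), 0.05)
  expect_error(replicate_correlation(fake, "total_rna", 1, 3), "3 genes")
})
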