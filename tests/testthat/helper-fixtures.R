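# Shared fixture builders. Everything is generated in code; no data files.

small_config <- function(seed = 1L, n_genes = 40L, library_size = 2e4, ...) {
  sim_config(seed = seed, n_genes = n_genes, library_size = library_size, ...)
}

annotation_of <- function(tr) {
  parent <- tr[!duplicated(tr$gene_id), ]
  data.frame(gene_id = parent$gene_id, utr5_len = parent$utr5_len,
             cds_len = parent$cds_len, utr3_len = parent$utr3_len,
             stringsAsFactors = FALSE)
}

# Hand-built fragment records.
frag <- function(transcript_id, start, end, assay = "total_rna",
                 replicate = 1L, genotype = "WT") {
  data.frame(transcript_id = transcript_id, start = start, end = end,
             assay = assay, replicate = replicate, genotype = genotype,
             stringsAsFactors = FALSE)
}

# A fixed three-gene annotation used by the hand-built examples.
toy_annotation <- function() {
  data.frame(gene_id = c("gA", "gB", "gC"),
             utr5_len = c(100L, 50L, 20L),
             cds_len = c(300L, 600L, 90L),
             utr3_len = c(100L, 150L, 40L),
             stringsAsFactors = FALSE)
}

# A single-source transcriptome with a chosen sequence, for digestion tests.
manual_transcriptome <- function(sequence, utr5_len, cds_len, utr3_len,
                                 gene_id = "gX", transcription = 100,
                                 te = 1) {
  stopifnot(nchar(sequence) == utr5_len + cds_len + utr3_len)
  tr <- data.frame(gene_id = gene_id, utr5_len = as.integer(utr5_len),
                   cds_len = as.integer(cds_len),
                   utr3_len = as.integer(utr3_len), sequence = sequence,
                   true_transcription = transcription, true_te = te,
                   te_class = "main", src_start = 0L,
                   src_end = as.integer(utr5_len + cds_len + utr3_len),
                   stringsAsFactors = FALSE)
  tr$pause_profile <- list(rep(1, utr5_len + cds_len))
  attr(tr, "scale_total_rna") <- sum(tr$true_transcription)
  attr(tr, "scale_ribo") <- sum(tr$true_transcription * tr$true_te)
  class(tr) <- c("transcriptome", "data.frame")
  tr
}

# Independent per-base coverage tally (the brute-force oracle).
brute_coverage <- function(fragments, len) {
  cov <- numeric(len)
  for (i in seq_len(nrow(fragments))) {
    s <- max(fragments$start[i], 0L) + 1L
    e <- min(fragments$end[i], len)
    if (s <= e) cov[s:e] <- cov[s:e] + 1
  }
  cov
}
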