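# Simulation of transcriptomes and sequencing read fragments for the three
# assays (total RNA, TRAP, ribosome footprinting), including genotype
# perturbations. All coordinates are 0-based, half-open, transcript-relative.

ASSAYS <- c("total_rna", "trap", "footprint")

#' Simulation configuration
#'
#' Bundles every tunable of the read simulator: transcriptome size, replicate
#' structure, sequencing depth, footprint digestion geometry, between-replicate
#' count noise, and the translation-efficiency (TE) mixture.
#'
#' @param seed Integer seed; every simulation stream is derived from it.
#' @param n_genes Number of genes to generate.
#' @param n_replicates Replicates per genotype (default 3).
#' @param library_size Expected fragment count per replicate for the
#'   unperturbed transcriptome. Either a single number or a named vector with
#'   entries `total_rna`, `trap`, `footprint`.
#' @param footprint_len_range Inclusive footprint size-selection window in nt
#'   (default `c(30, 45)`, the gel excision window).
#' @param protected_core_len Length in nt of the ribosome-protected core that
#'   is extended outward to the nearest RNase T1 cut site (default 30).
#' @param dispersion Between-replicate overdispersion of counts: the squared
#'   coefficient of variation of the Gamma factor in the Poisson-Gamma
#'   (negative binomial) count model. 0 gives pure Poisson noise.
#' @param te_mixture Parameters of the TE distribution: a list with `meanlog`,
#'   `sdlog` (log-normal bulk), `spike_prob`, `spike_meanlog`, `spike_sdlog`
#'   (a low-TE component mimicking the ribosomal-protein class).
#' @param transcription_te_anticorrelation If `TRUE` (default), transcription
#'   and TE are coupled with a negative rank correlation, the inverse trend
#'   seen between transcriptional output and translation efficiency.
#' @param rna_fragment_len Fragment length in nt for the full-length mRNA
#'   assays (total RNA and TRAP); default 75 (single-end 75-cycle reads).
#' @param utr5_meanlog,cds_meanlog,utr3_meanlog,len_sdlog Log-normal location
#'   and scale parameters of the segment-length distributions (nt; CDS drawn
#'   in codons and multiplied by 3).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       n_replicates = 3L,
                       library_size = 2e5,
                       footprint_len_range = c(30L, 45L),
                       protected_core_len = 30L,
                       dispersion = 0.01,
                       te_mixture = list(meanlog = 0, sdlog = 0.75,
                                         spike_prob = 0.12,
                                         spike_meanlog = log(0.09),
                                         spike_sdlog = 0.35),
                       transcription_te_anticorrelation = TRUE,
                       rna_fragment_len = 75L,
                       utr5_meanlog = log(150), cds_meanlog = log(400),
                       utr3_meanlog = log(300), len_sdlog = 0.4) {
  if (length(footprint_len_range) != 2L ||
      footprint_len_range[1] > footprint_len_range[2]) {
    stop("invalid footprint_len_range: min must not exceed max")
  }
  if (n_genes < 0) stop("n_genes must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (protected_core_len < 1) stop("protected_core_len must be >= 1")
  lib <- library_size
  if (is.null(names(lib))) lib <- stats::setNames(rep_len(lib, 3L), ASSAYS)
  if (!all(ASSAYS %in% names(lib))) {
    stop("named library_size must cover total_rna, trap, footprint")
  }
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_replicates = as.integer(n_replicates), library_size = lib,
    footprint_len_range = as.integer(footprint_len_range),
    protected_core_len = as.integer(protected_core_len),
    dispersion = dispersion, te_mixture = te_mixture,
    transcription_te_anticorrelation = isTRUE(transcription_te_anticorrelation),
    rna_fragment_len = as.integer(rna_fragment_len),
    utr5_meanlog = utr5_meanlog, cds_meanlog = cds_meanlog,
    utr3_meanlog = utr3_meanlog, len_sdlog = len_sdlog
  ), class = "sim_config")
}

#' Genotype perturbation specification
#'
#' Describes how a genotype differs from the reference transcriptome:
#' genomic deletions (the affected gene no longer produces its full-length
#' transcript), residual remnant transcripts driven from internal promoters,
#' transgene variants sharing the parent CDS but carrying different UTRs, a
#' global translation-efficiency multiplier, and a set of genes with an extra
#' TE boost (TOP-mRNA-like).
#'
#' @param name Genotype label used to tag simulated fragments.
#' @param deletions A data.frame with columns `gene_id`, `start`, `end`
#'   (0-based, half-open interval on the parent transcript). A deleted gene's
#'   transcription is zeroed and the interval is masked against any read.
#' @param residual_fragments A data.frame with columns `gene_id`, `start`,
#'   `end`, `tx_mult`, `te_mult`: remnant transcripts emitting reads only
#'   within the interval, at `tx_mult` times the parent's transcription and
#'   `te_mult` times its TE.
#' @param transgene_variants A data.frame with columns `gene_id`, `utr5_len`,
#'   `utr3_len`, `tx_mult`, `te_mult`: additional transcript entries sharing
#'   the parent CDS with new UTR lengths (sequences drawn at random).
#' @param global_te_multiplier Multiplies every gene's TE (default 1).
#' @param boosted_te_genes Character vector of gene ids receiving an extra TE
#'   multiplier of `boosted_te_factor`.
#' @param boosted_te_factor Extra TE multiplier for `boosted_te_genes`
#'   (default 2).
#' @return A list of class `genotype_spec`.
#' @export
genotype_spec <- function(name,
                          deletions = NULL,
                          residual_fragments = NULL,
                          transgene_variants = NULL,
                          global_te_multiplier = 1,
                          boosted_te_genes = character(),
                          boosted_te_factor = 2) {
  if (global_te_multiplier < 0) stop("global_te_multiplier must be >= 0")
  chk_mult <- function(d, cols) {
    if (!is.null(d) && any(unlist(d[cols]) < 0)) stop("multipliers must be >= 0")
  }
  chk_mult(residual_fragments, c("tx_mult", "te_mult"))
  chk_mult(transgene_variants, c("tx_mult", "te_mult"))
  structure(list(
    name = as.character(name), deletions = deletions,
    residual_fragments = residual_fragments,
    transgene_variants = transgene_variants,
    global_te_multiplier = global_te_multiplier,
    boosted_te_genes = as.character(boosted_te_genes),
    boosted_te_factor = boosted_te_factor
  ), class = "genotype_spec")
}

rlen <- function(n, meanlog, sdlog, min) pmax(round(stats::rlnorm(n, meanlog, sdlog)), min)

draw_te_mixture <- function(n, mix) {
  spike <- stats::runif(n) < mix$spike_prob
  te <- stats::rlnorm(n, mix$meanlog, mix$sdlog)
  te[spike] <- stats::rlnorm(sum(spike), mix$spike_meanlog, mix$spike_sdlog)
  list(te = te, class = ifelse(spike, "spike", "main"))
}

draw_pause_profile <- function(len) {
  prof <- rep(1, len)
  n_pause <- stats::rpois(1L, 3L)
  if (n_pause > 0 && len > 0) {
    at <- sample.int(len, min(n_pause, len))
    prof[at] <- prof[at] + stats::rexp(length(at), rate = 1 / 5)
  }
  prof / mean(prof)
}

#' Generate a synthetic transcriptome
#'
#' Draws gene structures (5'UTR/CDS/3'UTR lengths), nucleotide sequences with
#' uniform base composition (so G residues, the RNase T1 cut sites, occur at
#' about one in four positions), simulation-truth transcription levels and
#' translation efficiencies from the configured mixture, and per-gene ribosome
#' pause profiles over the 5'UTR+CDS. Because TE is dimensionless and only
#' defined relative to a reference, the drawn TE values are rescaled so the
#' abundance-weighted mean TE equals 1 — the scale an RPKM-ratio estimator
#' measures (degenerate zero-variance mixtures are left untouched).
#'
#' The result is a data.frame with one row per emission source. Columns:
#' `gene_id`, `utr5_len`, `cds_len`, `utr3_len`, `sequence` (RNA alphabet),
#' `true_transcription`, `true_te`, `te_class` (`"main"` or `"spike"` for the
#' low-TE component), `src_start`/`src_end` (the interval of the transcript
#' this source emits reads from; the full transcript for generated genes), and
#' list column `pause_profile` (per-position occupancy multiplier over the
#' 5'UTR+CDS, mean 1). Attributes `scale_total_rna` and `scale_ribo` record
#' the unperturbed totals of `true_transcription` and
#' `true_transcription * true_te`; they calibrate sequencing yield so that
#' genotype perturbations change realized library output.
#'
#' @param config A [sim_config()].
#' @param seed Seed for this draw; defaults to `config$seed`.
#' @return A `transcriptome` data.frame (see Details).
#' @export
generate_transcriptome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_genes
  if (n == 0L) return(empty_transcriptome())
  utr5 <- rlen(n, config$utr5_meanlog, config$len_sdlog, 10L)
  cds <- 3L * rlen(n, config$cds_meanlog - log(3), config$len_sdlog, 40L)
  utr3 <- rlen(n, config$utr3_meanlog, config$len_sdlog, 10L)
  len <- utr5 + cds + utr3
  seqs <- vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = "")
  }, character(1))
  transcription <- stats::rlnorm(n, log(50), 1.1)
  mix <- draw_te_mixture(n, config$te_mixture)
  te <- mix$te
  if (config$transcription_te_anticorrelation && n > 1L) {
    # couple TE to transcription with a noisy reversed rank (negative Spearman)
    noisy <- rank(-rank(transcription) + stats::rnorm(n, 0, n * 0.35),
                  ties.method = "first")
    te <- sort(te)[noisy]
    mix$class <- mix$class[order(mix$te)][noisy]
  }
  # TE is dimensionless and only defined relative to a reference point; pin
  # its scale so the abundance-weighted mean TE is 1, the scale an
  # RPKM-ratio estimator measures (total footprint output over total mRNA).
  if (any(te > 0) && stats::sd(te) > 0) {
    te <- te * sum(transcription) / sum(transcription * te)
  }
  tr <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    utr5_len = utr5, cds_len = cds, utr3_len = utr3,
    sequence = seqs,
    true_transcription = transcription, true_te = te,
    te_class = mix$class,
    src_start = 0L, src_end = len,
    stringsAsFactors = FALSE
  )
  tr$pause_profile <- lapply(utr5 + cds, draw_pause_profile)
  attr(tr, "scale_total_rna") <- sum(tr$true_transcription)
  attr(tr, "scale_ribo") <- sum(tr$true_transcription * tr$true_te)
  class(tr) <- c("transcriptome", "data.frame")
  tr
}

empty_transcriptome <- function() {
  tr <- data.frame(gene_id = character(), utr5_len = integer(),
                   cds_len = integer(), utr3_len = integer(),
                   sequence = character(), true_transcription = numeric(),
                   true_te = numeric(), te_class = character(),
                   src_start = integer(), src_end = integer(),
                   stringsAsFactors = FALSE)
  tr$pause_profile <- list()
  attr(tr, "scale_total_rna") <- 0
  attr(tr, "scale_ribo") <- 0
  class(tr) <- c("transcriptome", "data.frame")
  tr
}

transcript_len <- function(tr) tr$utr5_len + tr$cds_len + tr$utr3_len

#' Apply a genotype perturbation to a transcriptome
#'
#' Deletions zero the parent gene's transcription (the full-length transcript
#' is no longer produced) and mask the deleted interval against any residual
#' read. Residual remnants add emission sources restricted to their interval
#' on the parent's coordinates. Transgene variants add new transcript entries
#' (`<gene_id>_tg<i>`) sharing the parent CDS with freshly drawn UTR
#' sequences. The global TE multiplier and the boosted-gene factor scale
#' `true_te`. The yield-calibration attributes of the input are preserved, so
#' perturbations change realized sequencing output rather than being
#' renormalized away.
#'
#' Transgene UTR sequences are drawn from the RNG in effect; seed the RNG (or
#' rely on [simulate_reads()]'s seeding) for reproducibility.
#'
#' @param transcripts A `transcriptome` data.frame.
#' @param genotype A [genotype_spec()].
#' @return A perturbed `transcriptome` data.frame.
#' @export
apply_genotype <- function(transcripts, genotype) {
  stopifnot(inherits(genotype, "genotype_spec"))
  tr <- transcripts
  lookup <- function(ids) {
    miss <- setdiff(ids, tr$gene_id)
    if (length(miss)) {
      stop("unknown gene_id in genotype spec: ", paste(miss, collapse = ", "))
    }
  }
  parent_row <- function(g) which(tr$gene_id == g & tr$src_start == 0L &
                                    tr$src_end == transcript_len(tr))[1]
  orig_tx <- stats::setNames(tr$true_transcription, tr$gene_id)
  orig_te <- stats::setNames(tr$true_te, tr$gene_id)

  del_mask <- rep(list(NULL), nrow(tr))
  if (!is.null(genotype$deletions) && nrow(genotype$deletions)) {
    d <- genotype$deletions
    lookup(d$gene_id)
    for (i in seq_len(nrow(d))) {
      j <- parent_row(d$gene_id[i])
      L <- transcript_len(tr)[j]
      if (d$start[i] < 0 || d$end[i] > L || d$start[i] >= d$end[i]) {
        stop("deletion interval outside transcript for ", d$gene_id[i])
      }
      tr$true_transcription[j] <- 0
      del_mask[[j]] <- rbind(del_mask[[j]], c(d$start[i], d$end[i]))
    }
  }

  new_rows <- list()
  if (!is.null(genotype$residual_fragments) && nrow(genotype$residual_fragments)) {
    rf <- genotype$residual_fragments
    lookup(rf$gene_id)
    for (i in seq_len(nrow(rf))) {
      j <- parent_row(rf$gene_id[i])
      L <- transcript_len(tr)[j]
      if (rf$start[i] < 0 || rf$end[i] > L || rf$start[i] >= rf$end[i]) {
        stop("residual interval outside transcript for ", rf$gene_id[i])
      }
      row <- tr[j, , drop = FALSE]
      row$src_start <- as.integer(rf$start[i])
      row$src_end <- as.integer(rf$end[i])
      row$true_transcription <- orig_tx[[rf$gene_id[i]]] * rf$tx_mult[i]
      row$true_te <- orig_te[[rf$gene_id[i]]] * rf$te_mult[i]
      new_rows[[length(new_rows) + 1L]] <- row
    }
  }

  if (!is.null(genotype$transgene_variants) && nrow(genotype$transgene_variants)) {
    tg <- genotype$transgene_variants
    lookup(tg$gene_id)
    for (i in seq_len(nrow(tg))) {
      j <- parent_row(tg$gene_id[i])
      cds_seq <- substr(tr$sequence[j], tr$utr5_len[j] + 1L,
                        tr$utr5_len[j] + tr$cds_len[j])
      u5 <- as.integer(tg$utr5_len[i]); u3 <- as.integer(tg$utr3_len[i])
      rnd <- function(l) paste(sample(c("A", "C", "G", "U"), l, replace = TRUE),
                               collapse = "")
      row <- tr[j, , drop = FALSE]
      row$gene_id <- sprintf("%s_tg%d", tg$gene_id[i], i)
      row$utr5_len <- u5; row$utr3_len <- u3
      row$sequence <- paste0(rnd(u5), cds_seq, rnd(u3))
      row$src_start <- 0L
      row$src_end <- u5 + tr$cds_len[j] + u3
      row$true_transcription <- orig_tx[[tg$gene_id[i]]] * tg$tx_mult[i]
      row$true_te <- orig_te[[tg$gene_id[i]]] * tg$te_mult[i]
      row$pause_profile <- list(draw_pause_profile(u5 + tr$cds_len[j]))
      new_rows[[length(new_rows) + 1L]] <- row
    }
  }

  tr$del_mask <- del_mask
  if (length(new_rows)) {
    extra <- do.call(rbind, new_rows)
    extra$del_mask <- rep(list(NULL), nrow(extra))
    tr <- rbind(tr, extra)
  }
  tr$true_te <- tr$true_te * genotype$global_te_multiplier
  if (length(genotype$boosted_te_genes)) {
    lookup(genotype$boosted_te_genes)
    hit <- tr$gene_id %in% genotype$boosted_te_genes
    tr$true_te[hit] <- tr$true_te[hit] * genotype$boosted_te_factor
  }
  for (a in c("scale_total_rna", "scale_ribo")) {
    attr(tr, a) <- attr(transcripts, a)
  }
  class(tr) <- c("transcriptome", "data.frame")
  tr
}

# Expected per-source fragment count for one replicate at nominal depth.
# Yield is calibrated against the unperturbed transcriptome via the scale
# attributes, so perturbations (deletions, transgenes, global TE shifts)
# change realized library output instead of being renormalized away.
source_weights <- function(tr, assay) {
  w <- switch(assay,
              total_rna = tr$true_transcription,
              trap = ,
              footprint = tr$true_transcription * tr$true_te)
  scale <- switch(assay,
                  total_rna = attr(tr, "scale_total_rna"),
                  trap = ,
                  footprint = attr(tr, "scale_ribo"))
  if (is.null(scale) || !is.finite(scale) || scale <= 0) scale <- sum(w)
  if (scale <= 0) return(rep(0, nrow(tr)))
  w / scale
}

# 0-based cut boundaries within [src_start, src_end]: a fragment may start or
# end at b if b is a source end or lies immediately 3' of a G residue.
cut_boundaries <- function(sequence, src_start, src_end) {
  g <- which(strsplit(sequence, "", fixed = TRUE)[[1]] == "G")  # 1-based
  b <- g[g > src_start & g < src_end]  # boundary index == position after G
  starts <- sort(unique(c(src_start, b)))
  ends <- sort(unique(c(b, src_end)))
  list(starts = starts, ends = ends)
}

simulate_footprints_gene <- function(row, n_frag, config) {
  L5C <- row$utr5_len + row$cds_len
  win_lo <- max(row$src_start, 0L)
  win_hi <- min(row$src_end, L5C)
  if (n_frag == 0L || win_hi <= win_lo) return(NULL)
  prof <- row$pause_profile[[1]]
  wts <- prof[(win_lo + 1L):win_hi]
  pos <- win_lo - 1L + sample.int(win_hi - win_lo, n_frag, replace = TRUE,
                                  prob = wts)  # 0-based ribosome position
  half <- config$protected_core_len %/% 2L
  s0 <- pmax(pos - half, row$src_start)
  e0 <- pmin(pos + (config$protected_core_len - half), row$src_end)
  cb <- cut_boundaries(row$sequence, row$src_start, row$src_end)
  si <- findInterval(s0, cb$starts)           # largest start boundary <= s0
  start <- cb$starts[pmax(si, 1L)]
  ei <- findInterval(e0 - 0.5, cb$ends) + 1L  # smallest end boundary >= e0
  end <- cb$ends[pmin(ei, length(cb$ends))]
  len <- end - start
  keep <- len >= config$footprint_len_range[1] &
    len <= config$footprint_len_range[2]
  mask <- row$del_mask[[1]]
  if (!is.null(mask)) {
    for (k in seq_len(nrow(mask))) {
      keep <- keep & (end <= mask[k, 1] | start >= mask[k, 2])
    }
  }
  if (!any(keep)) return(NULL)
  data.frame(start = start[keep], end = end[keep])
}

simulate_rna_gene <- function(row, n_frag, config) {
  if (n_frag == 0L) return(NULL)
  span <- row$src_end - row$src_start
  if (span <= 0L) return(NULL)
  flen <- min(config$rna_fragment_len, span)
  start <- row$src_start +
    sample.int(span - flen + 1L, n_frag, replace = TRUE) - 1L
  end <- start + flen
  mask <- row$del_mask[[1]]
  if (!is.null(mask)) {
    keep <- rep(TRUE, n_frag)
    for (k in seq_len(nrow(mask))) {
      keep <- keep & (end <= mask[k, 1] | start >= mask[k, 2])
    }
    if (!any(keep)) return(NULL)
    start <- start[keep]; end <- end[keep]
  }
  data.frame(start = start, end = end)
}

#' Simulate aligned read fragments for one assay
#'
#' Per-replicate fragment counts per emission source are drawn from a
#' Poisson-Gamma (negative binomial) model with expected count
#' `library_size * weight / baseline_scale`, where the weight is
#' `true_transcription` for total RNA and `true_transcription * true_te` for
#' TRAP and footprints. Total-RNA and TRAP fragments are positioned uniformly
#' over the source interval. Footprint fragments are built by drawing a
#' ribosome position over the 5'UTR+CDS weighted by the pause profile,
#' extending a protected core of `protected_core_len` nt outward on each side
#' to the nearest RNase T1 cut boundary (cuts fall 3' of G residues;
#' transcript/source ends also terminate fragments), and retaining the
#' fragment only if its final length lies within `footprint_len_range` (gel
#' size selection; failed fragments are discarded, not redrawn, so per-gene
#' yield is sequence-dependent).
#'
#' @param transcripts A `transcriptome` data.frame, already perturbed by
#'   [apply_genotype()] if desired.
#' @param config A [sim_config()].
#' @param assay One of `"total_rna"`, `"trap"`, `"footprint"`.
#' @param genotype Either a [genotype_spec()] (applied internally; its name
#'   labels the fragments) or a character label (default `"WT"`).
#' @param seed Seed for this stream; default derives from `config$seed` and
#'   the assay so the three assays are independent but reproducible.
#' @return A data.frame of fragment records: `transcript_id`, `start`, `end`,
#'   `assay`, `replicate`, `genotype`.
#' @export
simulate_reads <- function(transcripts, config, assay, genotype = "WT",
                           seed = NULL) {
  assay <- match.arg(assay, ASSAYS)
  stopifnot(inherits(config, "sim_config"))
  if (inherits(genotype, "genotype_spec")) {
    label <- genotype$name
    if (is.null(seed)) seed <- config$seed + 101L * match(assay, ASSAYS) +
        1000L * (utf8ToInt(substr(label, 1, 1)) %% 97L)
    set.seed(seed)
    transcripts <- apply_genotype(transcripts, genotype)
  } else {
    label <- as.character(genotype)
    if (is.null(seed)) seed <- config$seed + 101L * match(assay, ASSAYS)
    set.seed(seed)
  }
  tr <- transcripts
  if (is.null(tr$del_mask)) tr$del_mask <- rep(list(NULL), nrow(tr))
  empty <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), assay = character(),
                      replicate = integer(), genotype = character(),
                      stringsAsFactors = FALSE)
  if (nrow(tr) == 0L) return(empty)
  mu <- config$library_size[[assay]] * source_weights(tr, assay)
  out <- vector("list", config$n_replicates * nrow(tr))
  idx <- 0L
  for (r in seq_len(config$n_replicates)) {
    lambda <- mu
    if (config$dispersion > 0) {
      lambda <- mu * stats::rgamma(length(mu), shape = 1 / config$dispersion,
                                   scale = config$dispersion)
    }
    n_frag <- stats::rpois(length(lambda), lambda)
    for (j in seq_len(nrow(tr))) {
      frag <- if (assay == "footprint") {
        simulate_footprints_gene(tr[j, ], n_frag[j], config)
      } else {
        simulate_rna_gene(tr[j, ], n_frag[j], config)
      }
      if (is.null(frag)) next
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        transcript_id = tr$gene_id[j], start = frag$start, end = frag$end,
        assay = assay, replicate = r, genotype = label,
        stringsAsFactors = FALSE
      )
    }
  }
  if (idx == 0L) return(empty)
  fr <- do.call(rbind, out[seq_len(idx)])
  rownames(fr) <- NULL
  fr
}

#' Simulate all three assays for one genotype
#'
#' Convenience wrapper running [simulate_reads()] for total RNA, TRAP, and
#' footprints with assay-specific derived seeds, returning one combined
#' fragment data.frame.
#'
#' @inheritParams simulate_reads
#' @param assays Subset of assays to simulate.
#' @export
simulate_assays <- function(transcripts, config, genotype = "WT",
                            assays = ASSAYS) {
  do.call(rbind, lapply(assays, function(a) {
    simulate_reads(transcripts, config, a, genotype = genotype)
  }))
}
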