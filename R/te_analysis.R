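# Translation efficiency: computation, classification, sensitivity
# comparison between ribosome profiling and TRAP, metagene occupancy.

#' Translation efficiency
#'
#' TE is the ratio of translational to transcriptional expression:
#' ribosome-profiling (or TRAP) RPKM divided by transcriptional-profiling
#' RPKM.
#'
#' @param ribo_rpkm,transcr_rpkm Numeric vectors (recycled as usual).
#' @return `ribo_rpkm / transcr_rpkm`.
#' @export
compute_te <- function(ribo_rpkm, transcr_rpkm) {
  if (any(transcr_rpkm <= 0)) {
    stop("transcr_rpkm must be > 0; filter undetected genes before computing TE")
  }
  ribo_rpkm / transcr_rpkm
}

#' Classify translation efficiency
#'
#' TE > `high` is high, TE < `low` is low, everything between (boundaries
#' included) is medium.
#'
#' @param te Nonnegative numeric vector.
#' @param high,low Category cutoffs (defaults 2 and 0.5).
#' @return Character vector over `{"high", "medium", "low"}`.
#' @export
classify_te <- function(te, high = 2, low = 0.5) {
  if (any(te < 0)) stop("te must be >= 0")
  ifelse(te > high, "high", ifelse(te < low, "low", "medium"))
}

#' Per-gene translation efficiency table
#'
#' The headline TE per gene divides replicate-mean RPKM by replicate-mean
#' RPKM (`te_ribo`, `te_trap`); `te_mean` is the mean of per-replicate TE
#' ratios, and the category label applies [classify_te()] to `te_ribo`.
#' Per-replicate TEs are returned in the `te_reps` attribute for use in the
#' TE Student test.
#'
#' @param expr An [compute_rpkm()] result covering the transcriptional assay
#'   and at least one translational assay.
#' @param genes Genes to include (typically [filter_joint()] output).
#' @param ribo_assay,transcr_assay,trap_assay Assay labels; set
#'   `trap_assay = NULL` if TRAP was not assayed.
#' @return data.frame `gene_id`, `te_ribo`, `te_trap`, `te_mean`, `category`,
#'   with attribute `te_reps` (long data.frame `gene_id`, `replicate`, `te`).
#' @export
te_table <- function(expr, genes, ribo_assay = "footprint",
                     transcr_assay = "total_rna", trap_assay = "trap") {
  transcr <- expression_vector(expr, transcr_assay, "mean", genes)
  ribo <- expression_vector(expr, ribo_assay, "mean", genes)
  te_ribo <- compute_te(ribo, transcr)
  te_trap <- rep(NA_real_, length(genes))
  if (!is.null(trap_assay) && trap_assay %in% expr$rpkm$assay) {
    te_trap <- compute_te(expression_vector(expr, trap_assay, "mean", genes),
                          transcr)
  }
  reps <- sort(unique(expr$rpkm$replicate[expr$rpkm$assay == ribo_assay]))
  te_reps <- do.call(rbind, lapply(reps, function(r) {
    tr_r <- expression_vector(expr, transcr_assay, r, genes)
    ri_r <- expression_vector(expr, ribo_assay, r, genes)
    ok <- tr_r > 0
    data.frame(gene_id = genes[ok], replicate = r,
               te = ri_r[ok] / tr_r[ok], stringsAsFactors = FALSE)
  }))
  te_mean <- tapply(te_reps$te, te_reps$gene_id, mean)[genes]
  out <- data.frame(gene_id = genes, te_ribo = unname(te_ribo),
                    te_trap = unname(te_trap),
                    te_mean = as.numeric(te_mean),
                    category = classify_te(unname(te_ribo)),
                    stringsAsFactors = FALSE)
  attr(out, "te_reps") <- te_reps
  out
}

#' Convert a mean log2 TE ratio to a percent sensitivity difference
#'
#' A mean log2 ratio of the two methods' TE estimates of magnitude `m`
#' corresponds to one method reporting `(2^m - 1) * 100` percent more signal;
#' the sign of the ratio conveys direction and is reported separately.
#'
#' @param mean_log2_ratio Numeric.
#' @return Percent sensitivity difference (nonnegative).
#' @export
percent_sensitivity <- function(mean_log2_ratio) {
  (2^abs(mean_log2_ratio) - 1) * 100
}

#' Compare ribosome-profiling and TRAP sensitivity by TE category
#'
#' Genes are categorized by the average of the two TE measurements (high
#' above 2, low below 0.5, else medium); per category, the mean
#' log2(TE_ribo / TE_trap) and its percent-sensitivity conversion are
#' reported. A ratio above 0 in the high-TE group, or below 0 in the low-TE
#' group, indicates the footprint-based measurement responds more strongly to
#' translational differences than TRAP. Genes with a zero TRAP TE are
#' excluded (with a message).
#'
#' @param te_ribo,te_trap Named (or parallel) numeric TE vectors per gene.
#' @return data.frame `category`, `n_genes`, `mean_log2_ratio`,
#'   `percent_sensitivity`, `direction` (`"ribo_higher"`, `"ribo_lower"`, or
#'   `"equal"`).
#' @export
sensitivity_comparison <- function(te_ribo, te_trap) {
  stopifnot(length(te_ribo) == length(te_trap))
  drop <- te_trap == 0
  if (any(drop)) {
    message("excluding ", sum(drop), " gene(s) with zero TRAP TE")
    te_ribo <- te_ribo[!drop]; te_trap <- te_trap[!drop]
  }
  cat_ <- classify_te((te_ribo + te_trap) / 2)
  res <- lapply(c("high", "medium", "low"), function(cc) {
    sel <- cat_ == cc
    if (!any(sel)) {
      return(data.frame(category = cc, n_genes = 0L,
                        mean_log2_ratio = NA_real_,
                        percent_sensitivity = NA_real_,
                        direction = NA_character_, stringsAsFactors = FALSE))
    }
    m <- mean(log2(te_ribo[sel] / te_trap[sel]))
    data.frame(category = cc, n_genes = sum(sel), mean_log2_ratio = m,
               percent_sensitivity = percent_sensitivity(m),
               direction = if (m > 0) "ribo_higher" else
                 if (m < 0) "ribo_lower" else "equal",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Metagene occupancy profile
#'
#' Averages normalized per-base read density across genes after aligning them
#' at a common anchor. Offset 0 is the first nucleotide of the start codon
#' (`anchor = "start_codon"`) or the first nucleotide 3' of the stop codon
#' (`anchor = "stop_codon"`). Per gene, coverage in the window is normalized
#' by that gene's mean coverage over the window before averaging, so each
#' gene contributes equally regardless of expression. Genes whose window does
#' not fit inside the transcript, or with fewer than `min_reads` fragments
#' overlapping the window, are excluded.
#'
#' @param fragments Fragment data.frame (subset to one assay first if mixed).
#' @param annotation Annotation data.frame.
#' @param anchor `"start_codon"` or `"stop_codon"`.
#' @param window `c(upstream, downstream)` extent in nt (both > 0).
#' @param min_reads Minimum fragments overlapping the window (default 1).
#' @return Object of class `metagene_profile`: list with `anchor`, `offsets`
#'   (`-upstream .. downstream`), `density`, `n_genes`.
#' @export
metagene_profile <- function(fragments, annotation,
                             anchor = c("start_codon", "stop_codon"),
                             window = c(50L, 50L), min_reads = 1L) {
  anchor <- match.arg(anchor)
  check_annotation(annotation)
  if (any(window <= 0)) stop("window must be positive in both directions")
  up <- window[1]; down <- window[2]
  offsets <- seq.int(-up, down)
  acc <- matrix(0, nrow = 0, ncol = length(offsets))
  for (j in seq_len(nrow(annotation))) {
    g <- annotation$gene_id[j]
    len <- annotation$utr5_len[j] + annotation$cds_len[j] + annotation$utr3_len[j]
    a <- if (anchor == "start_codon") annotation$utr5_len[j] else
      annotation$utr5_len[j] + annotation$cds_len[j]
    lo <- a - up; hi <- a + down + 1L  # window spans positions lo..hi-1
    if (lo < 0L || hi > len) next
    fr <- fragments[fragments$transcript_id == g, , drop = FALSE]
    n_over <- sum(fr$end > lo & fr$start < hi)
    if (n_over < min_reads) next
    cov <- coverage_vector(fr$start, fr$end, len)[(lo + 1L):hi]
    m <- mean(cov)
    if (m == 0) next
    acc <- rbind(acc, cov / m)
  }
  if (nrow(acc) == 0L) stop("no genes qualify for the metagene profile")
  structure(list(anchor = anchor, offsets = offsets,
                 density = colMeans(acc), n_genes = nrow(acc)),
            class = "metagene_profile")
}

#' @export
as.data.frame.metagene_profile <- function(x, ...) {
  data.frame(offset = x$offsets, density = x$density, n_genes = x$n_genes)
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("Metagene profile (", x$anchor, "), ", x$n_genes, " genes, offsets ",
      min(x$offsets), "..", max(x$offsets), "\n", sep = "")
  invisible(x)
}

#' Genes with the most extreme translation efficiency
#'
#' Sorts genes by `te_mean` (ties broken by `gene_id`, lexicographically, so
#' selection is stable) and returns the `k` lowest and `k` highest.
#'
#' @param te_records A [te_table()] result (or any data.frame with `gene_id`
#'   and `te_mean`).
#' @param k Number of genes per extreme (default 100).
#' @return List with data.frames `lowest` and `highest`.
#' @export
rank_te_extremes <- function(te_records, k = 100L) {
  n <- nrow(te_records)
  if (n < k) {
    warning("only ", n, " genes available; returning all")
    k <- n
  }
  ord_lo <- order(te_records$te_mean, te_records$gene_id)
  ord_hi <- order(-te_records$te_mean, te_records$gene_id)
  list(lowest = te_records[ord_lo[seq_len(k)], , drop = FALSE],
       highest = te_records[ord_hi[seq_len(k)], , drop = FALSE])
}
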