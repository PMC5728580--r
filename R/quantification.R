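# Fragment records -> filtered count tables, RPKM expression tables,
# region-partitioned coverage, and replicate-agreement statistics.

#' Count fragments per gene, assay, and replicate
#'
#' Each fragment increments exactly one gene's count (assignment by
#' `transcript_id`). The per-assay/replicate total mapped reads used for
#' normalization equals the number of fragments processed.
#'
#' @param fragments Fragment data.frame with columns `transcript_id`, `start`,
#'   `end`, `assay`, `replicate` (and optionally `genotype`).
#' @param annotation Annotation data.frame with columns `gene_id`,
#'   `utr5_len`, `cds_len`, `utr3_len`. Every annotated gene appears in the
#'   output (zero-filled) for every assay/replicate present in `fragments`.
#' @return A list of class `count_table`: `counts` (long data.frame
#'   `gene_id`, `assay`, `replicate`, `count`) and `total_mapped`
#'   (`assay`, `replicate`, `total`).
#' @export
count_reads <- function(fragments, annotation) {
  check_annotation(annotation)
  unknown <- setdiff(unique(fragments$transcript_id), annotation$gene_id)
  if (length(unknown)) {
    stop("fragments reference unknown transcript ids: ",
         paste(sort(unknown), collapse = ", "))
  }
  combos <- unique(fragments[, c("assay", "replicate"), drop = FALSE])
  if (nrow(combos) == 0L) {
    counts <- data.frame(gene_id = character(), assay = character(),
                         replicate = integer(), count = integer(),
                         stringsAsFactors = FALSE)
    totals <- data.frame(assay = character(), replicate = integer(),
                         total = integer(), stringsAsFactors = FALSE)
  } else {
    combos <- combos[order(combos$assay, combos$replicate), , drop = FALSE]
    counts <- expand.grid(gene_id = annotation$gene_id,
                          key = paste(combos$assay, combos$replicate, sep = "\r"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key_parts <- do.call(rbind, strsplit(counts$key, "\r", fixed = TRUE))
    counts$assay <- key_parts[, 1]
    counts$replicate <- as.integer(key_parts[, 2])
    counts$key <- NULL
    tal <- table(paste(fragments$transcript_id, fragments$assay,
                       fragments$replicate, sep = "\r"))
    counts$count <- as.integer(tal[paste(counts$gene_id, counts$assay,
                                         counts$replicate, sep = "\r")])
    counts$count[is.na(counts$count)] <- 0L
    tot <- table(paste(fragments$assay, fragments$replicate, sep = "\r"))
    totals <- data.frame(assay = combos$assay, replicate = combos$replicate,
                         total = as.integer(tot[paste(combos$assay,
                                                      combos$replicate,
                                                      sep = "\r")]),
                         stringsAsFactors = FALSE)
  }
  rownames(counts) <- NULL
  structure(list(counts = counts, total_mapped = totals,
                 annotation = annotation),
            class = "count_table")
}

check_annotation <- function(annotation) {
  need <- c("gene_id", "utr5_len", "cds_len", "utr3_len")
  if (!all(need %in% names(annotation))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(annotation$gene_id)) stop("duplicate gene_id in annotation")
  invisible(annotation)
}

#' Genes reliably detected in an assay
#'
#' A gene passes iff its unique-exon read count reaches `min_reads` in every
#' replicate of the assay; below about 10 reads, replicate variability rises
#' sharply, so such genes are not considered reliably detected.
#'
#' @param table A [count_reads()] result.
#' @param assay Assay to filter on.
#' @param min_reads Minimum count required in all replicates (default 10).
#' @return Sorted character vector of passing gene ids.
#' @export
filter_expressed <- function(table, assay, min_reads = 10) {
  stopifnot(inherits(table, "count_table"))
  cc <- table$counts[table$counts$assay == assay, , drop = FALSE]
  if (nrow(cc) == 0L) return(character())
  ok <- tapply(cc$count >= min_reads, cc$gene_id, all)
  sort(names(ok)[ok])
}

#' Genes in the joint transcriptome/translatome analysis set
#'
#' Genes must pass [filter_expressed()] in both the transcriptional assay and
#' the ribosome-profiling assay; genes detected only transcriptionally are
#' excluded from joint analyses.
#'
#' @inheritParams filter_expressed
#' @param transcr_assay,ribo_assay Assay labels.
#' @export
filter_joint <- function(table, transcr_assay = "total_rna",
                         ribo_assay = "footprint", min_reads = 10) {
  intersect(filter_expressed(table, transcr_assay, min_reads),
            filter_expressed(table, ribo_assay, min_reads))
}

#' Compute RPKM expression values
#'
#' RPKM = count / ((exon_len/1000) * (total_mapped/1e6)), per replicate, with
#' the per-replicate total mapped reads of the same assay as depth normalizer.
#' Replicate-mean RPKM is also reported.
#'
#' @param table A [count_reads()] result.
#' @param exon_len Named numeric vector of exonic lengths per gene, or `NULL`
#'   to derive `utr5_len + cds_len + utr3_len` from the table's annotation.
#' @return A list of class `expression_table`: `rpkm` (long data.frame
#'   `gene_id`, `assay`, `replicate`, `count`, `rpkm`), `rpkm_mean`
#'   (`gene_id`, `assay`, `mean_rpkm`), and `exon_len`.
#' @export
compute_rpkm <- function(table, exon_len = NULL) {
  stopifnot(inherits(table, "count_table"))
  if (is.null(exon_len)) {
    ann <- table$annotation
    exon_len <- stats::setNames(ann$utr5_len + ann$cds_len + ann$utr3_len,
                                ann$gene_id)
  }
  if (any(exon_len <= 0)) stop("exon_len must be > 0 for every gene")
  if (any(table$total_mapped$total <= 0)) {
    stop("total_mapped is zero for at least one assay/replicate; ",
         "RPKM normalization is impossible")
  }
  rpkm <- table$counts
  miss <- setdiff(unique(rpkm$gene_id), names(exon_len))
  if (length(miss)) stop("missing exon_len for: ", paste(miss, collapse = ", "))
  tot <- stats::setNames(table$total_mapped$total,
                         paste(table$total_mapped$assay,
                               table$total_mapped$replicate, sep = "\r"))
  denom <- (exon_len[rpkm$gene_id] / 1e3) *
    (tot[paste(rpkm$assay, rpkm$replicate, sep = "\r")] / 1e6)
  rpkm$rpkm <- as.numeric(rpkm$count / denom)
  mean_tab <- stats::aggregate(rpkm ~ gene_id + assay, data = rpkm, FUN = mean)
  names(mean_tab)[names(mean_tab) == "rpkm"] <- "mean_rpkm"
  structure(list(rpkm = rpkm, rpkm_mean = mean_tab, exon_len = exon_len),
            class = "expression_table")
}

#' Extract an expression vector or matrix
#'
#' @param expr An [compute_rpkm()] result.
#' @param assay Assay to extract.
#' @param replicate A replicate index, `"mean"` (default) for replicate-mean
#'   RPKM, or a vector of indices to average over.
#' @param genes Optional subset of gene ids (order preserved).
#' @return Named numeric vector of expression values.
#' @export
expression_vector <- function(expr, assay, replicate = "mean", genes = NULL) {
  stopifnot(inherits(expr, "expression_table"))
  if (identical(replicate, "mean")) {
    m <- expr$rpkm_mean[expr$rpkm_mean$assay == assay, ]
    v <- stats::setNames(m$mean_rpkm, m$gene_id)
  } else {
    rr <- expr$rpkm[expr$rpkm$assay == assay &
                      expr$rpkm$replicate %in% replicate, ]
    agg <- tapply(rr$rpkm, rr$gene_id, mean)
    v <- stats::setNames(as.numeric(agg), names(agg))
  }
  if (!is.null(genes)) v <- v[genes]
  v
}

# Per-base coverage over [0, len) from fragment intervals.
coverage_vector <- function(starts, ends, len) {
  cov <- numeric(len + 1L)
  if (length(starts)) {
    add <- tabulate(pmax(starts, 0L) + 1L, nbins = len + 1L)
    sub <- tabulate(pmin(ends, len) + 1L, nbins = len + 1L)
    cov <- cumsum(add - sub)
  }
  cov[seq_len(len)]
}

#' Fraction of coverage mass in the 5'UTR, CDS, and 3'UTR
#'
#' Per-base coverage mass is summed within each region and divided by the
#' total mass over the transcript.
#'
#' @param fragments Fragment data.frame (any assay mix; subset first if
#'   needed).
#' @param annotation Annotation data.frame.
#' @param gene_id Gene to profile.
#' @return Named numeric `c(utr5, cds, utr3)` summing to 1, or all-`NA` with
#'   attribute `undefined = TRUE` (and a warning) when the gene has no
#'   coverage.
#' @export
region_coverage_fractions <- function(fragments, annotation, gene_id) {
  check_annotation(annotation)
  j <- match(gene_id, annotation$gene_id)
  if (is.na(j)) stop("unknown gene_id: ", gene_id)
  u5 <- annotation$utr5_len[j]; cds <- annotation$cds_len[j]
  u3 <- annotation$utr3_len[j]
  len <- u5 + cds + u3
  fr <- fragments[fragments$transcript_id == gene_id, , drop = FALSE]
  cov <- coverage_vector(fr$start, fr$end, len)
  total <- sum(cov)
  if (total == 0) {
    warning("no coverage for gene ", gene_id, "; fractions undefined")
    return(structure(c(utr5 = NA_real_, cds = NA_real_, utr3 = NA_real_),
                     undefined = TRUE))
  }
  c(utr5 = sum(cov[seq_len(u5)]) / total,
    cds = sum(cov[u5 + seq_len(cds)]) / total,
    utr3 = sum(cov[u5 + cds + seq_len(u3)]) / total)
}

#' Region-partitioned expression normalized to a reference condition
#'
#' For each region, per-base read density (coverage mass / region length) is
#' divided by the library size; the reported value is the case density over
#' the reference density. The reference compared against itself yields 1 in
#' every region; regions with zero reference density are reported `NA`
#' (undefined).
#'
#' @param case_fragments,reference_fragments Fragment data.frames restricted
#'   to one gene and assay.
#' @param regions data.frame with columns `label`, `start`, `end` (disjoint,
#'   ordered, 0-based half-open).
#' @param library_sizes Named numeric `c(case = , reference = )`: total mapped
#'   fragments of the assay/condition, the depth normalizer.
#' @return data.frame `label`, `start`, `end`, `value`.
#' @export
region_partition_expression <- function(case_fragments, reference_fragments,
                                        regions, library_sizes) {
  stopifnot(all(c("label", "start", "end") %in% names(regions)),
            all(c("case", "reference") %in% names(library_sizes)))
  if (any(regions$start >= regions$end)) stop("empty region interval")
  if (is.unsorted(regions$start) ||
      any(regions$start[-1] < regions$end[-nrow(regions)])) {
    stop("regions must be disjoint and ordered")
  }
  len <- max(regions$end)
  mass <- function(fr) {
    cov <- coverage_vector(fr$start, fr$end, len)
    vapply(seq_len(nrow(regions)), function(i) {
      sum(cov[(regions$start[i] + 1L):regions$end[i]])
    }, numeric(1))
  }
  dens_case <- mass(case_fragments) / (regions$end - regions$start) /
    library_sizes[["case"]]
  dens_ref <- mass(reference_fragments) / (regions$end - regions$start) /
    library_sizes[["reference"]]
  value <- ifelse(dens_ref > 0, dens_case / dens_ref, NA_real_)
  data.frame(label = regions$label, start = regions$start, end = regions$end,
             value = value, stringsAsFactors = FALSE)
}

#' Replicate agreement (r squared)
#'
#' Coefficient of determination of the least-squares fit between two
#' replicates' expression values, optionally log10-scaled (the default, since
#' replicate scatter is assessed on log axes). Genes with nonpositive values
#' are dropped under the log transform.
#'
#' @param expr An [compute_rpkm()] result.
#' @param assay Assay to compare.
#' @param rep_a,rep_b Replicate indices.
#' @param log_transform Use log10 expression (default `TRUE`).
#' @param genes Optional gene subset (e.g. the [filter_expressed()] set).
#' @return r squared in `[0, 1]`.
#' @export
replicate_correlation <- function(expr, assay, rep_a, rep_b,
                                  log_transform = TRUE, genes = NULL) {
  a <- expression_vector(expr, assay, rep_a, genes)
  b <- expression_vector(expr, assay, rep_b, genes)
  shared <- intersect(names(a), names(b))
  x <- a[shared]; y <- b[shared]
  if (log_transform) {
    keep <- x > 0 & y > 0
    x <- log10(x[keep]); y <- log10(y[keep])
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 genes with finite values")
  stats::cor(x, y)^2
}
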