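# Stable file dialects: FASTA for transcript sequences, TSV for the
# annotation table, BED-like TSV for fragments, TSV outputs with headers.

#' Write a transcriptome to FASTA plus an annotation table
#'
#' @param transcripts A `transcriptome` data.frame.
#' @param fasta_path Output FASTA (one record per transcript, id = gene_id).
#' @param annotation_path Output TSV (`gene_id`, `utr5_len`, `cds_len`,
#'   `utr3_len`). Duplicate source rows for the same gene are written once.
#' @export
write_transcriptome <- function(transcripts, fasta_path, annotation_path) {
  parent <- transcripts[!duplicated(transcripts$gene_id), , drop = FALSE]
  seqs <- Biostrings::RNAStringSet(stats::setNames(parent$sequence,
                                                   parent$gene_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  write_tsv(parent[, c("gene_id", "utr5_len", "cds_len", "utr3_len")],
            annotation_path)
}

#' Read an annotation table
#'
#' @param path TSV with columns `gene_id`, `utr5_len`, `cds_len`, `utr3_len`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_annotation(ann)
  ann
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA of transcript sequences (RNA or DNA alphabet; T is read
#'   as U).
#' @return Named character vector of RNA sequences.
#' @export
read_transcript_sequences <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- chartr("Tt", "Uu", toupper(as.character(ss)))
  stats::setNames(out, sub("\\s.*$", "", names(ss)))
}

#' Write / read fragment records
#'
#' BED-like TSV with header: `transcript_id`, `start`, `end`, `assay`,
#' `replicate`, `genotype`; 0-based half-open coordinates.
#'
#' @param fragments Fragment data.frame.
#' @param path File path.
#' @export
write_fragments <- function(fragments, path) {
  write_tsv(fragments[, c("transcript_id", "start", "end", "assay",
                          "replicate", "genotype")], path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  fr <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "start", "end", "assay", "replicate", "genotype")
  if (!all(need %in% names(fr))) {
    stop("fragment file must have columns: ", paste(need, collapse = ", "))
  }
  if (any(fr$start < 0 | fr$start >= fr$end)) {
    stop("fragment intervals must satisfy 0 <= start < end")
  }
  fr
}

#' Convert SAM alignments to fragment records
#'
#' Adapter for reads already aligned to transcript coordinates: each mapped
#' record becomes one fragment spanning its aligned reference interval.
#' Requires the Rsamtools package.
#'
#' @param path SAM/BAM file with transcript-coordinate alignments.
#' @param assay,replicate,genotype Tags applied to every record.
#' @return Fragment data.frame.
#' @export
read_fragments_sam <- function(path, assay, replicate, genotype = "user") {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required for SAM/BAM ingestion")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE)
  }
  b <- Rsamtools::scanBam(path,
    param = Rsamtools::ScanBamParam(what = c("rname", "pos", "qwidth", "cigar"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
  width <- cigar_ref_width(b$cigar, b$qwidth)
  data.frame(transcript_id = as.character(b$rname), start = b$pos - 1L,
             end = b$pos - 1L + width, assay = assay,
             replicate = as.integer(replicate), genotype = genotype,
             stringsAsFactors = FALSE)
}

# Reference span from CIGAR (M/D/N/=/X consume reference); falls back to the
# query width when the CIGAR is absent.
cigar_ref_width <- function(cigar, qwidth) {
  vapply(seq_along(cigar), function(i) {
    cg <- cigar[i]
    if (is.na(cg) || cg == "*") return(as.integer(qwidth[i]))
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    as.integer(sum(n[op %in% c("M", "D", "N", "=", "X")]))
  }, integer(1))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a count table as TSV
#'
#' @param table A [count_reads()] result.
#' @param counts_path,totals_path Output paths.
#' @export
write_count_table <- function(table, counts_path, totals_path) {
  write_tsv(table$counts, counts_path)
  write_tsv(table$total_mapped, totals_path)
}

#' Write an expression table as TSV
#'
#' @param expr A [compute_rpkm()] result.
#' @param rpkm_path,mean_path Output paths.
#' @export
write_expression_table <- function(expr, rpkm_path, mean_path) {
  write_tsv(expr$rpkm, rpkm_path)
  write_tsv(expr$rpkm_mean, mean_path)
}
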