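#' Transcribe a gene model into stranded cDNA
#'
#' For each transcript the exonic substrings are taken from the reference
#' genome in genomic order and concatenated; minus-strand transcripts are
#' reverse-complemented, so every returned sequence is the sense strand of
#' the mature mRNA. Sequence names are the transcript ids.
#'
#' @param gt a `ground_truth` or [annotation_set()].
#' @param genome a `DNAStringSet` as returned by [read_genome()].
#' @return A named `DNAStringSet`, one entry per transcript.
#' @export
transcribe <- function(gt, genome) {
  ann <- if (inherits(gt, "ground_truth")) gt$annotation else gt
  tx <- ann$transcripts
  if (nrow(tx) == 0L) return(Biostrings::DNAStringSet())
  widths <- stats::setNames(Biostrings::width(genome), names(genome))
  seqs <- character(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    tid <- tx$transcript_id[i]
    ex <- transcript_exons(ann, tid)
    contig <- ex$contig[1L]
    if (!contig %in% names(genome))
      stop2("transcript '%s': contig '%s' not in genome", tid, contig)
    if (any(ex$end > widths[[contig]]))
      stop2("transcript '%s': exon beyond end of contig '%s'", tid, contig)
    parts <- substring(as.character(genome[[contig]]),
                       ex$start + 1L, ex$end)
    seqs[i] <- paste(parts, collapse = "")
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- tx$transcript_id
  minus <- tx$strand == "-"
  if (any(minus))
    out[minus] <- Biostrings::reverseComplement(out[minus])
  out
}

#' Per-isoform sequence statistics
#'
#' GC content counts G and C only; ambiguity codes (N) are excluded from the
#' numerator but included in the denominator, the usual QC convention.
#'
#' @param seqs a named `DNAStringSet` of transcript sequences.
#' @param ann optional [annotation_set()] supplying exon counts.
#' @return data.frame with `transcript_id`, `length`, `gc_content`,
#'   `n_exons` (NA when `ann` is not given).
#' @export
isoform_stats <- function(seqs, ann = NULL) {
  len <- Biostrings::width(seqs)
  gc <- as.vector(Biostrings::letterFrequency(seqs, "GC")) / pmax(len, 1L)
  n_exons <- rep(NA_integer_, length(seqs))
  if (!is.null(ann)) {
    m <- match(names(seqs), ann$transcripts$transcript_id)
    n_exons <- ann$transcripts$n_exons[m]
  }
  data.frame(transcript_id = names(seqs), length = len,
             gc_content = round(gc, 6L), n_exons = n_exons,
             stringsAsFactors = FALSE)
}

#' Write isoform statistics as TSV
#' @param stats data.frame from [isoform_stats()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_isoform_stats <- function(stats, path) {
  stats$gc_content <- sprintf("%.6f", stats$gc_content)
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write per-isoform FASTA files plus one combined FASTA
#'
#' Each isoform is written to `{transcript_id}.fa` in `directory` (path
#' separators in ids sanitized to underscore) and all isoforms to one
#' combined `transcripts.fa`.
#'
#' @param seqs a named `DNAStringSet`.
#' @param directory output directory, created if absent.
#' @return Invisibly, the combined FASTA path.
#' @export
write_per_isoform_fasta <- function(seqs, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(seqs)) {
    safe <- gsub("[/\\\\]", "_", names(seqs)[i])
    Biostrings::writeXStringSet(seqs[i],
                                file.path(directory, paste0(safe, ".fa")))
  }
  combined <- file.path(directory, "transcripts.fa")
  Biostrings::writeXStringSet(seqs, combined)
  invisible(combined)
}
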