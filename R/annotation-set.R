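#' In-memory gene model
#'
#' An `annotation_set` holds genes, transcripts and their ordered exons as a
#' validated, plain data structure. It is the common currency of the simulator
#' (which writes ground-truth annotations) and the evaluator (which compares
#' isoform sets). Coordinates are 0-based half-open internally; GTF I/O
#' converts to and from the 1-based inclusive convention at the boundary.
#'
#' @param exons a data.frame with columns `transcript_id`, `gene_id`,
#'   `contig`, `start`, `end` (0-based half-open) and `strand` (`"+"`/`"-"`),
#'   one row per exon.
#' @param source_dialect attribute dialect the annotation was read from,
#'   `"ensembl"` or `"ucsc"`; informational only.
#'
#' @return An object of class `annotation_set` with elements `exons` (sorted
#'   by transcript then start), `transcripts` (one row per transcript with
#'   contig, strand, span and intron-chain key) and `source_dialect`.
#' @export
annotation_set <- function(exons, source_dialect = "ensembl") {
  required <- c("transcript_id", "gene_id", "contig", "start", "end", "strand")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0L)
    stop2("exon table lacks columns: %s", paste(missing_cols, collapse = ", "))
  exons <- as.data.frame(exons)[required]
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$gene_id <- as.character(exons$gene_id)
  exons$contig <- as.character(exons$contig)
  exons$strand <- as.character(exons$strand)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)

  if (nrow(exons) > 0L) {
    if (any(!exons$strand %in% c("+", "-")))
      stop2("strand must be '+' or '-'")
    if (any(exons$start < 0L) || any(exons$end <= exons$start))
      stop2("exons must satisfy 0 <= start < end")
    exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
    rownames(exons) <- NULL
  }

  obj <- structure(
    list(exons = exons,
         transcripts = summarize_transcripts(exons),
         source_dialect = source_dialect),
    class = "annotation_set"
  )
  validate_annotation(obj)
  obj
}

# One row per transcript: identity, location, exon count, span, transcribed
# length and the intron-chain key used for exact splice-boundary matching.
summarize_transcripts <- function(exons) {
  empty <- data.frame(transcript_id = character(), gene_id = character(),
                      contig = character(), strand = character(),
                      n_exons = integer(), start = integer(), end = integer(),
                      length = integer(), chain = character(),
                      stringsAsFactors = FALSE)
  if (nrow(exons) == 0L) return(empty)
  idx <- split(seq_len(nrow(exons)), exons$transcript_id)
  rows <- lapply(idx, function(i) {
    e <- exons[i, , drop = FALSE]
    data.frame(
      transcript_id = e$transcript_id[1L],
      gene_id = e$gene_id[1L],
      contig = e$contig[1L],
      strand = e$strand[1L],
      n_exons = nrow(e),
      start = min(e$start),
      end = max(e$end),
      length = sum(e$end - e$start),
      chain = chain_key(e),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Intron-chain key: "donor-acceptor,donor-acceptor,..." over sorted exons,
# "" for mono-exonic transcripts. Donor = upstream exon end, acceptor =
# downstream exon start, genomic coordinates. Keys are only compared between
# transcripts on the same contig and strand.
chain_key <- function(exon_rows) {
  k <- nrow(exon_rows)
  if (k < 2L) return("")
  donors <- exon_rows$end[-k]
  acceptors <- exon_rows$start[-1L]
  paste(donors, acceptors, sep = "-", collapse = ",")
}

validate_annotation <- function(ann) {
  tx <- ann$transcripts
  ex <- ann$exons
  if (nrow(ex) == 0L) return(invisible(ann))
  for (i in seq_len(nrow(ex))[-1L]) {
    same_tx <- ex$transcript_id[i] == ex$transcript_id[i - 1L]
    if (!same_tx) next
    if (ex$contig[i] != ex$contig[i - 1L] ||
        ex$strand[i] != ex$strand[i - 1L] ||
        ex$gene_id[i] != ex$gene_id[i - 1L])
      stop2("transcript '%s' mixes contigs, strands or gene ids",
            ex$transcript_id[i])
    if (ex$start[i] < ex$end[i - 1L])
      stop2("transcript '%s' has overlapping or unsorted exons",
            ex$transcript_id[i])
  }
  if (anyDuplicated(tx$transcript_id))
    stop2("duplicated transcript ids")
  invisible(ann)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d transcripts, %d genes, %d exons (%s)\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
              nrow(x$exons), x$source_dialect))
  invisible(x)
}

#' Number of transcripts / genes in an annotation
#' @param ann an `annotation_set`.
#' @return An integer count.
#' @export
n_transcripts <- function(ann) nrow(ann$transcripts)

#' @rdname n_transcripts
#' @export
n_genes <- function(ann) length(unique(ann$transcripts$gene_id))

#' Restrict an annotation to a set of transcripts
#'
#' Genes left without any transcript are dropped entirely.
#'
#' @param ann an `annotation_set`.
#' @param ids character vector of transcript ids to keep.
#' @return A new `annotation_set`.
#' @export
subset_transcripts <- function(ann, ids) {
  keep <- ann$exons$transcript_id %in% ids
  annotation_set(ann$exons[keep, , drop = FALSE], ann$source_dialect)
}

#' Exon rows of one transcript, sorted by start
#' @param ann an `annotation_set`.
#' @param transcript_id a single transcript id.
#' @return A data.frame of exon rows.
#' @export
transcript_exons <- function(ann, transcript_id) {
  e <- ann$exons[ann$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(e) == 0L) stop2("unknown transcript '%s'", transcript_id)
  e
}

# Gene spans: [min start, max end] over a gene's transcripts, per contig.
gene_spans <- function(ann) {
  tx <- ann$transcripts
  if (nrow(tx) == 0L)
    return(data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer()))
  sp <- lapply(split(tx, tx$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1L], contig = g$contig[1L],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, sp)
  rownames(out) <- NULL
  out
}
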