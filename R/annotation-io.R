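#' Read a genome FASTA
#'
#' Loads a (multi-)FASTA into a named `DNAStringSet`. Sequences are
#' uppercased (soft-masked lowercase becomes uppercase) and restricted to the
#' alphabet `{A,C,G,T,N}`; record names are taken up to the first whitespace.
#'
#' @param path path to a FASTA file.
#' @return A `Biostrings::DNAStringSet`, one entry per record.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop2("FASTA file not found: %s", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop2("malformed FASTA '%s': %s", path,
                              conditionMessage(e))
  )
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(names(seqs)))) stop2("FASTA record with empty name")
  if (anyDuplicated(names(seqs)))
    stop2("duplicate contig name(s): %s",
          paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  bad <- Biostrings::letterFrequency(seqs, "ACGTN") != Biostrings::width(seqs)
  if (any(bad))
    stop2("contig(s) with characters outside {A,C,G,T,N}: %s",
          paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Read a GTF annotation into a gene model
#'
#' Parses exon features (other feature types are ignored for model building)
#' and assembles them into transcripts. GTF 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention. Both Ensembl
#' (`key "value";`) and UCSC attribute spacings are accepted.
#'
#' @param path path to a GTF file.
#' @return An [annotation_set()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop2("GTF file not found: %s", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop2("malformed GTF '%s': %s", path,
                              conditionMessage(e))
  )
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  m <- S4Vectors::mcols(gr)
  if (length(gr) == 0L)
    return(annotation_set(data.frame(
      transcript_id = character(), gene_id = character(),
      contig = character(), start = integer(), end = integer(),
      strand = character())))
  tid <- as.character(m$transcript_id %||% rep(NA_character_, length(gr)))
  gid <- as.character(m$gene_id %||% rep(NA_character_, length(gr)))
  if (any(is.na(tid)) || any(!nzchar(tid)))
    stop2("exon feature without transcript_id in '%s'", path)
  if (any(is.na(gid)) || any(!nzchar(gid)))
    stop2("exon feature without gene_id in '%s'", path)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop2("exon feature with missing strand in '%s'", path)
  annotation_set(data.frame(
    transcript_id = tid,
    gene_id = gid,
    contig = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  ))
}

#' Write a gene model as GTF
#'
#' Emits `gene`, `transcript` and `exon` features in Ensembl attribute style,
#' converting internal 0-based half-open coordinates back to 1-based
#' inclusive. Output ordering is canonical (contig, gene span, gene id,
#' transcript id, exon start), so identical models produce byte-identical
#' files. Reading the file back reproduces the model exactly.
#'
#' @param ann an [annotation_set()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(ann, path) {
  header <- "#!gene model written by lrtsim"
  if (n_transcripts(ann) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  tx <- ann$transcripts
  sp <- gene_spans(ann)
  sp <- sp[order(sp$contig, sp$start, sp$gene_id), , drop = FALSE]
  lines <- character(0L)
  fmt <- function(contig, feature, start0, end0, strand, attrs) {
    sprintf("%s\tlrtsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
            contig, feature, start0 + 1L, end0, strand, attrs)
  }
  out <- vector("list", nrow(sp))
  for (g in seq_len(nrow(sp))) {
    gid <- sp$gene_id[g]
    gtx <- tx[tx$gene_id == gid, , drop = FALSE]
    gtx <- gtx[order(gtx$start, gtx$transcript_id), , drop = FALSE]
    gl <- fmt(sp$contig[g], "gene", sp$start[g], sp$end[g], gtx$strand[1L],
              sprintf('gene_id "%s";', gid))
    tl <- character(0L)
    for (t in seq_len(nrow(gtx))) {
      tid <- gtx$transcript_id[t]
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
      ex <- transcript_exons(ann, tid)
      tl <- c(tl,
              fmt(gtx$contig[t], "transcript", gtx$start[t], gtx$end[t],
                  gtx$strand[t], attrs),
              fmt(ex$contig, "exon", ex$start, ex$end, ex$strand, attrs))
    }
    out[[g]] <- c(gl, tl)
  }
  writeLines(c(header, unlist(out)), path)
  invisible(path)
}

#' Subsample annotation completeness
#'
#' Randomly discards a proportion of the reference transcripts, emulating an
#' incomplete reference annotation. Exactly `round(percent * N)` transcripts
#' are retained, chosen uniformly without replacement; genes left with no
#' transcript are dropped, so completeness is reduced at both the isoform and
#' the gene level. Deterministic for a fixed seed.
#'
#' @param ann an [annotation_set()].
#' @param percent fraction of transcripts to retain, in (0, 1].
#' @param seed integer seed.
#' @return A new [annotation_set()] with the retained transcripts unchanged.
#' @export
sample_transcripts <- function(ann, percent, seed = 0L) {
  if (!is_fraction(percent, 0, 1, open_lo = TRUE, open_hi = FALSE))
    stop2("percent must be in (0, 1]")
  if (n_transcripts(ann) == 0L) stop2("annotation is empty")
  ids <- ann$transcripts$transcript_id
  n_keep <- as.integer(round_half_up(percent * length(ids)))
  if (n_keep >= length(ids)) return(ann)
  keep <- local({
    set.seed(derive_seed(seed, "sample_transcripts"))
    sample(ids, n_keep)
  })
  subset_transcripts(ann, keep)
}
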