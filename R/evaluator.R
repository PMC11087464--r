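#' Remove mono-exonic transcripts
#'
#' Mono-exonic transcripts lack splice junctions and are excluded before
#' splice-boundary matching and classification; genes emptied by the filter
#' are dropped.
#'
#' @param ann an [annotation_set()].
#' @return A filtered [annotation_set()].
#' @export
filter_mono_exonic <- function(ann) {
  keep <- ann$transcripts$transcript_id[ann$transcripts$n_exons >= 2L]
  ex <- ann$exons[ann$exons$transcript_id %in% keep, , drop = FALSE]
  annotation_set(ex, ann$source_dialect)
}

# Location-qualified chain key: chains are only comparable on the same
# contig and strand.
located_chains <- function(ann) {
  tx <- ann$transcripts
  stats::setNames(paste(tx$contig, tx$strand, tx$chain, sep = "|"),
                  tx$transcript_id)
}

#' Exact splice-boundary matching of two isoform sets
#'
#' A query transcript is a true positive iff some reference transcript on
#' the same contig and strand has an identical intron chain (all splice-site
#' boundaries shared exactly; terminal exon ends are free to differ). Each
#' reference transcript can absorb at most one query (one-to-one assignment
#' on chain equality, ties broken by lexicographic id for deterministic
#' reports). Unmatched queries are false positives, unmatched references
#' false negatives. Mono-exonic transcripts are excluded unless
#' `keep_mono = TRUE`.
#'
#' @param query,reference [annotation_set()] objects.
#' @param keep_mono keep mono-exonic transcripts (default FALSE).
#' @return A list of class `eval_result`: `TP`, `FP`, `FN`, `precision`,
#'   `sensitivity` (NA when the denominator is 0) and `matches`
#'   (data.frame `query_id`, `reference_id`).
#' @export
match_exact <- function(query, reference, keep_mono = FALSE) {
  if (!keep_mono) {
    query <- filter_mono_exonic(query)
    reference <- filter_mono_exonic(reference)
  }
  orphans <- setdiff(unique(query$transcripts$contig),
                     unique(reference$transcripts$contig))
  if (length(orphans) > 0L && n_transcripts(reference) > 0L)
    warning(sprintf("query contig(s) absent from reference: %s",
                    paste(orphans, collapse = ", ")))
  qc <- located_chains(query)
  rc <- located_chains(reference)
  matches <- list()
  for (key in intersect(unique(qc), unique(rc))) {
    q_ids <- sort(names(qc)[qc == key])
    r_ids <- sort(names(rc)[rc == key])
    m <- min(length(q_ids), length(r_ids))
    matches[[key]] <- data.frame(query_id = q_ids[seq_len(m)],
                                 reference_id = r_ids[seq_len(m)],
                                 stringsAsFactors = FALSE)
  }
  matches <- if (length(matches) > 0L) do.call(rbind, matches) else
    data.frame(query_id = character(), reference_id = character(),
               stringsAsFactors = FALSE)
  matches <- matches[order(matches$query_id), , drop = FALSE]
  rownames(matches) <- NULL
  TP <- nrow(matches)
  FP <- length(qc) - TP
  FN <- length(rc) - TP
  structure(list(
    TP = TP, FP = FP, FN = FN,
    precision = if (TP + FP > 0L) TP / (TP + FP) else NA_real_,
    sensitivity = if (TP + FN > 0L) TP / (TP + FN) else NA_real_,
    matches = matches), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: TP=%d FP=%d FN=%d precision=%.4f sensitivity=%.4f\n",
              x$TP, x$FP, x$FN, x$precision, x$sensitivity))
  invisible(x)
}

# Is `sub` a contiguous run of `full`? Chains as "d-a,d-a,..." strings.
is_contiguous_subchain <- function(sub, full) {
  if (sub == "" || full == "" || sub == full) return(FALSE)
  s <- strsplit(sub, ",", fixed = TRUE)[[1L]]
  f <- strsplit(full, ",", fixed = TRUE)[[1L]]
  ns <- length(s); nf <- length(f)
  if (ns >= nf) return(FALSE)
  for (off in 0:(nf - ns)) {
    if (identical(f[(off + 1L):(off + ns)], s)) return(TRUE)
  }
  FALSE
}

#' Classify query isoforms against a reference
#'
#' Five-way, strand-specific decision cascade per query transcript:
#' \describe{
#'   \item{FSM}{intron chain identical to a reference chain on the same
#'     contig and strand (terminal 5'/3' ends may differ by any amount).}
#'   \item{ISM}{intron chain is a contiguous subchain of a longer reference
#'     chain (fewer 5' or 3' exons, internal junctions matched).}
#'   \item{NIC}{no FSM/ISM match, overlaps a reference gene span, and every
#'     donor and acceptor it uses is annotated on that contig and strand
#'     (a novel combination of known sites).}
#'   \item{NNC}{as NIC but with at least one unannotated donor or acceptor.}
#'   \item{INTERGENIC}{overlaps no reference gene span (any strand).}
#' }
#' Mono-exonic queries are excluded unless `keep_mono = TRUE`.
#'
#' @param query,reference [annotation_set()] objects.
#' @param keep_mono keep mono-exonic query transcripts.
#' @return data.frame with `query_id`, `category`, `matched_reference_id`
#'   (NA for NIC/NNC/INTERGENIC).
#' @export
classify <- function(query, reference, keep_mono = FALSE) {
  if (!keep_mono) query <- filter_mono_exonic(query)
  qtx <- query$transcripts
  rtx <- reference$transcripts
  rchains <- located_chains(reference)
  spans <- gene_spans(reference)

  # Annotated donor/acceptor site sets per contig+strand.
  site_key <- function(contig, strand, pos) paste(contig, strand, pos)
  donors <- character(0L); acceptors <- character(0L)
  for (i in seq_len(nrow(rtx))) {
    if (rtx$n_exons[i] < 2L) next
    ex <- transcript_exons(reference, rtx$transcript_id[i])
    k <- nrow(ex)
    donors <- c(donors, site_key(rtx$contig[i], rtx$strand[i], ex$end[-k]))
    acceptors <- c(acceptors,
                   site_key(rtx$contig[i], rtx$strand[i], ex$start[-1L]))
  }
  donors <- unique(donors); acceptors <- unique(acceptors)

  out <- vector("list", nrow(qtx))
  for (i in seq_len(nrow(qtx))) {
    qid <- qtx$transcript_id[i]
    loc <- paste(qtx$contig[i], qtx$strand[i], qtx$chain[i], sep = "|")
    category <- NULL; ref_id <- NA_character_
    same_loc <- rtx$contig == qtx$contig[i] & rtx$strand == qtx$strand[i]
    if (qtx$chain[i] != "" && any(same_loc & rtx$chain == qtx$chain[i])) {
      category <- "FSM"
      ref_id <- min(rtx$transcript_id[same_loc & rtx$chain == qtx$chain[i]])
    } else if (qtx$chain[i] != "") {
      cand <- rtx$transcript_id[same_loc & rtx$n_exons > qtx$n_exons[i]]
      cand <- sort(cand)
      for (rid in cand) {
        if (is_contiguous_subchain(qtx$chain[i],
                                   rtx$chain[match(rid, rtx$transcript_id)])) {
          category <- "ISM"; ref_id <- rid; break
        }
      }
    }
    if (is.null(category)) {
      overlaps <- any(spans$contig == qtx$contig[i] &
                        spans$start < qtx$end[i] & spans$end > qtx$start[i])
      if (!overlaps) {
        category <- "INTERGENIC"
      } else {
        ex <- transcript_exons(query, qid)
        k <- nrow(ex)
        q_donors <- if (k >= 2L)
          site_key(qtx$contig[i], qtx$strand[i], ex$end[-k]) else character(0L)
        q_acceptors <- if (k >= 2L)
          site_key(qtx$contig[i], qtx$strand[i], ex$start[-1L]) else character(0L)
        known <- all(q_donors %in% donors) && all(q_acceptors %in% acceptors)
        category <- if (known) "NIC" else "NNC"
      }
    }
    out[[i]] <- data.frame(query_id = qid, category = category,
                           matched_reference_id = ref_id,
                           stringsAsFactors = FALSE)
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(query_id = character(), category = character(),
               matched_reference_id = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Base-pair Jaccard similarity of two isoform sets
#'
#' Each set's exons are merged per contig into a union of intervals
#' (strand-agnostic, the usual interval-overlap semantics of bp-resolution
#' interval tools); the Jaccard index is the intersection over the union of
#' total covered bases, 0 by convention when both sets are empty.
#'
#' @param a,b [annotation_set()] objects.
#' @return A list of class `similarity_result`: `jaccard`,
#'   `intersection_bp`, `union_bp`.
#' @export
jaccard_similarity <- function(a, b) {
  merged <- function(ann, contig) {
    ex <- ann$exons[ann$exons$contig == contig, , drop = FALSE]
    IRanges::reduce(IRanges::IRanges(start = ex$start + 1L, end = ex$end))
  }
  contigs <- union(unique(a$exons$contig), unique(b$exons$contig))
  inter_bp <- 0; union_bp <- 0
  for (ct in contigs) {
    ra <- merged(a, ct); rb <- merged(b, ct)
    inter_bp <- inter_bp + sum(IRanges::width(IRanges::intersect(ra, rb)))
    union_bp <- union_bp + sum(IRanges::width(IRanges::reduce(c(ra, rb))))
  }
  structure(list(jaccard = if (union_bp > 0) inter_bp / union_bp else 0,
                 intersection_bp = inter_bp, union_bp = union_bp),
            class = "similarity_result")
}

#' Provenance-based realized depth report
#'
#' Computes realized depths from a simulated FASTQ alignment-free: each
#' read is assigned to its origin isoform by parsing the provenance-carrying
#' read id, and `depth_i = sum(read lengths) / transcribed length`. Gene and
#' sample depths are arithmetic means over expressed isoforms (all isoforms
#' present in the ground truth are considered expressed unless a profile
#' with an `expressed` flag is supplied).
#'
#' @param fastq_path path to a FASTQ produced by [simulate_sample()].
#' @param gt a `ground_truth` or [annotation_set()].
#' @param profile optional `expression_profile` supplying expressed flags.
#' @return A list with `per_isoform` (data.frame `transcript_id`, `bases`,
#'   `length`, `depth`), `gene_depth`, `sample_depth` and `n_unparseable`.
#' @export
realized_depth_report <- function(fastq_path, gt, profile = NULL) {
  ann <- if (inherits(gt, "ground_truth")) gt$annotation else gt
  tx <- ann$transcripts
  reads <- Biostrings::readDNAStringSet(fastq_path, format = "fastq")
  prov <- parse_read_id(names(reads))
  bad <- is.na(prov$transcript_id)
  n_unparseable <- sum(bad)
  lens <- Biostrings::width(reads)[!bad]
  origin <- prov$transcript_id[!bad]
  bases <- vapply(split(lens, factor(origin, levels = tx$transcript_id)),
                  sum, numeric(1L))
  per <- data.frame(transcript_id = tx$transcript_id,
                    bases = as.numeric(bases),
                    length = tx$length,
                    depth = as.numeric(bases) / tx$length,
                    gene_id = tx$gene_id,
                    stringsAsFactors = FALSE)
  expressed <- rep(TRUE, nrow(per))
  if (!is.null(profile)) {
    m <- match(per$transcript_id, profile$transcript_id)
    expressed <- !is.na(m) & profile$expressed[m] == 1L
  }
  pe <- per[expressed, , drop = FALSE]
  gene_depth <- vapply(split(pe$depth, pe$gene_id), mean, numeric(1L))
  list(per_isoform = per[, c("transcript_id", "bases", "length", "depth")],
       gene_depth = gene_depth,
       sample_depth = if (nrow(pe) > 0L) mean(pe$depth) else 0,
       n_unparseable = n_unparseable)
}
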