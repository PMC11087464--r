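# Independent brute-force oracles for the evaluator, deliberately written
# with different data representations than the package (numeric junction
# vectors and per-base logical masks instead of string chain keys and
# IRanges set operations).

chain_key_of <- function(ex) {
  lrtsim:::chain_key(ex[order(ex$start), , drop = FALSE])
}

# Junctions of one transcript as an integer vector c(d1, a1, d2, a2, ...).
oracle_junctions <- function(ann, tid) {
  ex <- ann$exons[ann$exons$transcript_id == tid, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  k <- nrow(ex)
  if (k < 2L) return(integer(0L))
  as.integer(rbind(ex$end[-k], ex$start[-1L]))
}

oracle_tx_info <- function(ann) {
  tx <- ann$transcripts
  lapply(stats::setNames(tx$transcript_id, tx$transcript_id), function(tid) {
    i <- match(tid, tx$transcript_id)
    list(contig = tx$contig[i], strand = tx$strand[i],
         start = tx$start[i], end = tx$end[i], n_exons = tx$n_exons[i],
         junc = oracle_junctions(ann, tid))
  })
}

# All-pairs exact intron-chain matching with one-to-one assignment.
oracle_match <- function(query, reference, keep_mono = FALSE) {
  qi <- oracle_tx_info(query)
  ri <- oracle_tx_info(reference)
  if (!keep_mono) {
    qi <- Filter(function(t) t$n_exons >= 2L, qi)
    ri <- Filter(function(t) t$n_exons >= 2L, ri)
  }
  used <- rep(FALSE, length(ri))
  tp <- 0L
  for (q in qi) {
    for (j in seq_along(ri)) {
      r <- ri[[j]]
      if (!used[j] && q$contig == r$contig && q$strand == r$strand &&
          length(q$junc) == length(r$junc) && all(q$junc == r$junc)) {
        used[j] <- TRUE
        tp <- tp + 1L
        break
      }
    }
  }
  list(TP = tp, FP = length(qi) - tp, FN = length(ri) - tp)
}

# Independent five-way classification by explicit enumeration.
oracle_classify <- function(query, reference, keep_mono = FALSE) {
  qi <- oracle_tx_info(query)
  if (!keep_mono) qi <- Filter(function(t) t$n_exons >= 2L, qi)
  ri <- oracle_tx_info(reference)
  spans <- list()
  rtx <- reference$transcripts
  for (g in unique(rtx$gene_id)) {
    rows <- rtx[rtx$gene_id == g, , drop = FALSE]
    spans[[g]] <- list(contig = rows$contig[1L], start = min(rows$start),
                       end = max(rows$end))
  }
  site_tag <- function(t, pos) paste(t$contig, t$strand, pos)
  ref_donors <- unlist(lapply(ri, function(t)
    if (length(t$junc) > 0L) site_tag(t, t$junc[seq(1L, length(t$junc), 2L)])))
  ref_acceptors <- unlist(lapply(ri, function(t)
    if (length(t$junc) > 0L) site_tag(t, t$junc[seq(2L, length(t$junc), 2L)])))

  vapply(qi, function(q) {
    same <- Filter(function(r) r$contig == q$contig && r$strand == q$strand, ri)
    if (length(q$junc) > 0L) {
      for (r in same) {
        if (length(r$junc) == length(q$junc) && all(r$junc == q$junc))
          return("FSM")
      }
      nq <- length(q$junc)
      for (r in same) {
        nr <- length(r$junc)
        if (nr <= nq) next
        for (off in seq(0L, nr - nq, by = 2L)) {
          if (all(r$junc[(off + 1L):(off + nq)] == q$junc)) return("ISM")
        }
      }
    }
    hit <- any(vapply(spans, function(s)
      s$contig == q$contig && s$start < q$end && s$end > q$start, logical(1L)))
    if (!hit) return("INTERGENIC")
    if (length(q$junc) == 0L) return("NIC")
    qd <- site_tag(q, q$junc[seq(1L, length(q$junc), 2L)])
    qa <- site_tag(q, q$junc[seq(2L, length(q$junc), 2L)])
    if (all(qd %in% ref_donors) && all(qa %in% ref_acceptors)) "NIC" else "NNC"
  }, character(1L))
}

# Per-base counting Jaccard on logical masks.
oracle_jaccard <- function(a, b) {
  contigs <- union(unique(a$exons$contig), unique(b$exons$contig))
  inter <- 0L; un <- 0L
  for (ct in contigs) {
    ea <- a$exons[a$exons$contig == ct, , drop = FALSE]
    eb <- b$exons[b$exons$contig == ct, , drop = FALSE]
    L <- max(c(ea$end, eb$end, 1L))
    ma <- logical(L); mb <- logical(L)
    for (i in seq_len(nrow(ea))) ma[(ea$start[i] + 1L):ea$end[i]] <- TRUE
    for (i in seq_len(nrow(eb))) mb[(eb$start[i] + 1L):eb$end[i]] <- TRUE
    inter <- inter + sum(ma & mb)
    un <- un + sum(ma | mb)
  }
  if (un > 0L) inter / un else 0
}

# Random query/reference pair with a planted mix of relations: unchanged
# transcripts, terminal-trimmed copies, contiguous subchains, site
# recombinations, unannotated-site variants, and intergenic inventions.
random_eval_pair <- function(seed, n_query = 30L) {
  fx <- make_fixture(fixture_spec(n_genes = 8L, contig_length = 60000L,
                                  exons_per_transcript = c(2L, 6L),
                                  isoforms_per_gene = c(1L, 3L),
                                  seed = seed))
  ref <- fx$annotation
  set.seed(seed + 1L)
  ref_tx <- ref$transcripts
  rows <- list()
  for (i in seq_len(n_query)) {
    mode <- sample(c("copy", "trim", "sub", "shift", "invent"), 1L)
    tid <- sample(ref_tx$transcript_id, 1L)
    ex <- ref$exons[ref$exons$transcript_id == tid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    k <- nrow(ex)
    qid <- sprintf("q%03d", i)
    if (mode == "trim" && ex$end[1L] - ex$start[1L] > 10L) {
      ex$start[1L] <- ex$start[1L] + sample.int(9L, 1L)
    } else if (mode == "sub" && k >= 3L) {
      ex <- ex[2L:k, , drop = FALSE]  # drop the 5'-most exon: ISM candidate
    } else if (mode == "shift" && k >= 2L) {
      j <- sample.int(k - 1L, 1L)
      ex$end[j] <- ex$end[j] - sample.int(5L, 1L)  # unannotated donor
    } else if (mode == "invent") {
      gap_start <- max(ref$exons$end) + 1000L * i
      ex <- data.frame(transcript_id = qid, gene_id = paste0("qg", i),
                       contig = ex$contig[1L],
                       start = gap_start + c(0L, 200L),
                       end = gap_start + c(100L, 300L),
                       strand = ex$strand[1L], stringsAsFactors = FALSE)
    }
    ex$transcript_id <- qid
    ex$gene_id <- paste0("qg", i)
    rows[[qid]] <- ex
  }
  list(query = annotation_set(do.call(rbind, rows)), reference = ref)
}
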