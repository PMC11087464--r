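#' Configuration for novel alternative-splicing event generation
#'
#' @param complexity_index target transcriptome complexity; positively
#'   correlated with the realized mean number of isoforms per gene. Per-gene
#'   isoform targets are drawn as `1 + Poisson(complexity_index - 1)`.
#' @param event_weights named non-negative weights over the four event
#'   operators `ES` (exon skipping), `IR` (intron retention), `A5`
#'   (alternative donor site) and `A3` (alternative acceptor site); must sum
#'   to 1. The defaults put the largest mass on exon skipping, the most
#'   common event class in animals, and are fully user-overridable.
#' @param shift_range integer `c(min, max)` shift in bp for A5/A3 boundary
#'   moves; the default (3, 30) avoids sub-codon jitter while never erasing a
#'   whole exon.
#' @param max_attempts_per_isoform sampling attempts allowed per requested
#'   novel isoform before a gene is abandoned at its current count.
#' @param expressed_gene_fraction fraction of genes selected as expressed,
#'   in (0, 1].
#' @return A list of class `as_event_config`.
#' @export
as_event_config <- function(complexity_index = 2,
                            event_weights = c(ES = 0.4, IR = 0.2,
                                              A5 = 0.2, A3 = 0.2),
                            shift_range = c(3L, 30L),
                            max_attempts_per_isoform = 20L,
                            expressed_gene_fraction = 1.0) {
  if (!is.numeric(complexity_index) || complexity_index <= 0)
    stop2("complexity_index must be positive")
  if (!setequal(names(event_weights), c("ES", "IR", "A5", "A3")))
    stop2("event_weights must be named ES, IR, A5, A3")
  if (any(event_weights < 0) || abs(sum(event_weights) - 1) > 1e-9)
    stop2("event_weights must be non-negative and sum to 1")
  shift_range <- as.integer(shift_range)
  if (shift_range[1L] < 1L || shift_range[2L] < shift_range[1L])
    stop2("shift_range must satisfy 1 <= min <= max")
  if (!is_fraction(expressed_gene_fraction, 0, 1))
    stop2("expressed_gene_fraction must be in (0, 1]")
  structure(list(complexity_index = complexity_index,
                 event_weights = event_weights[c("ES", "IR", "A5", "A3")],
                 shift_range = shift_range,
                 max_attempts_per_isoform = as.integer(max_attempts_per_isoform),
                 expressed_gene_fraction = expressed_gene_fraction),
            class = "as_event_config")
}

#' Select the expressed gene set
#'
#' Retains `round(fraction * N_genes)` genes chosen uniformly at random,
#' with all their transcripts. Deterministic under `seed`.
#'
#' @param ann an [annotation_set()].
#' @param fraction fraction of genes to keep, in (0, 1].
#' @param seed integer seed.
#' @return A new [annotation_set()].
#' @export
select_expressed_genes <- function(ann, fraction = 1.0, seed = 0L) {
  if (!is_fraction(fraction, 0, 1)) stop2("fraction must be in (0, 1]")
  if (n_transcripts(ann) == 0L) stop2("annotation is empty")
  genes <- sort(unique(ann$transcripts$gene_id))
  n_keep <- as.integer(round_half_up(fraction * length(genes)))
  if (n_keep >= length(genes)) return(ann)
  keep_genes <- local({
    set.seed(derive_seed(seed, "select_expressed_genes"))
    sample(genes, n_keep)
  })
  keep_ids <- ann$transcripts$transcript_id[
    ann$transcripts$gene_id %in% keep_genes]
  subset_transcripts(ann, keep_ids)
}

#' Apply one alternative-splicing event to a transcript
#'
#' Operates on the exon rows of one transcript (0-based half-open, sorted by
#' start) and returns the modified exon rows, or `NULL` when the event has no
#' legal placement. Donor/acceptor are genomic: donor = upstream exon end,
#' acceptor = downstream exon start of an intron.
#'
#' * `ES` removes one uniformly chosen internal exon (needs >= 3 exons).
#' * `IR` merges one uniformly chosen adjacent exon pair, retaining the
#'   intervening intron (needs >= 2 exons).
#' * `A5` moves the donor of one intron by delta bp into the upstream exon
#'   (shrink) or into the intron (extend); `A3` does the symmetric move on
#'   the acceptor. The placement is drawn uniformly from the enumerated set
#'   of legal (intron, direction, delta) triples with delta in `shift_range`;
#'   moves that would empty an exon or cross a neighbouring boundary are
#'   never legal.
#'
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @param exons exon rows of a single transcript (as from
#'   [transcript_exons()]).
#' @param event one of `"ES"`, `"IR"`, `"A5"`, `"A3"`.
#' @param shift_range integer `c(min, max)` bp for A5/A3.
#' @return Modified exon rows, or `NULL` if no legal placement exists.
#' @export
apply_event <- function(exons, event, shift_range = c(3L, 30L)) {
  k <- nrow(exons)
  switch(event,
    ES = {
      if (k < 3L) return(NULL)
      drop_i <- if (k == 3L) 2L else sample(2L:(k - 1L), 1L)
      exons[-drop_i, , drop = FALSE]
    },
    IR = {
      if (k < 2L) return(NULL)
      i <- if (k == 2L) 1L else sample(seq_len(k - 1L), 1L)
      exons$end[i] <- exons$end[i + 1L]
      exons[-(i + 1L), , drop = FALSE]
    },
    A5 = shift_boundary(exons, shift_range, side = "donor"),
    A3 = shift_boundary(exons, shift_range, side = "acceptor"),
    stop2("unknown event code '%s'", event)
  )
}

# Enumerate legal (intron, direction, delta) placements for an alternative
# donor (A5) or acceptor (A3) move and sample one uniformly.
# For intron i (between exon i and exon i+1):
#   donor shrink  by d: end[i]   - d  legal while exon i keeps >= 1 bp
#   donor extend  by d: end[i]   + d  legal while the intron keeps >= 1 bp
#   acceptor shrink by d: start[i+1] + d (into the downstream exon)
#   acceptor extend by d: start[i+1] - d (into the intron)
shift_boundary <- function(exons, shift_range, side) {
  k <- nrow(exons)
  if (k < 2L) return(NULL)
  deltas <- seq.int(shift_range[1L], shift_range[2L])
  placements <- list()
  for (i in seq_len(k - 1L)) {
    exon_up <- exons$end[i] - exons$start[i]
    exon_dn <- exons$end[i + 1L] - exons$start[i + 1L]
    intron <- exons$start[i + 1L] - exons$end[i]
    if (side == "donor") {
      max_shrink <- min(shift_range[2L], exon_up - 1L)
      max_extend <- min(shift_range[2L], intron - 1L)
    } else {
      max_shrink <- min(shift_range[2L], exon_dn - 1L)
      max_extend <- min(shift_range[2L], intron - 1L)
    }
    for (d in deltas[deltas <= max_shrink])
      placements[[length(placements) + 1L]] <- c(i, -1L, d)
    for (d in deltas[deltas <= max_extend])
      placements[[length(placements) + 1L]] <- c(i, +1L, d)
  }
  if (length(placements) == 0L) return(NULL)
  p <- placements[[sample.int(length(placements), 1L)]]
  i <- p[1L]; dir <- p[2L]; d <- p[3L]
  if (side == "donor") {
    exons$end[i] <- exons$end[i] + dir * d
  } else {
    exons$start[i + 1L] <- exons$start[i + 1L] - dir * d
  }
  exons
}

#' Generate the ground-truth annotation with novel isoforms
#'
#' For each gene a target isoform count is drawn as
#' `1 + Poisson(complexity_index - 1)` (via quantile coupling on per-gene
#' uniforms, so realized counts are monotone in the complexity index at a
#' fixed seed), capped by what the event operators can reach within the
#' attempt budget. Novel isoforms are produced by repeatedly sampling a
#' parent isoform of the gene and an event type by `event_weights`; a
#' candidate is accepted only if its intron chain is new within the gene.
#'
#' @param ann an [annotation_set()] restricted to the expressed genes.
#' @param cfg an [as_event_config()].
#' @param seed integer seed.
#' @return A list of class `ground_truth` with elements `annotation` (an
#'   [annotation_set()] holding reference plus novel isoforms), `novel_ids`
#'   (character) and `provenance` (data.frame: `novel_id`, `parent_id`,
#'   `events`).
#' @export
generate_ground_truth <- function(ann, cfg = as_event_config(), seed = 0L) {
  if (!inherits(cfg, "as_event_config")) stop2("cfg must be an as_event_config")
  if (n_transcripts(ann) == 0L) stop2("annotation is empty")
  set.seed(derive_seed(seed, "generate_ground_truth"))
  genes <- sort(unique(ann$transcripts$gene_id))
  # Per-gene uniforms drawn first: the Poisson target is qpois(u, lambda),
  # monotone in lambda for fixed u, which guarantees the realized mean
  # isoforms/gene is non-decreasing in the complexity index at fixed seed.
  u <- stats::runif(length(genes))
  targets <- 1L + stats::qpois(u, max(cfg$complexity_index - 1, 0))

  exon_blocks <- list()
  novel_ids <- character(0L)
  prov <- list()
  for (gi in seq_along(genes)) {
    gid <- genes[gi]
    tx_ids <- ann$transcripts$transcript_id[ann$transcripts$gene_id == gid]
    pool <- lapply(tx_ids, function(tid) transcript_exons(ann, tid))
    names(pool) <- tx_ids
    chains <- vapply(pool, chain_key, character(1L))
    serial <- 0L
    attempts_left <- cfg$max_attempts_per_isoform *
      max(targets[gi] - length(pool), 0L)
    while (length(pool) < targets[gi] && attempts_left > 0L) {
      attempts_left <- attempts_left - 1L
      parent <- sample(names(pool), 1L)
      event <- sample(names(cfg$event_weights), 1L, prob = cfg$event_weights)
      cand <- apply_event(pool[[parent]], event, cfg$shift_range)
      if (is.null(cand)) next
      key <- chain_key(cand)
      if (key %in% chains) next
      serial <- serial + 1L
      parent_root <- sub("\\.as[0-9]+$", "", parent)
      novel_id <- sprintf("%s.as%d", parent_root, serial)
      while (novel_id %in% names(pool)) {
        serial <- serial + 1L
        novel_id <- sprintf("%s.as%d", parent_root, serial)
      }
      cand$transcript_id <- novel_id
      pool[[novel_id]] <- cand
      chains <- c(chains, key)
      novel_ids <- c(novel_ids, novel_id)
      prov[[novel_id]] <- data.frame(novel_id = novel_id, parent_id = parent,
                                     events = event, stringsAsFactors = FALSE)
    }
    exon_blocks[[gid]] <- do.call(rbind, pool)
  }
  provenance <- if (length(prov) > 0L) do.call(rbind, prov) else
    data.frame(novel_id = character(), parent_id = character(),
               events = character(), stringsAsFactors = FALSE)
  rownames(provenance) <- NULL
  structure(list(annotation = annotation_set(do.call(rbind, exon_blocks),
                                             ann$source_dialect),
                 novel_ids = novel_ids,
                 provenance = provenance),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d transcripts (%d novel) in %d genes\n",
              n_transcripts(x$annotation), length(x$novel_ids),
              n_genes(x$annotation)))
  invisible(x)
}

#' Write a provenance table for novel isoforms
#' @param gt a `ground_truth` object.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_provenance <- function(gt, path) {
  utils::write.table(gt$provenance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
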