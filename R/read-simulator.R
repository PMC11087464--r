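#' Read-simulation configuration
#'
#' @param accuracy_mean mean per-base accuracy in (0, 1]; the per-base error
#'   probability is `1 - accuracy`. Default 0.85 (a 15% error rate, typical
#'   of raw ONT long reads).
#' @param accuracy_sd sd of the per-read accuracy, drawn from a normal
#'   truncated to (0, 1]; default 0 (every read at `accuracy_mean`).
#' @param error_mix fractions `c(sub, ins, del)` partitioning the error
#'   probability; must sum to 1. Default 0.4/0.3/0.3, an indel-heavy
#'   ONT-like profile.
#' @param truncate_ratio_5p,truncate_ratio_3p fractions of each read removed
#'   from the 5' / 3' end of the mRNA-sense template; `r5 + r3 < 1`.
#' @param strand_symmetric when TRUE (cDNA-like) each read is independently
#'   reverse-complemented with probability 1/2, with the strand recorded in
#'   the read id; FALSE emulates direct-RNA reads (sense strand only).
#' @param seed integer seed.
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(accuracy_mean = 0.85, accuracy_sd = 0,
                            error_mix = c(sub = 0.4, ins = 0.3, del = 0.3),
                            truncate_ratio_5p = 0, truncate_ratio_3p = 0,
                            strand_symmetric = TRUE, seed = 0L) {
  if (!is_fraction(accuracy_mean, 0, 1)) stop2("accuracy_mean must be in (0, 1]")
  if (accuracy_sd < 0) stop2("accuracy_sd must be >= 0")
  if (length(error_mix) != 3L || any(error_mix < 0) ||
      abs(sum(error_mix) - 1) > 1e-9)
    stop2("error_mix must be three non-negative fractions summing to 1")
  if (!is_fraction(truncate_ratio_5p, 0, 1, open_lo = FALSE, open_hi = TRUE) ||
      !is_fraction(truncate_ratio_3p, 0, 1, open_lo = FALSE, open_hi = TRUE) ||
      truncate_ratio_5p + truncate_ratio_3p >= 1)
    stop2("truncation ratios must lie in [0, 1) with sum < 1")
  structure(list(accuracy_mean = accuracy_mean, accuracy_sd = accuracy_sd,
                 error_mix = stats::setNames(as.numeric(error_mix),
                                             c("sub", "ins", "del")),
                 truncate_ratio_5p = truncate_ratio_5p,
                 truncate_ratio_3p = truncate_ratio_3p,
                 strand_symmetric = isTRUE(strand_symmetric),
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Number of reads generated for an isoform
#'
#' Each full-length read contributes exactly 1x depth before truncation, so
#' the read count is the rounded target depth.
#'
#' @param depth target isoform depth (>= 0).
#' @return Integer read count.
#' @export
reads_per_isoform <- function(depth) {
  if (depth < 0) stop2("depth must be >= 0")
  as.integer(round_half_up(depth))
}

#' Clip a template from the 5' and/or 3' end
#'
#' Removes `floor(r5 * L)` bases from the 5' end and `floor(r3 * L)` from the
#' 3' end of the mRNA-sense template. If clipping would leave nothing, a
#' single base is kept and a warning raised.
#'
#' @param template mRNA-sense DNA string.
#' @param r5,r3 truncation fractions, `r5 + r3 < 1`.
#' @return List with `sequence` and `span` (0-based half-open offsets on the
#'   template).
#' @export
clip_template <- function(template, r5 = 0, r3 = 0) {
  L <- nchar(template)
  if (L == 0L) stop2("empty template")
  a <- floor(r5 * L)
  b <- floor(r3 * L)
  if (L - a - b < 1L) {
    warning("clipping would remove the whole read; keeping 1 base")
    a <- min(a, L - 1L)
    b <- L - a - 1L
  }
  list(sequence = substring(template, a + 1L, L - b),
       span = c(a, L - b))
}

phred_char <- function(accuracy) {
  q <- min(41L, as.integer(round(-10 * log10(max(1 - accuracy, 1e-5)))))
  intToUtf8(q + 33L)
}

#' Introduce sequencing errors into a template
#'
#' Each template base independently suffers an error with probability
#' `1 - accuracy`, partitioned by `error_mix` into substitution (a uniform
#' different base), insertion (the base followed by one uniform random base)
#' or deletion (the base is skipped). The quality string is flat at the
#' phred score implied by the accuracy, capped at Q41. Uses the current RNG
#' state.
#'
#' @param template DNA string.
#' @param accuracy per-base accuracy in (0, 1].
#' @param error_mix fractions `c(sub, ins, del)` summing to 1.
#' @return List with `sequence`, `quality` and `n_errors` (the number of
#'   edit events, i.e. the by-construction edit distance to the template).
#' @export
introduce_errors <- function(template, accuracy,
                             error_mix = c(sub = 0.4, ins = 0.3, del = 0.3)) {
  qc <- phred_char(accuracy)
  if (accuracy >= 1) {
    return(list(sequence = template,
                quality = strrep(qc, nchar(template)),
                n_errors = 0L))
  }
  e <- 1 - accuracy
  b <- strsplit(template, "", fixed = TRUE)[[1L]]
  n <- length(b)
  is_err <- stats::runif(n) < e
  n_err <- sum(is_err)
  etype <- integer(n)  # 0 none, 1 sub, 2 ins, 3 del
  if (n_err > 0L)
    etype[is_err] <- sample.int(3L, n_err, replace = TRUE, prob = error_mix)
  pool <- c("A", "C", "G", "T")
  sub_i <- which(etype == 1L)
  if (length(sub_i) > 0L) {
    old <- match(b[sub_i], pool)
    old[is.na(old)] <- 1L  # N: substitute with any uniform ACGT
    b[sub_i] <- pool[((old - 1L + sample.int(3L, length(sub_i),
                                             replace = TRUE)) %% 4L) + 1L]
  }
  counts <- rep(1L, n)
  counts[etype == 3L] <- 0L
  counts[etype == 2L] <- 2L
  out <- b[rep.int(seq_len(n), counts)]
  ins_i <- which(etype == 2L)
  if (length(ins_i) > 0L)
    out[cumsum(counts)[ins_i]] <- pool[sample.int(4L, length(ins_i),
                                                  replace = TRUE)]
  seq <- paste(out, collapse = "")
  list(sequence = seq, quality = strrep(qc, nchar(seq)), n_errors = n_err)
}

escape_id <- function(x) gsub(":", "%3A", x, fixed = TRUE)
unescape_id <- function(x) gsub("%3A", ":", x, fixed = TRUE)

#' Parse a simulated read id back to its provenance
#'
#' Read ids have the form `{transcript_id}:{serial}:{strand}` with colons in
#' the transcript id percent-encoded.
#'
#' @param ids character vector of read ids.
#' @return data.frame with `transcript_id`, `serial`, `strand`; unparseable
#'   ids yield NA rows.
#' @export
parse_read_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.*):([0-9]+):([+-])$", ids))
  bad <- vapply(m, length, integer(1L)) != 4L
  data.frame(
    transcript_id = ifelse(bad, NA_character_,
                           unescape_id(vapply(m, function(x)
                             if (length(x) == 4L) x[2L] else NA_character_,
                             character(1L)))),
    serial = ifelse(bad, NA_integer_,
                    as.integer(vapply(m, function(x)
                      if (length(x) == 4L) x[3L] else NA_character_,
                      character(1L)))),
    strand = ifelse(bad, NA_character_,
                    vapply(m, function(x)
                      if (length(x) == 4L) x[4L] else NA_character_,
                      character(1L))),
    stringsAsFactors = FALSE)
}

#' Simulate a full sample of long reads
#'
#' For every expressed isoform, `round(depth)` reads are generated: the
#' mRNA-sense template is clipped by the configured 5'/3' truncation
#' fractions, sequencing errors are introduced at the configured accuracy,
#' and (in strand-symmetric mode) the read is reverse-complemented with
#' probability 1/2. All reads are assembled into one FASTQ stream with
#' provenance-carrying read ids. Fully deterministic under the config seed.
#'
#' @param seqs named `DNAStringSet` of transcript sequences (from
#'   [transcribe()]).
#' @param profile an `expression_profile` covering the sequences.
#' @param cfg a [read_sim_config()].
#' @return A list of class `sim_sample`: `reads` (data.frame `read_id`,
#'   `sequence`, `quality`) and `stats` (list with `per_isoform` data.frame
#'   and `sample` summary including realized mean depth and realized
#'   per-base error rate).
#' @export
simulate_sample <- function(seqs, profile, cfg = read_sim_config()) {
  missing_seq <- setdiff(profile$transcript_id, names(seqs))
  if (length(missing_seq) > 0L)
    stop2("profile isoform(s) missing from sequences: %s",
          paste(utils::head(missing_seq, 5L), collapse = ", "))
  set.seed(derive_seed(cfg$seed, "simulate_sample"))
  prof <- profile[order(profile$transcript_id), , drop = FALSE]

  chunks <- vector("list", nrow(prof))
  per <- vector("list", nrow(prof))
  total_edits <- 0; total_template_bases <- 0
  for (i in seq_len(nrow(prof))) {
    tid <- prof$transcript_id[i]
    template_full <- as.character(seqs[[tid]])
    L <- nchar(template_full)
    n_reads <- if (prof$expressed[i] == 1L)
      reads_per_isoform(prof$depth[i]) else 0L
    bases <- 0
    if (n_reads > 0L) {
      clip <- clip_template(template_full, cfg$truncate_ratio_5p,
                            cfg$truncate_ratio_3p)
      tid_esc <- escape_id(tid)
      r_seq <- character(n_reads)
      r_qual <- character(n_reads)
      for (s in seq_len(n_reads)) {
        acc <- cfg$accuracy_mean
        if (cfg$accuracy_sd > 0) {
          repeat {
            acc <- stats::rnorm(1L, cfg$accuracy_mean, cfg$accuracy_sd)
            if (acc > 0 && acc <= 1) break
          }
        }
        er <- introduce_errors(clip$sequence, acc, cfg$error_mix)
        r_seq[s] <- er$sequence
        r_qual[s] <- er$quality
        total_edits <- total_edits + er$n_errors
        total_template_bases <- total_template_bases + nchar(clip$sequence)
      }
      strand <- rep("+", n_reads)
      if (cfg$strand_symmetric) {
        flip <- stats::runif(n_reads) < 0.5
        if (any(flip))
          r_seq[flip] <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(r_seq[flip])))
        strand[flip] <- "-"
      }
      bases <- sum(nchar(r_seq))
      chunks[[i]] <- list(
        id = sprintf("%s:%d:%s", tid_esc, seq_len(n_reads), strand),
        seq = r_seq, qual = r_qual)
    }
    per[[i]] <- data.frame(transcript_id = tid, n_reads = n_reads,
                           bases = bases, realized_depth = bases / L,
                           stringsAsFactors = FALSE)
  }
  chunks <- chunks[!vapply(chunks, is.null, logical(1L))]
  ids <- unlist(lapply(chunks, `[[`, "id"), use.names = FALSE) %||% character(0L)
  rseq <- unlist(lapply(chunks, `[[`, "seq"), use.names = FALSE) %||% character(0L)
  rqual <- unlist(lapply(chunks, `[[`, "qual"), use.names = FALSE) %||% character(0L)
  per_isoform <- do.call(rbind, per)
  rownames(per_isoform) <- NULL
  expressed <- prof$expressed == 1L
  sample_stats <- list(
    total_reads = sum(per_isoform$n_reads),
    total_bases = sum(per_isoform$bases),
    realized_mean_depth = if (any(expressed))
      mean(per_isoform$realized_depth[expressed]) else 0,
    realized_error_rate = if (total_template_bases > 0)
      total_edits / total_template_bases else 0
  )
  structure(list(reads = data.frame(read_id = ids, sequence = rseq,
                                    quality = rqual,
                                    stringsAsFactors = FALSE),
                 stats = list(per_isoform = per_isoform,
                              sample = sample_stats)),
            class = "sim_sample")
}

#' Write simulated reads as FASTQ (phred+33)
#'
#' @param sample a `sim_sample` (or its `reads` data.frame).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(sample, path) {
  reads <- if (inherits(sample, "sim_sample")) sample$reads else sample
  n <- nrow(reads)
  lines <- character(4L * n)
  if (n > 0L) {
    lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", reads$read_id)
    lines[seq(2L, by = 4L, length.out = n)] <- reads$sequence
    lines[seq(3L, by = 4L, length.out = n)] <- "+"
    lines[seq(4L, by = 4L, length.out = n)] <- reads$quality
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write per-isoform simulation statistics as TSV
#' @param sample a `sim_sample`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sim_stats <- function(sample, path) {
  df <- sample$stats$per_isoform
  df$realized_depth <- sprintf("%.6f", df$realized_depth)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
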