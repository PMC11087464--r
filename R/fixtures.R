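#' Specification for a synthetic toy genome and annotation
#'
#' The fixture generator builds small genomes with known gene structure so
#' that the whole simulate-and-evaluate pipeline can run without any
#' external data. Genes are placed left to right on each contig with at
#' least 500 bp of intergenic spacing (so intergenic regions always exist),
#' alternate between the + and - strand by index, and each gene's isoforms
#' share a common exon scaffold with random terminal variation.
#'
#' @param n_contigs number of contigs.
#' @param contig_length contig length in bp.
#' @param n_genes total number of genes, distributed round-robin over
#'   contigs.
#' @param exons_per_transcript integer `c(min, max)` exons per scaffold.
#' @param exon_length integer `c(min, max)` exon length in bp.
#' @param intron_length integer `c(min, max)` intron length in bp.
#' @param isoforms_per_gene integer `c(min, max)` isoforms per gene.
#' @param gc_bias genome GC fraction for i.i.d. bases.
#' @param seed integer seed.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_contigs = 1L, contig_length = 100000L,
                         n_genes = 10L, exons_per_transcript = c(2L, 5L),
                         exon_length = c(80L, 300L),
                         intron_length = c(60L, 400L),
                         isoforms_per_gene = c(1L, 3L),
                         gc_bias = 0.5, seed = 0L) {
  rng_ok <- function(r) length(r) == 2L && r[1L] >= 1L && r[1L] <= r[2L]
  if (!rng_ok(exons_per_transcript) || !rng_ok(exon_length) ||
      !rng_ok(intron_length) || !rng_ok(isoforms_per_gene))
    stop2("all ranges must satisfy 1 <= min <= max")
  if (!is_fraction(gc_bias, 0, 1, open_lo = FALSE))
    stop2("gc_bias must be in [0, 1]")
  structure(list(n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 n_genes = as.integer(n_genes),
                 exons_per_transcript = as.integer(exons_per_transcript),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 gc_bias = gc_bias, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a toy genome and annotation
#'
#' @param spec a [fixture_spec()].
#' @return A list with `genome` (`DNAStringSet`) and `annotation`
#'   ([annotation_set()]); deterministic under the spec seed.
#' @export
make_fixture <- function(spec = fixture_spec()) {
  set.seed(derive_seed(spec$seed, "make_fixture"))
  gap <- 500L
  max_gene_len <- spec$exons_per_transcript[2L] * spec$exon_length[2L] +
    (spec$exons_per_transcript[2L] - 1L) * spec$intron_length[2L]
  genes_per_contig <- ceiling(spec$n_genes / spec$n_contigs)
  required <- gap + genes_per_contig * (max_gene_len + gap)
  if (required > spec$contig_length)
    stop2("genes do not fit: need contig_length >= %d", required)

  pool <- c("A", "C", "G", "T")
  pbase <- c((1 - spec$gc_bias) / 2, spec$gc_bias / 2,
             spec$gc_bias / 2, (1 - spec$gc_bias) / 2)
  contigs <- vapply(seq_len(spec$n_contigs), function(i) {
    paste(sample(pool, spec$contig_length, replace = TRUE, prob = pbase),
          collapse = "")
  }, character(1L))
  genome <- Biostrings::DNAStringSet(contigs)
  names(genome) <- sprintf("chr%d", seq_len(spec$n_contigs))

  cursor <- rep(gap, spec$n_contigs)
  exon_rows <- list()
  for (g in seq_len(spec$n_genes)) {
    ci <- ((g - 1L) %% spec$n_contigs) + 1L
    contig <- names(genome)[ci]
    strand <- if (g %% 2L == 1L) "+" else "-"
    gid <- sprintf("gene%03d", g)
    n_ex <- sample(spec$exons_per_transcript[1L]:spec$exons_per_transcript[2L], 1L)
    ex_len <- sample(spec$exon_length[1L]:spec$exon_length[2L], n_ex,
                     replace = TRUE)
    in_len <- if (n_ex > 1L)
      sample(spec$intron_length[1L]:spec$intron_length[2L], n_ex - 1L,
             replace = TRUE) else integer(0L)
    starts <- cursor[ci] + cumsum(c(0L, ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    cursor[ci] <- ends[n_ex] + gap
    n_iso <- sample(spec$isoforms_per_gene[1L]:spec$isoforms_per_gene[2L], 1L)
    # Isoform t uses the t-th exon window of the scaffold: the full chain
    # first, then progressively trimmed 5'/3' terminal exons, at most one
    # mono-exonic isoform. Distinct windows give distinct intron chains.
    windows <- list(c(1L, n_ex))
    for (d in seq_len(max(n_ex - 2L, 0L))) {
      for (i in 0:d) {
        w <- c(1L + i, n_ex - (d - i))
        if (w[2L] - w[1L] >= 1L) windows[[length(windows) + 1L]] <- w
      }
    }
    windows[[length(windows) + 1L]] <- c(1L, 1L)
    n_iso <- min(n_iso, length(windows))
    for (t in seq_len(n_iso)) {
      tid <- sprintf("%s.t%d", gid, t)
      w <- windows[[t]]
      s <- starts[w[1L]:w[2L]]
      e <- ends[w[1L]:w[2L]]
      k <- length(s)
      if (t > 1L) {
        # additionally jitter the outer ends of the terminal exons, which
        # never touches a splice boundary
        first_len <- e[1L] - s[1L]
        last_len <- e[k] - s[k]
        if (first_len > 21L)
          s[1L] <- s[1L] + sample.int(20L, 1L)
        if (k > 1L && last_len > 21L)
          e[k] <- e[k] - sample.int(20L, 1L)
      }
      exon_rows[[tid]] <- data.frame(
        transcript_id = tid, gene_id = gid, contig = contig,
        start = s, end = e, strand = strand, stringsAsFactors = FALSE)
    }
  }
  annotation <- annotation_set(do.call(rbind, exon_rows))
  list(genome = genome, annotation = annotation)
}

#' Write a fixture's FASTA and GTF to disk
#' @param fixture a list from [make_fixture()].
#' @param fasta_path,gtf_path output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_fixture <- function(fixture, fasta_path, gtf_path) {
  Biostrings::writeXStringSet(fixture$genome, fasta_path)
  write_gtf(fixture$annotation, gtf_path)
  invisible(c(fasta_path, gtf_path))
}
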