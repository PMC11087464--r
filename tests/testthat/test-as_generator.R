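# A three-exon transcript used across the event-operator tests:
# exons [0,100), [200,300), [400,500) on the + strand.
three_exon_tx <- function() {
  data.frame(transcript_id = "t1", gene_id = "g1", contig = "chr1",
             start = c(0L, 200L, 400L), end = c(100L, 300L, 500L),
             strand = "+", stringsAsFactors = FALSE)
}

test_that("exon skipping removes an internal exon", {
  set.seed(1)
  out <- apply_event(three_exon_tx(), "ES")
  expect_equal(nrow(out), 2L)
  expect_equal(chain_key_of(out), "100-400")
  # needs at least three exons
  expect_null(apply_event(three_exon_tx()[1:2, ], "ES"))
})

test_that("intron retention merges adjacent exons", {
  two <- three_exon_tx()[1:2, ]
  set.seed(1)
  out <- apply_event(two, "IR")
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 0L)
  expect_equal(out$end, 300L)
  expect_null(apply_event(two[1, , drop = FALSE], "IR"))
})

test_that("A5/A3 boundary moves land in the enumerated legal placement set", {
  two <- three_exon_tx()[1:2, ]  # exons [0,100), [200,300); intron [100,200)
  rng <- c(3L, 30L)
  legal_donors <- c(100L - rng[1L]:min(rng[2L], 99L),       # shrink
                    100L + rng[1L]:min(rng[2L], 99L))       # extend
  legal_acceptors <- c(200L + rng[1L]:min(rng[2L], 99L),
                       200L - rng[1L]:min(rng[2L], 99L))
  set.seed(7)
  for (i in 1:50) {
    d <- apply_event(two, "A5", rng)
    expect_true(d$end[1L] %in% legal_donors)
    expect_equal(d$start[2L], 200L)
    a <- apply_event(two, "A3", rng)
    expect_true(a$start[2L] %in% legal_acceptors)
    expect_equal(a$end[1L], 100L)
  }
  # a delta of 10 shrinking the donor is one of the legal outcomes
  expect_true((100L - 10L) %in% legal_donors)
  # no legal placement on a pair of 1 bp exons separated by a 1 bp intron
  tiny <- data.frame(transcript_id = "t", gene_id = "g", contig = "c",
                     start = c(0L, 2L), end = c(1L, 3L), strand = "+")
  expect_null(apply_event(tiny, "A5", rng))
  expect_error(apply_event(two, "XX"), "unknown event")
})

test_that("expressed-gene selection is an exact, seeded subset", {
  fx <- make_fixture(fixture_spec(n_genes = 10L, seed = 2L))
  ann <- fx$annotation
  expect_identical(select_expressed_genes(ann, 1.0, seed = 1L), ann)
  half <- select_expressed_genes(ann, 0.5, seed = 1L)
  expect_equal(n_genes(half), 5L)
  expect_identical(select_expressed_genes(ann, 0.5, seed = 1L)$exons,
                   half$exons)
  expect_error(select_expressed_genes(ann, 0), "fraction")
  # all transcripts of a selected gene are retained
  g <- half$transcripts$gene_id[1L]
  expect_setequal(half$transcripts$transcript_id[half$transcripts$gene_id == g],
                  ann$transcripts$transcript_id[ann$transcripts$gene_id == g])
})

test_that("complexity 1 on single-isoform genes yields no novel isoforms", {
  fx <- make_fixture(fixture_spec(n_genes = 8L, isoforms_per_gene = c(1L, 1L),
                                  seed = 3L))
  gt <- generate_ground_truth(fx$annotation,
                              as_event_config(complexity_index = 1), seed = 1L)
  expect_length(gt$novel_ids, 0L)
  expect_identical(gt$annotation$exons, fx$annotation$exons)
})

test_that("novel intron chains are unique within each gene and legal", {
  fx <- make_fixture(fixture_spec(n_genes = 15L, contig_length = 200000L,
                                  seed = 4L))
  gt <- generate_ground_truth(fx$annotation,
                              as_event_config(complexity_index = 5), seed = 9L)
  expect_gt(length(gt$novel_ids), 0L)
  tx <- gt$annotation$transcripts
  for (g in unique(tx$gene_id)) {
    chains <- paste(tx$contig, tx$strand, tx$chain)[tx$gene_id == g]
    expect_equal(anyDuplicated(chains), 0L)
  }
  # provenance covers every novel isoform and points at real parents
  expect_setequal(gt$provenance$novel_id, gt$novel_ids)
  expect_true(all(gt$provenance$parent_id %in% tx$transcript_id))
  # all transcripts pass model validation and stay within the contig
  expect_silent(lrtsim:::validate_annotation(gt$annotation))
  expect_true(all(gt$annotation$exons$end <=
                    Biostrings::width(fx$genome)[1L]))
})

test_that("realized isoforms per gene grow monotonically with complexity", {
  fx <- make_fixture(fixture_spec(n_genes = 20L, contig_length = 200000L,
                                  exons_per_transcript = c(3L, 6L), seed = 6L))
  means <- vapply(c(1, 3, 5, 7, 9), function(cx) {
    gt <- generate_ground_truth(fx$annotation,
                                as_event_config(complexity_index = cx),
                                seed = 17L)
    n_transcripts(gt$annotation) / n_genes(gt$annotation)
  }, numeric(1L))
  expect_true(all(diff(means) >= 0))
  expect_gt(means[5L], means[1L])
})

test_that("ground-truth generation is byte-deterministic under seed", {
  fx <- make_fixture(fixture_spec(n_genes = 10L, seed = 8L))
  cfg <- as_event_config(complexity_index = 4)
  p1 <- withr::local_tempfile(fileext = ".gtf")
  p2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(generate_ground_truth(fx$annotation, cfg, seed = 3L)$annotation, p1)
  write_gtf(generate_ground_truth(fx$annotation, cfg, seed = 3L)$annotation, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("event-config validation enforces weight and shift invariants", {
  expect_error(as_event_config(event_weights = c(ES = 0.5, IR = 0.5,
                                                 A5 = 0.2, A3 = 0.2)),
               "sum to 1")
  expect_error(as_event_config(shift_range = c(0L, 5L)), "shift_range")
  expect_error(as_event_config(complexity_index = -1), "positive")
})
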