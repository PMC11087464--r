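ann_from <- function(...) {
  # each argument: list(tid, gid, starts, ends, strand = "+", contig = "c1")
  rows <- lapply(list(...), function(t) {
    data.frame(transcript_id = t[[1L]], gene_id = t[[2L]], contig = t$contig %||% "c1",
               start = as.integer(t[[3L]]), end = as.integer(t[[4L]]),
               strand = t$strand %||% "+", stringsAsFactors = FALSE)
  })
  annotation_set(do.call(rbind, rows))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("mono-exonic transcripts are excluded before matching", {
  ann <- ann_from(list("m1", "g1", 0, 100),
                  list("m2", "g2", 500, 700),
                  list("t1", "g3", c(1000, 1200), c(1100, 1300)),
                  list("t2", "g4", c(2000, 2200), c(2100, 2300)),
                  list("t3", "g5", c(3000, 3200), c(3100, 3300)))
  f <- filter_mono_exonic(ann)
  expect_equal(n_transcripts(f), 3L)
  expect_false(any(c("m1", "m2") %in% f$transcripts$transcript_id))
  expect_false("g1" %in% f$transcripts$gene_id)
  # all-multi-exonic input is untouched
  expect_identical(filter_mono_exonic(f)$exons, f$exons)
})

test_that("self-comparison yields perfect precision and sensitivity", {
  fx <- make_fixture(fixture_spec(n_genes = 10L, seed = 60L))
  res <- match_exact(fx$annotation, fx$annotation)
  expect_equal(res$FP, 0L)
  expect_equal(res$FN, 0L)
  expect_equal(res$precision, 1)
  expect_equal(res$sensitivity, 1)
})

test_that("TP/FP/FN follow the printed formulas on a constructed case", {
  # reference: 5 multi-exonic transcripts; query: 3 exact chains + 1 novel
  ref <- ann_from(list("r1", "g1", c(0, 200), c(100, 300)),
                  list("r2", "g2", c(1000, 1200), c(1100, 1300)),
                  list("r3", "g3", c(2000, 2200), c(2100, 2300)),
                  list("r4", "g4", c(3000, 3200), c(3100, 3300)),
                  list("r5", "g5", c(4000, 4200), c(4100, 4300)))
  qry <- ann_from(list("q1", "g1", c(10, 200), c(100, 290)),
                  list("q2", "g2", c(1000, 1200), c(1100, 1300)),
                  list("q3", "g3", c(2000, 2200), c(2100, 2300)),
                  list("q4", "gx", c(5000, 5200), c(5100, 5300)))
  res <- match_exact(qry, ref)
  expect_equal(res$TP, 3L)
  expect_equal(res$FP, 1L)
  expect_equal(res$FN, 2L)
  expect_equal(res$precision, 0.75)
  expect_equal(res$sensitivity, 0.6)
  expect_equal(res$matches$query_id, c("q1", "q2", "q3"))
})

test_that("matching is strand- and contig-specific", {
  ref <- ann_from(list("r1", "g1", c(0, 200), c(100, 300)))
  qry_strand <- ann_from(list("q1", "g1", c(0, 200), c(100, 300),
                              strand = "-"))
  expect_equal(match_exact(qry_strand, ref)$TP, 0L)
  qry_contig <- ann_from(list("q1", "g1", c(0, 200), c(100, 300),
                              contig = "c2"))
  expect_equal(suppressWarnings(match_exact(qry_contig, ref))$TP, 0L)
  expect_warning(match_exact(qry_contig, ref), "absent")
})

test_that("classification follows the FSM/ISM/NIC/NNC/intergenic cascade", {
  ref <- ann_from(list("r1", "g1", c(100, 200), c(150, 300)),
                  list("r2", "g2", c(1000, 1200, 1400), c(1100, 1300, 1500)))
  # FSM: same chain, terminal ends shifted by 50
  q_fsm <- ann_from(list("q1", "q", c(50, 200), c(150, 350)))
  expect_equal(classify(q_fsm, ref)$category, "FSM")
  # ISM: contiguous subchain of r2's two-intron chain
  q_ism <- ann_from(list("q2", "q", c(1000, 1200), c(1100, 1250)))
  expect_equal(classify(q_ism, ref)$category, "ISM")
  # NIC: known donor from r2 intron 1 + known acceptor from r2 intron 2
  q_nic <- ann_from(list("q3", "q", c(1000, 1400), c(1100, 1500)))
  expect_equal(classify(q_nic, ref)$category, "NIC")
  # NNC: one never-annotated acceptor
  q_nnc <- ann_from(list("q4", "q", c(1000, 1401), c(1100, 1500)))
  expect_equal(classify(q_nnc, ref)$category, "NNC")
  # INTERGENIC: no gene-span overlap
  q_int <- ann_from(list("q5", "q", c(9000, 9200), c(9100, 9300)))
  expect_equal(classify(q_int, ref)$category, "INTERGENIC")
  # antisense overlap is not FSM under strand-specific matching
  q_anti <- ann_from(list("q6", "q", c(100, 200), c(150, 300), strand = "-"))
  expect_equal(classify(q_anti, ref)$category, "NNC")
})

test_that("internal exon-skipping subsets are not ISM", {
  ref <- ann_from(list("r1", "g1", c(0, 200, 400, 600), c(100, 300, 500, 700)))
  # skips the exon at [200,300): junctions are known sites recombined
  q <- ann_from(list("q1", "q", c(0, 400, 600), c(100, 500, 700)))
  cls <- classify(q, ref)
  expect_equal(cls$category, "NIC")
})

test_that("Jaccard matches interval arithmetic and is symmetric", {
  a <- ann_from(list("a1", "g1", 0, 100))
  b <- ann_from(list("b1", "g1", 50, 150))
  ja <- jaccard_similarity(a, b)
  expect_equal(ja$jaccard, 50 / 150)
  expect_equal(ja$intersection_bp, 50L)
  expect_equal(ja$union_bp, 150L)
  expect_equal(jaccard_similarity(b, a)$jaccard, ja$jaccard)
  expect_equal(jaccard_similarity(a, a)$jaccard, 1)
  disjoint <- ann_from(list("c1", "g1", 500, 600))
  expect_equal(jaccard_similarity(a, disjoint)$jaccard, 0)
})

test_that("evaluator agrees with brute-force oracles on random fixtures", {
  for (seed in 1:12) {
    pair <- random_eval_pair(seed)
    res <- match_exact(pair$query, pair$reference)
    orc <- oracle_match(pair$query, pair$reference)
    expect_equal(res$TP, orc$TP)
    expect_equal(res$FP, orc$FP)
    expect_equal(res$FN, orc$FN)

    cls <- classify(pair$query, pair$reference)
    orc_cls <- oracle_classify(pair$query, pair$reference)
    expect_equal(stats::setNames(cls$category, cls$query_id),
                 orc_cls[cls$query_id])
    # totality and exclusivity: one category per evaluated transcript
    expect_equal(sort(cls$query_id),
                 sort(filter_mono_exonic(pair$query)$transcripts$transcript_id))

    expect_equal(jaccard_similarity(pair$query, pair$reference)$jaccard,
                 oracle_jaccard(pair$query, pair$reference))
  }
})

test_that("provenance-based depth report recovers emitted depths", {
  seqs <- Biostrings::DNAStringSet(c(t1 = strrep("ACGT", 250L),
                                     t2 = strrep("GGCA", 250L)))
  prof <- data.frame(transcript_id = c("t1", "t2"), gene_id = "g1",
                     depth = c(640 / 17, 40 / 17), expressed = 1L)
  sim <- simulate_sample(seqs, prof,
                         read_sim_config(accuracy_mean = 1,
                                         strand_symmetric = FALSE, seed = 1L))
  fq <- withr::local_tempfile(fileext = ".fq")
  write_fastq(sim, fq)
  # both isoforms have transcribed length 1000, matching the sequences
  ann <- ann_from(list("t1", "g1", 0, 1000),
                  list("t2", "g1", 0, 1000))
  rep <- realized_depth_report(fq, ann)
  expect_equal(rep$per_isoform$depth,
               c(reads_per_isoform(640 / 17), reads_per_isoform(40 / 17)))
  # gene depth = mean of isoform depths; the Zipf pair (640/17, 40/17)
  # averages 20, and (38 + 2) / 2 recovers it exactly after read rounding
  expect_equal(unname(rep$gene_depth[["g1"]]), 20)
  expect_equal(rep$n_unparseable, 0L)
})

test_that("an empty FASTQ yields all-zero depths", {
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(character(0L), fq)
  ann <- ann_from(list("t1", "g1", c(0, 2000), c(1000, 3000)))
  rep <- realized_depth_report(fq, ann)
  expect_equal(rep$per_isoform$depth, 0)
  expect_equal(rep$sample_depth, 0)
})
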