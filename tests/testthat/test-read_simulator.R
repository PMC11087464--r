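test_that("read counts follow the rounded target depth", {
  expect_equal(reads_per_isoform(20), 20L)
  expect_equal(reads_per_isoform(0.4), 0L)
  expect_equal(reads_per_isoform(0), 0L)
  expect_error(reads_per_isoform(-1), "depth")
})

test_that("template clipping removes floor(r * L) bases from each end", {
  tpl <- strrep("A", 1000L)
  c1 <- clip_template(tpl, 0.2, 0)
  expect_equal(c1$span, c(200L, 1000L))
  expect_equal(nchar(c1$sequence), 800L)

  expect_equal(clip_template(tpl, 0, 0)$sequence, tpl)

  c3 <- clip_template(tpl, 0.2, 0.2)
  expect_equal(nchar(c3$sequence), 600L)

  # degenerate input (ratios summing past 1) floors at one base and warns
  expect_warning(out <- clip_template("ACGT", 0.8, 0.3), "1 base")
  expect_equal(nchar(out$sequence), 1L)
})

test_that("perfect accuracy reproduces the template at capped quality", {
  set.seed(1)
  tpl <- paste(sample(c("A", "C", "G", "T"), 500L, replace = TRUE),
               collapse = "")
  out <- introduce_errors(tpl, 1.0)
  expect_identical(out$sequence, tpl)
  expect_equal(out$n_errors, 0L)
  expect_equal(unique(strsplit(out$quality, "")[[1L]]),
               intToUtf8(41L + 33L))  # Q41 cap
  expect_equal(nchar(out$quality), nchar(out$sequence))
})

test_that("realized error rate tracks 1 - accuracy", {
  set.seed(2)
  tpl <- paste(sample(c("A", "C", "G", "T"), 200000L, replace = TRUE),
               collapse = "")
  out <- introduce_errors(tpl, 0.85)
  rate <- out$n_errors / nchar(tpl)
  expect_lt(abs(rate - 0.15), 0.005)
})

test_that("a deletion-only error mix shortens reads binomially", {
  set.seed(3)
  tpl <- paste(sample(c("A", "C", "G", "T"), 1000L, replace = TRUE),
               collapse = "")
  mix <- c(sub = 0, ins = 0, del = 1)
  lens <- vapply(1:30, function(i)
    nchar(introduce_errors(tpl, 0.9, mix)$sequence), numeric(1L))
  sigma <- sqrt(1000 * 0.9 * 0.1)
  expect_true(all(abs(lens - 900) <= 3 * sigma))
})

test_that("read ids carry recoverable provenance, with colon escaping", {
  ids <- c("tx1:3:+", "weird%3Aid:12:-")
  p <- parse_read_id(ids)
  expect_equal(p$transcript_id, c("tx1", "weird:id"))
  expect_equal(p$serial, c(3L, 12L))
  expect_equal(p$strand, c("+", "-"))
  expect_true(is.na(parse_read_id("garbage")$transcript_id))
})

test_that("error-free untruncated simulation conserves depth exactly", {
  seqs <- Biostrings::DNAStringSet(c(t1 = strrep("ACGT", 250L)))
  prof <- data.frame(transcript_id = "t1", gene_id = "g1", depth = 3,
                     expressed = 1L)
  sim <- simulate_sample(seqs, prof,
                         read_sim_config(accuracy_mean = 1,
                                         strand_symmetric = FALSE, seed = 1L))
  expect_equal(nrow(sim$reads), 3L)
  expect_true(all(sim$reads$sequence == as.character(seqs[["t1"]])))
  expect_equal(sim$stats$per_isoform$realized_depth, 3)
})

test_that("truncation scales realized depth by 1 - r5 - r3", {
  seqs <- Biostrings::DNAStringSet(c(t1 = strrep("ACGT", 250L)))
  prof <- data.frame(transcript_id = "t1", gene_id = "g1", depth = 10,
                     expressed = 1L)
  sim <- simulate_sample(seqs, prof,
                         read_sim_config(accuracy_mean = 1,
                                         truncate_ratio_5p = 0.2,
                                         truncate_ratio_3p = 0.2,
                                         strand_symmetric = FALSE, seed = 1L))
  expect_true(all(nchar(sim$reads$sequence) == 600L))
  expect_equal(sim$stats$per_isoform$realized_depth, 10 * 0.6)
})

test_that("strand-symmetric mode emits both orientations, recorded in ids", {
  seqs <- Biostrings::DNAStringSet(c(t1 = strrep("ACGGT", 100L)))
  prof <- data.frame(transcript_id = "t1", gene_id = "g1", depth = 40,
                     expressed = 1L)
  sim <- simulate_sample(seqs, prof,
                         read_sim_config(accuracy_mean = 1, seed = 5L))
  p <- parse_read_id(sim$reads$read_id)
  expect_setequal(unique(p$strand), c("+", "-"))
  minus <- which(p$strand == "-")[1L]
  expect_equal(sim$reads$sequence[minus],
               as.character(Biostrings::reverseComplement(seqs[["t1"]])))
})

test_that("FASTQ output is deterministic under seed and parseable", {
  fx <- make_fixture(fixture_spec(n_genes = 5L, seed = 50L))
  seqs <- transcribe(fx$annotation, fx$genome)
  prof <- build_profile(fx$annotation, depth_config(mu = 5, seed = 2L))
  cfg <- read_sim_config(accuracy_mean = 0.9, seed = 6L)
  s1 <- simulate_sample(seqs, prof, cfg)
  s2 <- simulate_sample(seqs, prof, cfg)
  p1 <- withr::local_tempfile(fileext = ".fq")
  p2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq(s1, p1)
  write_fastq(s2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # provenance completeness: every read id parses to a known isoform and
  # per-isoform counts in the stats equal counts recovered from the FASTQ
  ids <- parse_read_id(s1$reads$read_id)
  expect_true(all(ids$transcript_id %in% names(seqs)))
  counts <- table(ids$transcript_id)
  st <- s1$stats$per_isoform
  for (tid in names(counts))
    expect_equal(st$n_reads[st$transcript_id == tid],
                 as.integer(counts[[tid]]))
  expect_error(simulate_sample(seqs[1:2],
                               prof, cfg), "missing from sequences")
})
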