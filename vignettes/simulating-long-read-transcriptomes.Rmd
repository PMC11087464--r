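---
title: "Simulating and benchmarking long-read RNA-seq isoform detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and benchmarking long-read RNA-seq isoform detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrtsim)
```

## The problem

Isoform-detection tools reconstruct transcript structures from spliced
long-read RNA-seq alignments. Benchmarking them needs datasets where the
truth is known: which isoforms exist, including *novel* ones absent from the
reference annotation, at what expression level, and with what read quality.
`lrtsim` provides that as a two-level simulator — a gene-model level that
invents novel alternative-splicing (AS) isoforms, and a read level that
turns their cDNA into error-containing FASTQ — plus an evaluator that scores
any isoform GTF against the ground truth the simulator emits.

All coordinates are 0-based half-open internally; GTF I/O converts to and
from the 1-based inclusive convention at the file boundary.

## Ground-truth generation

Starting from a reference annotation (optionally degraded to a chosen
completeness with `sample_transcripts()`, which keeps exactly
`round(percent * N)` transcripts unchanged), a fraction of genes is selected
as expressed and novel isoforms are generated per gene by four event
operators on the exon chain:

* **ES** — skip one internal exon;
* **IR** — retain the intron between one adjacent exon pair (merging them);
* **A5 / A3** — move one donor (or acceptor) splice site by a shift of
  3–30 bp into the flanking exon or intron.

Default event weights are ES 0.4, IR 0.2, A5 0.2, A3 0.2 — exon skipping is
the most common event class in animals — and are fully user-overridable in
`as_event_config()`. For A5/A3 the set of legal (intron, direction, shift)
placements is enumerated and one placement drawn uniformly; a placement is
legal only if it neither empties an exon nor crosses a neighbouring
boundary. Enumeration (rather than rejection sampling of a shift for one
pre-chosen intron) never dead-ends while legal moves exist and makes the
operator's support directly checkable against brute-force enumeration in
the tests.

The target isoform count of gene $g$ is
$n_g = 1 + \mathrm{Poisson}(c - 1)$ where $c$ is the *transcriptome
complexity index* (`--complexity`, default 2). The Poisson draw is realized
as $1 + F^{-1}_{\mathrm{Pois}(c-1)}(u_g)$ with one uniform $u_g$ per gene
fixed by the seed. This quantile coupling makes the realized mean
isoforms/gene non-decreasing in $c$ pointwise at a fixed seed — the
qualitative behaviour the complexity index is meant to control — which a
plain `rpois()` stream would only guarantee in expectation. A candidate
isoform is accepted only if its intron chain is new within its gene, so the
ground truth never contains within-gene duplicate chains; generation stops
at $n_g$ isoforms or after 20 attempts per requested isoform. Novel ids are
`{parent_id}.as{serial}` and every novel isoform's parent and event are
recorded in a provenance table.

## Expression model

Depth here is a length-normalized quantity: emitted bases divided by
transcribed length. Gene and sample depths are arithmetic means over
expressed isoforms.

**Gene level.** Each expressed gene draws a depth $10^x$ with $x$ from a
Gaussian mixture in log10 space (default: weights 0.7/0.3, means
$\log_{10}\mu \mp 0.5$, sds 0.6/0.4), rejected until the depth lies in
$[\mathrm{low\_cutoff},\ \mathrm{high\_cutoff\_ratio}\cdot\mu]$ (defaults
0.01 and 200). Accepted depths are rescaled by a common factor to mean
$\mu$, re-clipped, and the rescale/clip pass repeated up to 5 times until
the mean is within 1% of $\mu$. The default mixture gives the heavy right
tail and a $\ge 10^4$–$10^5$-fold dynamic range typical of bulk expression.

**Isoform level.** Within a gene with $k$ isoforms, rank $r$ receives an
unnormalized weight $r^{-\alpha}$ ($\alpha$ = `--alpha`, default 4), scaled
so the arithmetic mean of the $k$ weights equals the gene depth; ranks are
assigned to isoforms by a seeded random permutation. The rank weights are
deterministic, so the within-gene max/min ratio is *exactly* $k^\alpha$ —
2401-fold for a 7-isoform gene at the default — giving a closed form the
tests assert rather than a distributional approximation.

**Sample-level calibration.** `--mu` targets the *sample* depth, i.e. the
arithmetic mean over expressed isoforms. Normalizing gene depths alone
leaves a chance bias in that isoform-level mean whenever isoform counts
correlate, by sampling accident, with the heavy-tailed gene depths. A final
uniform rescale of all isoform depths therefore pins the pre-cutoff isoform
mean at $\mu$ exactly; being uniform it preserves all within-gene Zipf
ratios and the identity "gene depth = mean of its isoforms' depths".
Isoforms ending below `low_cutoff` are flagged unexpressed (depth 0) but
kept in the ground-truth annotation, so an evaluator can distinguish
annotated-but-silent isoforms from missing ones.

## Transcription and read generation

Transcription concatenates exonic genome substrings in genomic order and
reverse-complements minus-strand transcripts, so every cDNA is the
mRNA-sense sequence; `N` bases pass through unchanged. Poly(A) tails are
not appended.

Each expressed isoform yields `round(depth)` reads; a full-length read
contributes exactly 1× depth, which keeps realized and target depth in an
exact relationship that truncation then scales. Per read:

1. **Truncation** removes `floor(r5·L)` bases from the 5' end and
   `floor(r3·L)` from the 3' end of the template (`--truncate_ratio_5p/3p`,
   defaults 0). The same fractions apply to every read — a deliberately
   uniform completeness model; real data shows length-dependent,
   non-uniform degradation that this model does not attempt.
2. **Errors**: each base independently suffers an error with probability
   $1 - \mathrm{accuracy}$ (`--accuracy-mean`, default 0.85), split
   sub/ins/del 0.4/0.3/0.3 by default. Substitutions draw a uniform
   different base, insertions append one uniform base, deletions skip the
   base. The per-read quality string is flat at the phred score implied by
   the accuracy, capped at Q41. The number of error events is the
   by-construction edit distance, so realized error rates are measured
   without alignment. No homopolymer or sequence-context effects are
   modelled.
3. **Strandedness**: in the default cDNA-like mode each read is
   reverse-complemented with probability 1/2; direct-RNA mode
   (`strand_symmetric = FALSE`) keeps the sense strand.

Read ids are `{transcript_id}:{serial}:{strand}` (colons in ids
percent-encoded), so provenance survives into any downstream BAM and the
package can compute realized per-isoform depths alignment-free
(`realized_depth_report()`). Reads that would be clipped to nothing
(possible only when `r5 + r3 >= 1`, outside the validated configuration
range) are floored at one base with a warning.

One master seed derives per-stage seeds by hashing the stage name, so a
`simulation_config` reproduces every output file byte-identically, and the
run manifest stores everything needed for `read_manifest()` to do so later.

## Evaluation

Matching follows the exact splice-boundary criterion: a query transcript is
a true positive iff a same-contig, same-strand reference transcript has an
identical intron chain; terminal exon ends may differ by any amount.
Mono-exonic transcripts have no splice junctions and are excluded (unless
`keep_mono`). Each reference transcript is matched at most once
(one-to-one assignment; on chain-equality groups this reduces to counting,
with lexicographic tie-breaks for deterministic reports). Precision is
TP/(TP+FP), sensitivity TP/(TP+FN).

Classification is a strand-specific cascade: **FSM** (chain identical),
**ISM** (chain is a *contiguous* subchain of a longer reference chain —
internal exon-skipping subsets are not ISM and fall through to NIC/NNC),
**NIC** (gene-span overlap, all donors and acceptors individually
annotated), **NNC** (at least one unannotated site), **INTERGENIC** (no
gene-span overlap on any strand; a span is positional, so antisense overlap
disqualifies INTERGENIC while strand-specific junction matching still sends
antisense queries to NNC). Exactly one category per evaluated transcript.

The base-pair Jaccard merges each set's exons per contig (strand-agnostic,
the usual interval-tool semantics), then reports intersection over union of
covered bases; 0 when the union is empty.

## What the fixtures emulate — and what they don't

`make_fixture()` builds i.i.d.-base genomes at a chosen GC fraction with
non-overlapping genes laid left to right, ≥ 500 bp intergenic gaps
(guaranteeing INTERGENIC cases), strands alternating by gene index, and
per-gene isoforms that are exon windows of a shared scaffold with jittered
terminal ends — distinct intron chains by construction, with at most one
mono-exonic isoform per gene. This exercises every code path (strand
handling, terminal tolerance, ISM containment, mono-exon filtering) but has
none of the statistical structure of real genomes: no splice-site motifs,
repeats, GC-content gradients, overlapping genes, or realistic length
distributions. Passing tests therefore demonstrate algorithmic
correctness, not biological realism of any particular simulated dataset.

Test and check problem sizes are deliberately modest — fixtures of 8–500
genes on 0.06–6 Mb contigs, read sets in the tens of thousands, error-rate
calibration over $10^6$ bases — chosen so the whole suite completes in
about a minute while keeping binomial sampling noise well inside the
asserted tolerances (e.g. ±0.5 percentage points on error rates, where the
binomial standard deviation at $10^6$ bases is ~0.04 pp).

## Numerical and degenerate-input choices

* Sampling counts use round-half-up, so retained-set sizes are
  platform-stable (`round()` in R is banker's rounding).
* Depth TSVs print 17 significant digits, making profile round-trips exact.
* GTF output ordering is canonical (contig, gene span, gene id, transcript
  id, exon start), so equal models give byte-identical files.
* `alpha = 0` collapses the Zipf model to equal sharing; `k = 1` returns
  the gene depth; a single gene receives exactly `mu`.
* Empty FASTQs yield all-zero depth reports; unparseable read ids are
  counted and skipped rather than fatal.
* GC content counts G and C only, over the full length including `N`.

## Known limitations

The error model is context-free and the truncation model uniform; quality
strings are flat per read. The AS operator set is {ES, IR, A5, A3} —
alternative first/last exons arise only indirectly through truncation, and
mutually exclusive exons, fusion transcripts and novel intergenic genes are
not generated. The evaluator implements the exact-chain criterion and the
five-way classification only; it does not reproduce any external tool's
extended class codes or terminal-exon tolerances.
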