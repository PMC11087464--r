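#' End-to-end simulation configuration
#'
#' Bundles every knob of the pipeline with the conventional defaults: mean
#' sample depth 20, transcriptome complexity 2, accuracy 0.85 (15% error
#' rate), no truncation, full annotation completeness, isoform depth cutoff
#' 0.01 and gene-depth cap at 200x the mean depth.
#'
#' @param genome_path reference genome FASTA.
#' @param gtf_path reference annotation GTF.
#' @param output_prefix prefix for all output files.
#' @param complexity target transcriptome complexity index.
#' @param mu target mean sample depth.
#' @param alpha Zipf exponent for isoform-level depths.
#' @param accuracy_mean per-base read accuracy.
#' @param truncate_ratio_5p,truncate_ratio_3p read truncation fractions.
#' @param percent annotation completeness: fraction of reference transcripts
#'   retained before simulation.
#' @param low_cutoff minimum isoform depth.
#' @param high_cutoff_ratio gene-depth cap as a multiple of `mu`.
#' @param expressed_gene_fraction fraction of genes selected as expressed.
#' @param seed master seed; all stage seeds are derived from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(genome_path, gtf_path, output_prefix,
                              complexity = 2, mu = 20, alpha = 4,
                              accuracy_mean = 0.85,
                              truncate_ratio_5p = 0, truncate_ratio_3p = 0,
                              percent = 1.0, low_cutoff = 0.01,
                              high_cutoff_ratio = 200,
                              expressed_gene_fraction = 1.0, seed = 0L) {
  cfg <- list(genome_path = genome_path, gtf_path = gtf_path,
              output_prefix = output_prefix, complexity = complexity,
              mu = mu, alpha = alpha, accuracy_mean = accuracy_mean,
              truncate_ratio_5p = truncate_ratio_5p,
              truncate_ratio_3p = truncate_ratio_3p, percent = percent,
              low_cutoff = low_cutoff,
              high_cutoff_ratio = high_cutoff_ratio,
              expressed_gene_fraction = expressed_gene_fraction,
              seed = as.integer(seed))
  # re-validate through the component constructors
  as_event_config(complexity_index = complexity,
                  expressed_gene_fraction = expressed_gene_fraction)
  depth_config(mu = mu, alpha = alpha, low_cutoff = low_cutoff,
               high_cutoff_ratio = high_cutoff_ratio)
  read_sim_config(accuracy_mean = accuracy_mean,
                  truncate_ratio_5p = truncate_ratio_5p,
                  truncate_ratio_3p = truncate_ratio_3p)
  if (!is_fraction(percent, 0, 1)) stop2("percent must be in (0, 1]")
  structure(cfg, class = "simulation_config")
}

pipeline_outputs <- function(prefix) {
  c(gt_gtf = paste0(prefix, ".gt.gtf"),
    expression = paste0(prefix, ".expression.tsv"),
    fastq = paste0(prefix, ".fq"),
    stats = paste0(prefix, ".stats.tsv"),
    provenance = paste0(prefix, ".provenance.tsv"),
    manifest = paste0(prefix, ".manifest.txt"))
}

write_manifest <- function(cfg, path) {
  keys <- c("genome_path", "gtf_path", "output_prefix", "complexity", "mu",
            "alpha", "accuracy_mean", "truncate_ratio_5p",
            "truncate_ratio_3p", "percent", "low_cutoff",
            "high_cutoff_ratio", "expressed_gene_fraction", "seed")
  vals <- vapply(cfg[keys], function(v) format(v, digits = 17L), character(1L))
  writeLines(c(sprintf("tool_version=%s",
                       as.character(utils::packageVersion("lrtsim"))),
               paste0(keys, "=", vals)), path)
  invisible(path)
}

#' Rebuild a simulation configuration from a run manifest
#' @param path manifest path written by [run_end_to_end()].
#' @return A [simulation_config()].
#' @export
read_manifest <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1L), 2L),
                          vapply(kv, `[`, character(1L), 1L))
  num <- function(k) as.numeric(vals[[k]])
  simulation_config(
    genome_path = vals[["genome_path"]], gtf_path = vals[["gtf_path"]],
    output_prefix = vals[["output_prefix"]], complexity = num("complexity"),
    mu = num("mu"), alpha = num("alpha"),
    accuracy_mean = num("accuracy_mean"),
    truncate_ratio_5p = num("truncate_ratio_5p"),
    truncate_ratio_3p = num("truncate_ratio_3p"), percent = num("percent"),
    low_cutoff = num("low_cutoff"),
    high_cutoff_ratio = num("high_cutoff_ratio"),
    expressed_gene_fraction = num("expressed_gene_fraction"),
    seed = as.integer(num("seed")))
}

#' Run the full simulation pipeline
#'
#' Pipeline: subsample annotation completeness, select expressed genes,
#' generate novel AS isoforms (ground-truth annotation), assign expression
#' depths, transcribe stranded cDNA, and simulate reads. Writes
#' `{prefix}.gt.gtf`, `{prefix}.expression.tsv`, `{prefix}.fq`,
#' `{prefix}.stats.tsv`, `{prefix}.provenance.tsv` and a run manifest. One
#' master seed deterministically derives all stage seeds, so identical
#' configurations produce byte-identical outputs. On any stage failure the
#' partial outputs are removed.
#'
#' @param cfg a [simulation_config()].
#' @return Invisibly, a list with the output `paths` and the in-memory
#'   `ground_truth`, `profile` and `sim` objects.
#' @export
run_end_to_end <- function(cfg) {
  paths <- pipeline_outputs(cfg$output_prefix)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(paths)
      stop2("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  genome <- stage("read_genome", read_genome(cfg$genome_path))
  ann <- stage("read_gtf", read_gtf(cfg$gtf_path))
  ann <- stage("sample_transcripts",
               if (cfg$percent < 1) sample_transcripts(ann, cfg$percent,
                                                       cfg$seed) else ann)
  expressed <- stage("select_expressed_genes",
                     select_expressed_genes(ann, cfg$expressed_gene_fraction,
                                            cfg$seed))
  gt <- stage("generate_ground_truth",
              generate_ground_truth(
                expressed,
                as_event_config(complexity_index = cfg$complexity,
                                expressed_gene_fraction =
                                  cfg$expressed_gene_fraction),
                cfg$seed))
  profile <- stage("build_profile",
                   build_profile(gt, depth_config(
                     mu = cfg$mu, alpha = cfg$alpha,
                     low_cutoff = cfg$low_cutoff,
                     high_cutoff_ratio = cfg$high_cutoff_ratio,
                     seed = cfg$seed)))
  seqs <- stage("transcribe", transcribe(gt, genome))
  sim <- stage("simulate_sample",
               simulate_sample(seqs, profile, read_sim_config(
                 accuracy_mean = cfg$accuracy_mean,
                 truncate_ratio_5p = cfg$truncate_ratio_5p,
                 truncate_ratio_3p = cfg$truncate_ratio_3p,
                 seed = cfg$seed)))
  stage("write_outputs", {
    write_gtf(gt$annotation, paths[["gt_gtf"]])
    write_profile(profile, paths[["expression"]])
    write_fastq(sim, paths[["fastq"]])
    write_sim_stats(sim, paths[["stats"]])
    write_provenance(gt, paths[["provenance"]])
    write_manifest(cfg, paths[["manifest"]])
  })
  invisible(list(paths = paths, ground_truth = gt, profile = profile,
                 sim = sim))
}

#' Evaluate a query isoform GTF against a reference GTF
#'
#' Writes a metrics TSV (TP, FP, FN, precision, sensitivity), a
#' per-transcript classification TSV, and (optionally) a Jaccard TSV.
#'
#' @param query_gtf,reference_gtf GTF paths.
#' @param output_prefix prefix for report files.
#' @param keep_mono keep mono-exonic transcripts (default: excluded).
#' @param jaccard also compute base-pair Jaccard similarity.
#' @return Invisibly, a list with `metrics` ([match_exact()] result),
#'   `classification` and `similarity`.
#' @export
run_evaluate <- function(query_gtf, reference_gtf, output_prefix,
                         keep_mono = FALSE, jaccard = TRUE) {
  query <- read_gtf(query_gtf)
  reference <- read_gtf(reference_gtf)
  res <- match_exact(query, reference, keep_mono = keep_mono)
  cls <- classify(query, reference, keep_mono = keep_mono)
  metrics <- data.frame(TP = res$TP, FP = res$FP, FN = res$FN,
                        precision = res$precision,
                        sensitivity = res$sensitivity)
  utils::write.table(metrics, paste0(output_prefix, ".metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cls, paste0(output_prefix, ".classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  similarity <- NULL
  if (jaccard) {
    similarity <- jaccard_similarity(query, reference)
    utils::write.table(
      data.frame(jaccard = similarity$jaccard,
                 intersection_bp = similarity$intersection_bp,
                 union_bp = similarity$union_bp),
      paste0(output_prefix, ".jaccard.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(metrics = res, classification = cls,
                 similarity = similarity))
}

#' Pairwise Jaccard matrix over several isoform GTFs
#'
#' @param gtf_paths character vector of >= 2 GTF paths.
#' @return A symmetric numeric matrix with unit diagonal, dimnames taken
#'   from the file names.
#' @export
jaccard_matrix <- function(gtf_paths) {
  if (length(gtf_paths) < 2L) stop2("need at least two GTFs")
  sets <- lapply(gtf_paths, read_gtf)
  n <- length(sets)
  m <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- jaccard_similarity(sets[[i]], sets[[j]])$jaccard
    }
  }
  dimnames(m) <- list(basename(gtf_paths), basename(gtf_paths))
  m
}
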