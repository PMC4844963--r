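## End-to-end driver for a simulated small-RNA sample: preprocessing,
## truth-alignment lookup (the synthetic generator plays the role of the
## genome aligner), cluster expression calling and population
## characterization.

#' Run the small-RNA pipeline on a synthetic sample
#'
#' Cleans the raw reads (quality truncation, barcode/adapter stripping,
#' 25–35-base gate), keeps the alignments of retained reads, computes the
#' cluster-expression table, and characterizes the retained population
#' (1U bias, length modes) and the cluster-mapped subpopulation.
#'
#' @param reference A [generate_reference()] bundle.
#' @param sample A [simulate_small_rna_sample()] result.
#' @param qmin Quality-truncation threshold (default 15).
#' @param min_reads,min_rpkm,max_depth_ratio Cluster-expression thresholds.
#' @return A list of class `pipeline_result`: `report` (preprocessing
#'   counts), `expression` (cluster table), `expressed_ids`, `u1`
#'   ([u1_bias_test()] on all retained reads), `lengths`
#'   ([length_distribution()]), `cluster_seqs` (sequences of reads
#'   aligned inside clusters), `alignments` (retained), `n_mapped`.
#' @export
run_small_rna_pipeline <- function(reference, sample, qmin = 15L,
                                   min_reads = 100, min_rpkm = 10,
                                   max_depth_ratio = 0.9) {
  pre <- preprocess_small_rna(sample$reads, adapter = reference$config$adapter,
                              qmin = qmin)
  keep <- pre$retained$read_id
  aln <- sample$alignments[sample$alignments$read_id %in% keep]
  n_mapped <- length(unique(aln$read_id))
  expr <- cluster_expression(aln, reference$clusters,
                             total_mapped_reads = n_mapped,
                             min_reads = min_reads, min_rpkm = min_rpkm,
                             max_depth_ratio = max_depth_ratio)
  seqs <- pre$retained$insert
  ov <- GenomicRanges::findOverlaps(aln, reference$clusters, type = "within",
                                    ignore.strand = TRUE)
  cluster_seqs <- unique(aln$seq[S4Vectors::queryHits(ov)])
  structure(list(report = pre$report,
                 expression = expr,
                 expressed_ids = expr$cluster_id[expr$expressed],
                 u1 = u1_bias_test(seqs),
                 lengths = length_distribution(seqs),
                 cluster_seqs = cluster_seqs,
                 alignments = aln,
                 n_mapped = n_mapped),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Small-RNA pipeline result\n")
  cat(sprintf("  reads: %d in, %d retained\n", x$report$input, x$report$retained))
  cat(sprintf("  clusters expressed: %d of %d\n",
              sum(x$expression$expressed), nrow(x$expression)))
  cat(sprintf("  1U fraction %.3f (p = %.3g, %ssignificant)\n",
              x$u1$u1_fraction, x$u1$p_value,
              if (x$u1$significant) "" else "not "))
  cat("  length modes:", paste(x$lengths$modes, collapse = ", "), "\n")
  invisible(x)
}

#' Window profiles for the expressed clusters of a sample
#'
#' Convenience wrapper building [window_fractions()] for every cluster in
#' `cluster_ids`, keyed by cluster id, ready for [correlation_summary()].
#'
#' @param result A `pipeline_result`.
#' @param reference The matching reference bundle.
#' @param cluster_ids Clusters to profile (default: the expressed ones).
#' @param window_size Window width in bases (default 100).
#' @return Named list of `window_profile` objects.
#' @export
expressed_cluster_profiles <- function(result, reference,
                                       cluster_ids = result$expressed_ids,
                                       window_size = 100L) {
  out <- lapply(cluster_ids, function(id) {
    cl <- reference$clusters[reference$clusters$cluster_id == id]
    window_fractions(cl, result$alignments, window_size = window_size)
  })
  stats::setNames(out, cluster_ids)
}
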