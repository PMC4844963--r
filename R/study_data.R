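#' Published per-sample read counts
#'
#' The study's printed per-sample totals — reads sequenced, reads mapped
#' to the genome, and reads mapped within the 214 annotated piRNA
#' clusters — for brain and testes at 10 dpp, 14 dpp and adult stages.
#' Used as input to [mapping_summary()] to reproduce the reported
#' mapping percentages.
#'
#' @return data.frame `sample_id`, `sequenced`, `genome_mapped`,
#'   `cluster_mapped`.
#' @export
study_read_counts <- function() {
  read.delim(system.file("extdata", "study_read_counts.tsv",
                         package = "pirnadev"),
             stringsAsFactors = FALSE)
}

#' Published unique-sequence sharing counts
#'
#' Of the 14,978 unique piRNA sequences mapped within the clusters
#' expressed in adult brain, the number also present (exact sequence
#' match) in each testes stage.
#'
#' @return data.frame `reference_sample`, `shared_unique`, `query_unique`.
#' @export
study_sharing_counts <- function() {
  read.delim(system.file("extdata", "study_sharing_counts.tsv",
                         package = "pirnadev"),
             stringsAsFactors = FALSE)
}
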