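## piRNA-cluster expression calling.
##
## A cluster is called expressed when it has (i) at least 100 contained
## reads, (ii) RPKM of at least 10 against all genome-mapped reads, and
## (iii) reads spread along the cluster rather than piled at one base:
## max per-base depth / contained read count < 0.9 (a guard against PCR
## duplicate towers).

#' Assign alignments to piRNA clusters
#'
#' An alignment contributes to a cluster iff its interval is fully
#' contained in the cluster interval (configurable to any-overlap).
#' Multi-mapping reads contribute once per containing cluster, and a read
#' aligning twice inside one cluster counts twice by default (alignment
#' counting); set `count_unit = "read"` to count distinct read ids.
#'
#' @param alignments `GRanges` of mapped reads with a `read_id` metadata
#'   column.
#' @param clusters `GRanges` of piRNA clusters with `cluster_id` (and
#'   optionally `klass`) metadata columns.  Overlapping clusters raise a
#'   warning; each alignment is then credited to every containing cluster.
#' @param mode Containment rule: `"within"` (default) or `"any"` overlap.
#' @param count_unit `"alignment"` (default) or `"read"`.
#' @return A list with `counts` (data.frame: `cluster_id`, `read_count`)
#'   and `depth` (named list of integer per-base depth vectors over each
#'   cluster, counting contained alignments only).
#' @export
assign_alignments <- function(alignments, clusters,
                              mode = c("within", "any"),
                              count_unit = c("alignment", "read")) {
  mode <- match.arg(mode)
  count_unit <- match.arg(count_unit)
  if (length(clusters) > 1L) {
    self <- GenomicRanges::findOverlaps(clusters, clusters, ignore.strand = TRUE)
    if (length(self) > length(clusters))
      warning("overlapping clusters: alignments credited to every containing cluster")
  }
  ov <- GenomicRanges::findOverlaps(
    alignments, clusters,
    type = if (mode == "within") "within" else "any",
    ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  ids <- as.character(clusters$cluster_id)
  counts <- integer(length(clusters))
  if (length(ov)) {
    if (count_unit == "read") {
      tab <- table(factor(s[!duplicated(paste(s, alignments$read_id[q]))],
                          levels = seq_along(clusters)))
    } else {
      tab <- table(factor(s, levels = seq_along(clusters)))
    }
    counts <- as.integer(tab)
  }
  depth <- vector("list", length(clusters))
  names(depth) <- ids
  for (i in seq_along(clusters)) {
    hit <- q[s == i]
    cl <- clusters[i]
    if (!length(hit)) {
      depth[[i]] <- integer(GenomicRanges::width(cl))
      next
    }
    a <- alignments[hit]
    rel <- IRanges::shift(IRanges::ranges(a), 1L - GenomicRanges::start(cl))
    rel <- IRanges::restrict(rel, start = 1L, end = GenomicRanges::width(cl))
    depth[[i]] <- as.integer(IRanges::coverage(rel, width = GenomicRanges::width(cl)))
  }
  list(counts = data.frame(cluster_id = ids, read_count = counts,
                           stringsAsFactors = FALSE),
       depth = depth)
}

#' Reads per kilobase per million mapped reads
#'
#' @param read_count Reads assigned to the feature.
#' @param cluster_length_bp Feature length in bases (> 0).
#' @param total_mapped_reads Library-wide count of genome-mapped reads (> 0).
#' @return `read_count / ((cluster_length_bp/1e3) * (total_mapped_reads/1e6))`.
#' @export
#' @examples
#' rpkm(100, 10000, 1e6)  # 10
rpkm <- function(read_count, cluster_length_bp, total_mapped_reads) {
  if (any(cluster_length_bp <= 0)) stop("cluster_length_bp must be positive")
  if (any(total_mapped_reads <= 0)) stop("total_mapped_reads must be positive")
  read_count / ((cluster_length_bp / 1e3) * (total_mapped_reads / 1e6))
}

#' Expression call for a piRNA cluster
#'
#' TRUE iff `read_count >= min_reads` and `rpkm >= min_rpkm` and
#' `depth_ratio < max_depth_ratio` (count and RPKM thresholds inclusive,
#' depth-concentration threshold exclusive).
#'
#' @param read_count,rpkm,depth_ratio Per-cluster statistics
#'   (`depth_ratio` = max per-base depth / read count).
#' @param min_reads,min_rpkm,max_depth_ratio Thresholds (defaults 100, 10,
#'   0.9).
#' @return Logical vector.
#' @export
call_expressed <- function(read_count, rpkm, depth_ratio,
                           min_reads = 100, min_rpkm = 10,
                           max_depth_ratio = 0.9) {
  read_count >= min_reads & rpkm >= min_rpkm & depth_ratio < max_depth_ratio
}

#' Cluster expression table
#'
#' Counts contained alignments per cluster, computes RPKM and the
#' depth-concentration ratio, and applies the three-part expression call.
#'
#' @inheritParams assign_alignments
#' @param total_mapped_reads Number of distinct genome-mapped reads in the
#'   sample; defaults to the number of distinct `read_id`s in `alignments`.
#' @param min_reads,min_rpkm,max_depth_ratio Expression thresholds.
#' @return A data.frame with one row per cluster: `cluster_id`, `klass`,
#'   `length`, `read_count`, `rpkm`, `max_depth`, `depth_ratio`,
#'   `expressed`.
#' @export
cluster_expression <- function(alignments, clusters, total_mapped_reads = NULL,
                               mode = c("within", "any"),
                               count_unit = c("alignment", "read"),
                               min_reads = 100, min_rpkm = 10,
                               max_depth_ratio = 0.9) {
  if (is.null(total_mapped_reads))
    total_mapped_reads <- length(unique(alignments$read_id))
  asg <- assign_alignments(alignments, clusters, mode = match.arg(mode),
                           count_unit = match.arg(count_unit))
  res <- asg$counts
  res$klass <- if (!is.null(clusters$klass)) as.character(clusters$klass) else NA_character_
  res$length <- GenomicRanges::width(clusters)
  res$rpkm <- rpkm(res$read_count, res$length, total_mapped_reads)
  res$max_depth <- vapply(asg$depth, function(d) if (length(d)) max(d) else 0L, integer(1))
  res$depth_ratio <- ifelse(res$read_count > 0, res$max_depth / res$read_count, 0)
  res$expressed <- call_expressed(res$read_count, res$rpkm, res$depth_ratio,
                                  min_reads = min_reads, min_rpkm = min_rpkm,
                                  max_depth_ratio = max_depth_ratio)
  res[, c("cluster_id", "klass", "length", "read_count", "rpkm",
          "max_depth", "depth_ratio", "expressed")]
}

#' Intergenic enrichment among expressed clusters
#'
#' One-tailed Fisher exact test of the 2x2 table
#' (expressed vs not) x (intergenic vs genic): the upper hypergeometric
#' tail P(X >= observed intergenic-and-expressed count).
#'
#' @param expressed_ids Character vector of expressed cluster ids.
#' @param clusters `GRanges` (or data.frame) with `cluster_id` and `klass`
#'   columns covering every cluster.
#' @return A list with the 2x2 `table` and the one-tailed `p_value`.
#' @export
intergenic_enrichment <- function(expressed_ids, clusters) {
  if (length(expressed_ids) == 0L) stop("empty expressed set")
  ids <- as.character(clusters$cluster_id)
  klass <- as.character(clusters$klass)
  if (!all(expressed_ids %in% ids)) stop("expressed ids not found among clusters")
  if (anyNA(klass)) stop("every cluster needs a genic/intergenic class")
  expressed <- ids %in% expressed_ids
  inter <- klass == "intergenic"
  tab <- matrix(c(sum(expressed & inter), sum(expressed & !inter),
                  sum(!expressed & inter), sum(!expressed & !inter)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("expressed", "not_expressed"),
                                c("intergenic", "genic")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(table = tab, p_value = p)
}

#' Mapping and cluster-read summary
#'
#' Per-sample counts and percentages of genome-mapped and cluster-mapped
#' reads, formatted with the reporting convention: percentages rounded
#' half-up, integer precision for mapping rates of 1% and above, two
#' decimals below 1%.
#'
#' @param stats data.frame with columns `sample_id`, `sequenced`,
#'   `genome_mapped`, `cluster_mapped` (distinct read counts).
#' @return The input with added `mapped_pct` (genome_mapped / sequenced)
#'   and `cluster_pct` (cluster_mapped / genome_mapped) character columns;
#'   undefined ratios (zero denominator) are reported as `"NA"`.
#' @export
mapping_summary <- function(stats) {
  stopifnot(all(c("sample_id", "sequenced", "genome_mapped", "cluster_mapped")
                %in% names(stats)))
  stats$mapped_pct <- format_percent(stats$genome_mapped, stats$sequenced)
  stats$cluster_pct <- format_percent(stats$cluster_mapped, stats$genome_mapped)
  stats
}

#' Format a count ratio as a printed percentage
#'
#' @param numerator,denominator Counts.
#' @param kind `"mapping"` (integer percent, two decimals below 1%) or
#'   `"sharing"` (one decimal).
#' @return Character vector such as `"7"`, `"0.46"` or `"88.5"`
#'   (percent sign omitted); `"NA"` for zero denominators.
#' @export
#' @examples
#' format_percent(31398, 453456)          # "7"
#' format_percent(741, 161869)            # "0.46"
#' format_percent(13253, 14978, "sharing")  # "88.5"
format_percent <- function(numerator, denominator,
                           kind = c("mapping", "sharing")) {
  kind <- match.arg(kind)
  pct <- 100 * numerator / denominator
  out <- character(length(pct))
  for (i in seq_along(pct)) {
    if (!is.finite(pct[i])) { out[i] <- "NA"; next }
    digits <- if (kind == "sharing") 1L else if (pct[i] > 0 && pct[i] < 1) 2L else 0L
    out[i] <- formatC(round_half_up(pct[i], digits), format = "f", digits = digits)
  }
  out
}
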