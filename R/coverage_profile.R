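## piRNA production profiles along clusters: non-overlapping 100-base
## windows, per-window read fractions, and cross-sample Pearson
## correlation with a significance filter (p <= 0.001) summarized by the
## median retained correlation.

#' Per-window read fractions along a cluster
#'
#' Divides the cluster into non-overlapping windows (the trailing window
#' may be shorter) and assigns each contained alignment to exactly one
#' window by its 5'-most genomic coordinate.
#'
#' @param cluster A single-interval `GRanges` (or anything with one
#'   start/end) for the cluster.
#' @param alignments `GRanges` of alignments; only those fully contained
#'   in the cluster are used.
#' @param window_size Window width in bases (default 100).
#' @return A list of class `window_profile`: `cluster_id`, `window_size`,
#'   `n_windows`, `counts`, `fractions` (sums to 1).  Errors when the
#'   cluster contains no alignment.
#' @export
window_fractions <- function(cluster, alignments, window_size = 100L) {
  stopifnot(length(cluster) == 1L, window_size >= 1L)
  ov <- GenomicRanges::findOverlaps(alignments, cluster, type = "within",
                                    ignore.strand = TRUE)
  hit <- alignments[S4Vectors::queryHits(ov)]
  if (!length(hit)) stop("cluster contains no alignment; profile undefined")
  ## 5'-most genomic coordinate: start for +, end for - (start for *)
  five <- ifelse(as.character(GenomicRanges::strand(hit)) == "-",
                 GenomicRanges::end(hit), GenomicRanges::start(hit))
  rel <- five - GenomicRanges::start(cluster)  # 0-based offset in cluster
  len <- GenomicRanges::width(cluster)
  n_win <- as.integer(ceiling(len / window_size))
  win <- pmin(rel %/% window_size + 1L, n_win)
  counts <- as.integer(table(factor(win, levels = seq_len(n_win))))
  structure(list(
    cluster_id = if (!is.null(cluster$cluster_id)) as.character(cluster$cluster_id) else NA_character_,
    window_size = as.integer(window_size),
    n_windows = n_win,
    counts = counts,
    fractions = counts / sum(counts)), class = "window_profile")
}

#' Pearson correlation with a t-distribution p-value
#'
#' Sample Pearson r with the two-sided p-value from
#' `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom.  Pairs where
#' either vector has zero variance are undefined: `NA` is returned with a
#' warning so callers can skip the pair.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return A list with `r` and `p_value`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance; correlation undefined, pair skipped")
    return(list(r = NA_real_, p_value = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Cross-sample coverage-correlation summary
#'
#' For every cluster expressed in both samples of a pair, correlates the
#' two window profiles; correlations with p <= `p_cutoff` are retained and
#' summarized by their median.
#'
#' @param profiles_a,profiles_b Named lists of `window_profile` objects
#'   (names = cluster ids), one per sample; only shared names are used.
#' @param p_cutoff Significance filter on the correlation p-value
#'   (default 0.001).
#' @return A list: `per_cluster` (data.frame `cluster_id`, `r`, `p_value`,
#'   `retained`), `retained_r`, and `median_r` (`NA` when nothing is
#'   retained).
#' @export
correlation_summary <- function(profiles_a, profiles_b, p_cutoff = 0.001) {
  shared <- intersect(names(profiles_a), names(profiles_b))
  if (length(shared) == 0L) stop("no cluster expressed in both samples")
  rows <- lapply(shared, function(id) {
    pa <- profiles_a[[id]]
    pb <- profiles_b[[id]]
    if (pa$n_windows != pb$n_windows)
      stop("window count mismatch for cluster ", id)
    res <- withCallingHandlers(
      pearson_with_p(pa$fractions, pb$fractions),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(cluster_id = id, r = res$r, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$retained <- !is.na(tab$p_value) & tab$p_value <= p_cutoff
  retained_r <- tab$r[tab$retained]
  list(per_cluster = tab,
       retained_r = retained_r,
       median_r = if (length(retained_r)) stats::median(retained_r) else NA_real_)
}
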