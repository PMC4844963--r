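## CAGE-based gene expression: CTSS aggregation from stranded alignments,
## power-law normalization of tag counts to tags per million (tpm),
## promoter-window gene expression, the >= 0.5 tpm expressed-gene call,
## and the transcription-factor expression-scenario filter.

#' Aggregate CAGE alignments into CTSS counts
#'
#' The CTSS of a forward mate is the 5'-most genomic coordinate on its
#' strand: interval start for `+`, interval end for `-` (0-based
#' single-base positions in the output).  No mapping-quality filter is
#' applied.
#'
#' @param cage_alignments Stranded `GRanges` of forward-mate alignments.
#' @return data.frame `chrom`, `pos` (0-based), `strand`, `count`, sorted
#'   by chrom/pos/strand; empty input gives an empty table.
#' @export
aggregate_ctss <- function(cage_alignments) {
  if (length(cage_alignments) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  str <- as.character(GenomicRanges::strand(cage_alignments))
  if (any(str == "*")) stop("CAGE alignments must be stranded")
  pos1 <- ifelse(str == "+", GenomicRanges::start(cage_alignments),
                 GenomicRanges::end(cage_alignments))
  key <- data.frame(chrom = as.character(GenomicRanges::seqnames(cage_alignments)),
                    pos = pos1 - 1L, strand = str, stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(count = rep(1L, nrow(key))), key, sum)
  agg <- agg[order(agg$chrom, agg$pos, agg$strand), ]
  rownames(agg) <- NULL
  agg
}

#' Fit the reverse-cumulative power law of CTSS counts
#'
#' Computes `R(x)` = number of CTSSs with raw count `>= x` and fits
#' `log R(x) = log c - alpha log x` by ordinary least squares over the
#' distinct counts falling in `fit_range`.
#'
#' @param ctss_counts Integer vector of per-CTSS raw tag counts.
#' @param fit_range Inclusive count interval used for the fit (default
#'   `c(1, 1000)`).
#' @return An object of class `powerlaw_fit` with `alpha`, `c`,
#'   `fit_range`, `n_points`.  Errors with fewer than two distinct count
#'   values inside the range.
#' @export
fit_power_law <- function(ctss_counts, fit_range = c(1, 1000)) {
  stopifnot(length(fit_range) == 2L, fit_range[1] >= 1)
  x <- sort(unique(ctss_counts[ctss_counts >= fit_range[1] &
                                 ctss_counts <= fit_range[2]]))
  if (length(x) < 2L) stop("need at least 2 distinct count values in fit range")
  rx <- vapply(x, function(v) sum(ctss_counts >= v), numeric(1))
  fit <- stats::lm(log(rx) ~ log(x))
  structure(list(alpha = -unname(stats::coef(fit)[2]),
                 c = exp(unname(stats::coef(fit)[1])),
                 fit_range = fit_range,
                 n_points = length(x)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: alpha = %.4f, c = %.4g (%d support points in [%g, %g])\n",
              x$alpha, x$c, x$n_points, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Power-law normalization of CTSS counts to tags per million
#'
#' Maps a raw count by matching reverse-cumulative functions between the
#' sample's fitted law `R_s(x) = c_s x^(-alpha_s)` and a reference law
#' with exponent `alpha_ref` whose intercept `c_ref` is chosen so the
#' reference totals `total_ref` tags (the sum of the reverse-cumulative
#' function over integer counts equals the total tag count):
#' `tpm = (c_ref/c_s)^(1/alpha_ref) * x^(alpha_s/alpha_ref)`.
#' Strictly monotone in `x`, and the identity when the sample fit equals
#' the reference law.
#'
#' @param raw_count Positive raw count(s).
#' @param fit A `powerlaw_fit` for the sample.
#' @param alpha_ref Reference exponent (default 1.25).
#' @param total_ref Reference total tag count (default 1e6, giving tags
#'   per million).
#' @param c_ref Optional explicit reference intercept, overriding the
#'   `total_ref`-derived value.
#' @return Normalized expression (tpm), same length as `raw_count`.
#' @export
powerlaw_normalize <- function(raw_count, fit, alpha_ref = 1.25,
                               total_ref = 1e6, c_ref = NULL) {
  if (any(raw_count <= 0)) stop("raw_count must be positive")
  stopifnot(inherits(fit, "powerlaw_fit"), alpha_ref > 0)
  if (is.null(c_ref)) c_ref <- total_ref / powerlaw_zeta(alpha_ref)
  (c_ref / fit$c)^(1 / alpha_ref) * raw_count^(fit$alpha / alpha_ref)
}

#' Add a tpm column to a CTSS table
#'
#' Fits the power law on the table's counts (unless a fit is supplied) and
#' normalizes every count.
#'
#' @param ctss CTSS data.frame from [aggregate_ctss()].
#' @param fit Optional pre-computed `powerlaw_fit`.
#' @param ... Passed to [fit_power_law()] and [powerlaw_normalize()].
#' @inheritParams powerlaw_normalize
#' @return The CTSS table with a `tpm` column, plus the fit as attribute
#'   `"powerlaw_fit"`.
#' @export
normalize_ctss <- function(ctss, fit = NULL, alpha_ref = 1.25,
                           total_ref = 1e6, fit_range = c(1, 1000)) {
  if (is.null(fit)) fit <- fit_power_law(ctss$count, fit_range = fit_range)
  ctss$tpm <- powerlaw_normalize(ctss$count, fit, alpha_ref = alpha_ref,
                                 total_ref = total_ref)
  attr(ctss, "powerlaw_fit") <- fit
  ctss
}

#' Promoter-window gene expression from normalized CTSSs
#'
#' For each gene, forms the union of strand-oriented promoter windows
#' `[TSS - upstream, TSS + downstream]` (both ends inclusive; upstream is
#' against the direction of transcription) over all its TSSs, sums the
#' tpm of each unique CTSS inside the union exactly once, and calls the
#' gene expressed when the sum reaches `expressed_cutoff`.
#'
#' @param ctss Normalized CTSS table (needs a `tpm` column).
#' @param gene_models data.frame `gene_id`, `chrom`, `strand`, `tss` (one
#'   row per TSS; 0-based TSS positions).
#' @param upstream,downstream Window extents in bases (defaults 1000 and
#'   500).
#' @param expressed_cutoff Expression call threshold in tpm, inclusive
#'   (default 0.5).
#' @param strand_match Require CTSS strand to equal the gene strand
#'   (default TRUE).
#' @return data.frame `gene_id`, `tpm`, `expressed`.  Genes without a TSS
#'   are skipped with a warning.
#' @export
gene_expression <- function(ctss, gene_models, upstream = 1000L,
                            downstream = 500L, expressed_cutoff = 0.5,
                            strand_match = TRUE) {
  if (is.null(ctss$tpm)) stop("ctss table has no tpm column; normalize first")
  gm <- gene_models[!is.na(gene_models$tss), , drop = FALSE]
  dropped <- setdiff(unique(gene_models$gene_id), unique(gm$gene_id))
  if (length(dropped))
    warning("genes without TSS skipped: ", paste(dropped, collapse = ", "))
  genes <- unique(gm$gene_id)
  tpm <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    rows <- gm[gm$gene_id == g, , drop = FALSE]
    strand <- rows$strand[1]
    lo <- if (strand == "+") rows$tss - upstream else rows$tss - downstream
    hi <- if (strand == "+") rows$tss + downstream else rows$tss + upstream
    win <- IRanges::reduce(IRanges::IRanges(start = lo, end = hi))
    sel <- ctss$chrom == rows$chrom[1] &
      IRanges::overlapsAny(IRanges::IRanges(ctss$pos, width = 1L), win)
    if (strand_match) sel <- sel & ctss$strand == strand
    tpm[g] <- sum(ctss$tpm[sel])
  }
  data.frame(gene_id = genes, tpm = unname(tpm),
             expressed = unname(tpm) >= expressed_cutoff,
             stringsAsFactors = FALSE)
}

#' Expression-scenario filter for candidate transcription factors
#'
#' Two regulatory scenarios for discriminatory TFs: an activator of the
#' clusters expressed in adult brain (motif enriched in the BT-cluster
#' promoters) must be expressed above threshold in adult brain and in all
#' three testes stages (scenario 1); a repressor of the clusters not
#' expressed in adult brain (motif enriched in the non-BT promoters) must
#' be expressed above threshold in adult brain but at or below threshold
#' in all testes stages (scenario 2).  "Above" is strict (> threshold),
#' "no more than" is `<=`.
#'
#' @param tf_candidates data.frame with columns `tf_id`, `enriched_in`
#'   (`"BT"` or `"nonBT"`), `annotated_role` (`activator`, `repressor`,
#'   `both`), and one numeric expression column per sample in
#'   `sample_ids`.
#' @param sample_ids Names of the four expression columns: adult brain
#'   first, then the three testes stages.
#' @param threshold Expression threshold in tpm (default 0.5).
#' @return The retained rows with added `scenario` (1 or 2) and
#'   `role_consistent` (scenario 1 matches activator/both, scenario 2
#'   matches repressor/both) columns; candidates with missing expression
#'   are rejected.
#' @export
tf_scenario_filter <- function(tf_candidates,
                               sample_ids = c("brain_adult", "testes_10dpp",
                                              "testes_14dpp", "testes_adult"),
                               threshold = 0.5) {
  stopifnot(all(c("tf_id", "enriched_in", "annotated_role") %in% names(tf_candidates)),
            all(sample_ids %in% names(tf_candidates)),
            length(sample_ids) == 4L)
  expr <- as.matrix(tf_candidates[, sample_ids])
  ok <- stats::complete.cases(expr)
  brain <- expr[, 1]
  testes <- expr[, -1, drop = FALSE]
  s1 <- ok & tf_candidates$enriched_in == "BT" &
    brain > threshold & apply(testes > threshold, 1, all)
  s2 <- ok & tf_candidates$enriched_in == "nonBT" &
    brain > threshold & apply(testes <= threshold, 1, all)
  out <- tf_candidates[s1 | s2, , drop = FALSE]
  out$scenario <- ifelse(s1[s1 | s2], 1L, 2L)
  out$role_consistent <- ifelse(out$scenario == 1L,
                                out$annotated_role %in% c("activator", "both"),
                                out$annotated_role %in% c("repressor", "both"))
  rownames(out) <- NULL
  out
}
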