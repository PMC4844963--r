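## piRNA target prediction.
##
## Route 1 (deadenylation test): per-piRNA top-scoring gene hits above a
## stringent alignment-score threshold, then a Mann-Whitney comparison of
## non-zero fold changes between predicted target genes and the other
## expressed genes.
##
## Route 2 (complementarity signature): a genome scan for loci where a
## guide piRNA aligns with a perfect 10-base 5' seed and a bounded
## mismatch budget elsewhere, overlapped on the opposite strand by an
## exactly matching sense piRNA read; overlapping mRNAs and
## consensus-length-filtered repeat elements are reported as targets.

#' Top-scoring gene target per piRNA
#'
#' Drops hits below `min_score`, optionally restricts to expressed genes,
#' and keeps the single highest-scoring gene per piRNA (ties broken by the
#' lexicographically smallest gene id).
#'
#' @param hit_table data.frame `pirna_id`, `gene_id`, `score`.
#' @param min_score Score threshold, hits below it are dropped
#'   (default 160).
#' @param expressed_genes Optional character vector; hits to other genes
#'   are dropped first.
#' @return data.frame `pirna_id`, `gene_id`, `score`, one row per piRNA
#'   that retains at least one hit.
#' @export
select_top_gene_targets <- function(hit_table, min_score = 160,
                                    expressed_genes = NULL) {
  stopifnot(all(c("pirna_id", "gene_id", "score") %in% names(hit_table)))
  h <- hit_table[is.finite(hit_table$score) & hit_table$score >= min_score, , drop = FALSE]
  if (!is.null(expressed_genes)) h <- h[h$gene_id %in% expressed_genes, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(data.frame(pirna_id = character(0), gene_id = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  h <- h[order(h$pirna_id, -h$score, h$gene_id), ]
  out <- h[!duplicated(h$pirna_id), c("pirna_id", "gene_id", "score")]
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' U statistic with midrank tie handling.  The p-value is exact (full
#' enumeration of all labelings) when `|x| + |y| <= exact_limit` and the
#' pooled sample is tie-free; otherwise the normal approximation with tie
#' correction and a 0.5 continuity correction is used.  Two-sided.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exact_limit Largest pooled size for exact enumeration
#'   (default 12).
#' @return A list: `U` (for sample `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, exact_limit = 12L) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(pooled))
  if (nx + ny <= exact_limit && !ties) {
    ## enumerate every way of labeling nx of the pooled values as "x"
    combs <- utils::combn(nx + ny, nx)
    Us <- apply(combs, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p_value = p, method = "exact"))
  }
  mu <- nx * ny / 2
  n <- nx + ny
  tie_tab <- table(pooled)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  list(U = U, p_value = p, method = "normal")
}

#' Deadenylation test on fold changes
#'
#' Compares the non-zero generalized fold changes (e.g. GFOLD values,
#' juvenile vs adult) of predicted target genes against those of
#' non-target genes with the Mann-Whitney test.
#'
#' @param target_genes Character vector of predicted target gene ids.
#' @param gfold_values Named numeric vector (or data.frame `gene_id`,
#'   `gfold`) of per-gene fold changes over the background gene set.
#' @return A list: `p_value`, `U`, `n_target`, `n_background`,
#'   `median_target`, `median_background`, `method`.  Errors when either
#'   group is empty after dropping zero values.
#' @export
deadenylation_test <- function(target_genes, gfold_values) {
  if (is.data.frame(gfold_values)) {
    gfold_values <- stats::setNames(gfold_values$gfold, gfold_values$gene_id)
  }
  tg <- gfold_values[names(gfold_values) %in% target_genes]
  bg <- gfold_values[!(names(gfold_values) %in% target_genes)]
  tg <- tg[tg != 0]
  bg <- bg[bg != 0]
  if (length(tg) == 0L) stop("no target gene with non-zero fold change")
  if (length(bg) == 0L) stop("no non-target gene with non-zero fold change")
  mw <- mann_whitney(tg, bg)
  list(p_value = mw$p_value, U = mw$U,
       n_target = length(tg), n_background = length(bg),
       median_target = stats::median(tg), median_background = stats::median(bg),
       method = mw$method)
}

## All zero-mismatch genomic matches of a sequence, both strands.
## Returns a GRanges (1-based); used for sense reads and for guide seeds.
exact_genome_matches <- function(seqs, genome) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  hits <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    for (chrom in names(genome)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") s else revcomp(s)
        m <- Biostrings::matchPattern(Biostrings::DNAString(pat), genome[[chrom]])
        if (length(m)) {
          hits[[length(hits) + 1L]] <- GenomicRanges::GRanges(
            seqnames = factor(chrom, levels = names(genome)),
            ranges = IRanges::ranges(m),
            strand = strand,
            read_id = id)
        }
      }
    }
  }
  if (!length(hits)) {
    return(GenomicRanges::GRanges(read_id = character(0)))
  }
  do.call(c, hits)
}

## Guide alignments: zero mismatches in the 5'-most seed_len read bases,
## Phred-sum of qualities at mismatched non-seed positions <= budget.
guide_genome_matches <- function(guides, genome, seed_len = 10L,
                                 budget = 160, qualities = NULL) {
  hits <- list()
  for (id in names(guides)) {
    g <- toupper(guides[[id]])
    L <- nchar(g)
    if (L < seed_len) {
      warning("guide ", id, " shorter than the seed; rejected")
      next
    }
    qual <- if (!is.null(qualities) && !is.null(qualities[[id]]))
      qualities[[id]] else rep(30L, L)
    stopifnot(length(qual) == L)
    seed <- substr(g, 1L, seed_len)
    for (chrom in names(genome)) {
      chrom_seq <- genome[[chrom]]
      clen <- length(chrom_seq)
      ## + strand: read 5' seed at the alignment's genomic start
      m <- Biostrings::matchPattern(Biostrings::DNAString(seed), chrom_seq)
      for (s in BiocGenerics::start(m)) {
        e <- s + L - 1L
        if (e > clen) next
        ref <- as.character(Biostrings::subseq(chrom_seq, s, e))
        mm <- which(strsplit(ref, "")[[1]] != strsplit(g, "")[[1]])
        mm <- mm[mm > seed_len]
        if (sum(qual[mm]) <= budget) {
          hits[[length(hits) + 1L]] <- GenomicRanges::GRanges(
            seqnames = factor(chrom, levels = names(genome)),
            ranges = IRanges::IRanges(s, e), strand = "+",
            read_id = id, n_mismatch = length(mm),
            mismatch_positions = paste(mm, collapse = ","))
        }
      }
      ## - strand: genomic segment equals revcomp(read); the read's 5'
      ## seed occupies the segment's 3'-most genomic bases
      m <- Biostrings::matchPattern(Biostrings::DNAString(revcomp(seed)), chrom_seq)
      for (t in BiocGenerics::start(m)) {
        e <- t + seed_len - 1L
        s <- e - L + 1L
        if (s < 1L) next
        ref <- as.character(Biostrings::subseq(chrom_seq, s, e))
        rc <- revcomp(g)  # aligned to the + strand reference
        mmg <- which(strsplit(ref, "")[[1]] != strsplit(rc, "")[[1]])
        mm_read <- (e - s + 1L) - mmg + 1L  # genomic -> read positions
        mm_read <- mm_read[mm_read > seed_len]
        if (sum(qual[mm_read]) <= budget) {
          hits[[length(hits) + 1L]] <- GenomicRanges::GRanges(
            seqnames = factor(chrom, levels = names(genome)),
            ranges = IRanges::IRanges(s, e), strand = "-",
            read_id = id, n_mismatch = length(mm_read),
            mismatch_positions = paste(sort(mm_read), collapse = ","))
        }
      }
    }
  }
  if (!length(hits)) {
    return(GenomicRanges::GRanges(read_id = character(0), n_mismatch = integer(0),
                                  mismatch_positions = character(0)))
  }
  do.call(c, hits)
}

#' Scan a genome for guide/sense piRNA targeting signatures
#'
#' Sense reads are placed at every exact zero-mismatch genomic match (both
#' strands, all occurrences).  Guide reads are aligned allowing zero
#' mismatches in their 5'-most `seed_len` bases and a mismatch quality
#' budget over the remainder: the sum of Phred scores at mismatched
#' non-seed read positions must not exceed `budget` (with the default
#' uniform Q30 qualities this allows at most 5 non-seed mismatches).  A
#' signature site is a guide alignment overlapped by at least one sense
#' alignment on the opposite genomic strand by at least one base.
#'
#' @param guide_seqs,sense_seqs Named character vectors of read sequences.
#' @param genome `DNAStringSet` of chromosome sequences.
#' @param seed_len Seed length in read bases (default 10).
#' @param budget Phred-sum mismatch budget outside the seed (default 160).
#' @param guide_qualities Optional named list of integer per-base Phred
#'   scores for the guides; defaults to Q30 everywhere.
#' @param ping_pong When TRUE, additionally require the genomic span of
#'   the guide's first 10 bases to coincide exactly with the genomic span
#'   of the sense read's first 10 bases (the 10-nt 5'-5' register);
#'   default FALSE.
#' @return A `GRanges` of signature sites (the guide alignment interval)
#'   with metadata `guide_id`, `n_mismatch`, `mismatch_positions`,
#'   `sense_ids` (comma-separated supporting sense reads).
#' @export
signature_scan <- function(guide_seqs, sense_seqs, genome, seed_len = 10L,
                           budget = 160, guide_qualities = NULL,
                           ping_pong = FALSE) {
  if (is.null(names(guide_seqs))) names(guide_seqs) <- paste0("guide", seq_along(guide_seqs))
  if (is.null(names(sense_seqs))) names(sense_seqs) <- paste0("sense", seq_along(sense_seqs))
  sense_sites <- exact_genome_matches(sense_seqs, genome)
  guide_sites <- guide_genome_matches(guide_seqs, genome, seed_len = seed_len,
                                      budget = budget, qualities = guide_qualities)
  if (!length(guide_sites) || !length(sense_sites)) {
    return(GenomicRanges::GRanges(guide_id = character(0), n_mismatch = integer(0),
                                  mismatch_positions = character(0),
                                  sense_ids = character(0)))
  }
  ov <- GenomicRanges::findOverlaps(guide_sites, sense_sites, minoverlap = 1L,
                                    ignore.strand = TRUE)
  opp <- as.character(GenomicRanges::strand(guide_sites))[S4Vectors::queryHits(ov)] !=
    as.character(GenomicRanges::strand(sense_sites))[S4Vectors::subjectHits(ov)]
  ov <- ov[opp]
  if (ping_pong) {
    keep <- mapply(function(qi, si) {
      five_span <- function(gr) {
        if (as.character(GenomicRanges::strand(gr)) == "+")
          c(GenomicRanges::start(gr), GenomicRanges::start(gr) + 9L)
        else
          c(GenomicRanges::end(gr) - 9L, GenomicRanges::end(gr))
      }
      identical(five_span(guide_sites[qi]), five_span(sense_sites[si]))
    }, S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
    ov <- ov[keep]
  }
  if (!length(ov)) {
    return(GenomicRanges::GRanges(guide_id = character(0), n_mismatch = integer(0),
                                  mismatch_positions = character(0),
                                  sense_ids = character(0)))
  }
  qh <- S4Vectors::queryHits(ov)
  support <- tapply(sense_sites$read_id[S4Vectors::subjectHits(ov)], qh,
                    function(x) paste(sort(unique(x)), collapse = ","))
  idx <- as.integer(names(support))
  out <- guide_sites[idx]
  names(S4Vectors::mcols(out))[names(S4Vectors::mcols(out)) == "read_id"] <- "guide_id"
  out$sense_ids <- as.character(support)
  out
}

#' Filter repeat elements by consensus-length fraction
#'
#' Retains elements whose length reaches `min_fraction` of the family
#' consensus length; rows with missing or non-positive consensus length
#' are skipped with a warning.
#'
#' @param repeat_table data.frame with `element_length` and
#'   `consensus_length` columns.
#' @param min_fraction Minimum element/consensus length ratio, inclusive
#'   (default 0.75).
#' @return The retained rows; the number of skipped rows is attached as
#'   attribute `"skipped"`.
#' @export
filter_repeats <- function(repeat_table, min_fraction = 0.75) {
  bad <- is.na(repeat_table$consensus_length) | repeat_table$consensus_length <= 0
  if (any(bad)) warning(sum(bad), " repeat rows without usable consensus length skipped")
  ok <- repeat_table[!bad, , drop = FALSE]
  out <- ok[ok$element_length >= min_fraction * ok$consensus_length, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- sum(bad)
  out
}

#' Annotate signature sites with overlapping genes and repeats
#'
#' A gene or repeat element is a potential target iff at least one
#' signature site overlaps its interval by at least one base; each is
#' reported once regardless of the number of supporting sites.
#'
#' @param sites Signature-site `GRanges` from [signature_scan()]
#'   (1-based).
#' @param gene_ranges `GRanges` of gene intervals with a `gene_id`
#'   metadata column (may be NULL).
#' @param repeat_table Repeat data.frame (`chrom`, `start`, `end`,
#'   `strand`, `family`; 0-based half-open), typically pre-filtered with
#'   [filter_repeats()] (may be NULL).
#' @return A list: `mrna_targets` (character), `repeat_targets`
#'   (data.frame of overlapped repeat rows), `repeat_family_counts`
#'   (table by family), `unannotated` (number of sites overlapping
#'   neither).
#' @export
annotate_targets <- function(sites, gene_ranges = NULL, repeat_table = NULL) {
  in_gene <- rep(FALSE, length(sites))
  mrna <- character(0)
  if (!is.null(gene_ranges) && length(gene_ranges)) {
    ov <- GenomicRanges::findOverlaps(sites, gene_ranges, ignore.strand = TRUE)
    mrna <- sort(unique(as.character(gene_ranges$gene_id[S4Vectors::subjectHits(ov)])))
    in_gene[S4Vectors::queryHits(ov)] <- TRUE
  }
  in_rep <- rep(FALSE, length(sites))
  rep_rows <- NULL
  fam_counts <- table(factor(character(0), levels = c("SINE", "LINE", "LTR", "other")))
  if (!is.null(repeat_table) && nrow(repeat_table)) {
    rg <- GenomicRanges::GRanges(repeat_table$chrom,
                                 IRanges::IRanges(repeat_table$start + 1L,
                                                  repeat_table$end))
    ov <- GenomicRanges::findOverlaps(sites, rg, ignore.strand = TRUE)
    hit_rows <- sort(unique(S4Vectors::subjectHits(ov)))
    rep_rows <- repeat_table[hit_rows, , drop = FALSE]
    fam <- ifelse(rep_rows$family %in% c("SINE", "LINE", "LTR"),
                  rep_rows$family, "other")
    fam_counts <- table(factor(fam, levels = c("SINE", "LINE", "LTR", "other")))
    in_rep[S4Vectors::queryHits(ov)] <- TRUE
  }
  list(mrna_targets = mrna,
       repeat_targets = rep_rows,
       repeat_family_counts = fam_counts,
       unannotated = sum(!in_gene & !in_rep))
}
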