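## Characterization of candidate piRNA populations: positional base
## composition (sequence-logo style), the 1U first-base bias of primary
## piRNAs, read-length modes (MILI-bound ~26-27 nt vs MIWI-bound
## ~29-30 nt), exact-sequence sharing between samples, and contamination
## by annotated ncRNAs.

#' Positional base composition and information content
#'
#' Per-position A/C/G/T frequencies over all sequences long enough to
#' cover the position, plus the sequence-logo information content
#' `IC(i) = 2 + sum_b f(b,i) log2 f(b,i)` in bits (0 log 0 = 0).
#'
#' @param seqs Character vector of sequences over A/C/G/T/N (T plays the
#'   role of U).
#' @param max_pos Number of 5' positions profiled; defaults to the longest
#'   sequence.
#' @return A list of class `composition_matrix`: `freq` (4 x max_pos
#'   matrix), `counts`, `ic` (bits per position), `n_sequences`,
#'   `coverage` (sequences covering each position).  `N` bases are
#'   excluded from the frequency denominator.
#' @export
positional_composition <- function(seqs, max_pos = NULL) {
  if (length(seqs) == 0L) stop("empty sequence set")
  seqs <- toupper(seqs)
  if (is.null(max_pos)) max_pos <- max(nchar(seqs))
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = 4, ncol = max_pos, dimnames = list(bases, NULL))
  lens <- nchar(seqs)
  for (i in seq_len(max_pos)) {
    b <- substr(seqs[lens >= i], i, i)
    tb <- table(factor(b, levels = bases))
    counts[, i] <- as.integer(tb)
  }
  cov <- colSums(counts)
  freq <- sweep(counts, 2, pmax(cov, 1L), "/")
  ic <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  ic[cov == 0] <- NA_real_
  structure(list(freq = freq, counts = counts, ic = ic,
                 n_sequences = length(seqs), coverage = cov),
            class = "composition_matrix")
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat("Positional composition over", x$n_sequences, "sequences,",
      ncol(x$freq), "positions\n")
  cat("IC (bits), first positions:",
      paste(formatC(utils::head(x$ic, 8), digits = 3, format = "f"), collapse = " "),
      "\n")
  invisible(x)
}

#' Test for 1U first-base bias
#'
#' Fraction of sequences whose first base is T, with a one-sided exact
#' binomial test against a background first-base probability.  The bias is
#' declared significant when the upper-tail p-value is at most `alpha`
#' and the observed fraction exceeds the background.
#'
#' @param seqs Character vector of sequences.
#' @param background Null probability that a first base is T (default
#'   0.25).
#' @param alpha Significance threshold on the upper-tail p-value
#'   (default 0.001).
#' @return A list: `u1_fraction`, `n`, `p_value`
#'   (`P(X >= observed | Binomial(n, background))`), `significant`.
#' @export
u1_bias_test <- function(seqs, background = 0.25, alpha = 0.001) {
  if (length(seqs) == 0L) stop("empty sequence set")
  stopifnot_scalar_prob(background, "background")
  first <- substr(toupper(seqs), 1, 1)
  n <- length(seqs)
  k <- sum(first == "T")
  p <- stats::pbinom(k - 1L, n, background, lower.tail = FALSE)
  list(u1_fraction = k / n, n = n, p_value = p,
       significant = (p <= alpha) && (k / n > background))
}

#' Read-length histogram and modal lengths
#'
#' Integer histogram of sequence lengths with plateau-aware local maxima
#' as modes: a run of equal counts strictly greater than both neighbours
#' is one mode (reported at its first length), provided its count reaches
#' `prominence` times the total.
#'
#' @param seqs Character vector of sequences.
#' @param prominence Minimum fraction of all sequences a mode must carry
#'   (default 0.1).
#' @return A list: `histogram` (data.frame `length`, `count`, spanning the
#'   full observed range including zeros) and `modes` (increasing integer
#'   vector).
#' @export
length_distribution <- function(seqs, prominence = 0.1) {
  if (length(seqs) == 0L) stop("empty sequence set")
  lens <- nchar(seqs)
  rng <- seq(min(lens), max(lens))
  counts <- as.integer(table(factor(lens, levels = rng)))
  ## pad with zero sentinels so boundary maxima are detected
  padded <- c(0L, counts, 0L)
  r <- rle(padded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  modes <- integer(0)
  for (j in seq_along(r$values)) {
    if (j == 1L || j == length(r$values)) next
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]) {
      if (r$values[j] >= prominence * length(seqs)) {
        modes <- c(modes, rng[starts[j] - 1L])  # first length of the plateau
      }
    }
  }
  list(histogram = data.frame(length = rng, count = counts),
       modes = sort(modes))
}

#' Fraction of unique query sequences present in a reference sample
#'
#' Deduplicates the query to unique strings and returns the fraction that
#' occur (exact string equality) among the unique reference sequences.
#'
#' @param query_seqs,reference_seqs Character vectors of sequences.
#' @return `|unique(query) intersect unique(reference)| / |unique(query)|`.
#' @export
shared_sequence_fraction <- function(query_seqs, reference_seqs) {
  if (length(query_seqs) == 0L) stop("empty query set")
  if (length(reference_seqs) == 0L) stop("empty reference set")
  q <- unique(toupper(query_seqs))
  r <- unique(toupper(reference_seqs))
  sum(q %in% r) / length(q)
}

#' Fraction of reads with perfect ncRNA matches
#'
#' A read matches iff it occurs as an exact full-length substring of any
#' ncRNA sequence or of its reverse complement; used to flag snoRNA/tRNA/
#' miRNA/rRNA fragments masquerading as piRNAs.
#'
#' @param seqs Character vector of reads.
#' @param ncrna ncRNA sequences (`DNAStringSet` or character vector, e.g.
#'   from [Biostrings::readDNAStringSet()]).
#' @return Fraction of `seqs` with at least one perfect match; 0 with a
#'   warning when the ncRNA set is empty.
#' @export
ncrna_match_fraction <- function(seqs, ncrna) {
  if (length(seqs) == 0L) stop("empty sequence set")
  if (length(ncrna) == 0L) {
    warning("empty ncRNA set; match fraction is 0")
    return(0)
  }
  db <- toupper(as.character(ncrna))
  haystack <- paste(c(db, revcomp(db)), collapse = "|")
  matched <- vapply(unique(toupper(seqs)), function(s) {
    grepl(s, haystack, fixed = TRUE)
  }, logical(1))
  hit <- unique(toupper(seqs))[matched]
  sum(toupper(seqs) %in% hit) / length(seqs)
}
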