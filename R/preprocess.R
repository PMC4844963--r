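## Read cleaning for small-RNA tags and CAGE forward mates.
##
## Small-RNA raw reads are 5'-barcode + endogenous insert + 3'-adapter.
## Cleaning is: (1) truncate at the first base with quality <= 15,
## (2) strip the 4-base barcode, (3) strip the 3' adapter (at least one
## adapter base must be present, anchored at the read end), (4) keep
## inserts of 25..35 bases.  CAGE forward mates instead lose a fixed
## 9-base prefix (barcode + template-switch GGG) and must stay > 15 bases.

#' Truncate reads at the first low-quality base
#'
#' Keeps, for every read, the longest prefix in which every base has
#' quality strictly greater than `qmin`; the offending base and everything
#' after it are removed.  A read whose first base is low quality becomes
#' empty (it is kept in the table so downstream accounting conserves read
#' counts).
#'
#' @param reads Read table (`read_id`, `sequence`, `quality`), Phred+33.
#' @param qmin Quality threshold; bases with score `<= qmin` trigger
#'   truncation (default 15).
#' @return The read table with truncated `sequence` and `quality` and an
#'   added `quality_trimmed` column counting removed bases.
#' @export
truncate_at_low_quality <- function(reads, qmin = 15L) {
  if (nrow(reads) == 0L) {
    reads$quality_trimmed <- integer(0)
    return(reads)
  }
  if (qmin < 0L || qmin > 60L) stop("qmin out of the Phred range")
  ## first character encoding a score <= qmin: ASCII range 33 .. 33+qmin
  pat <- sprintf("[\\x21-\\x%02x]", 33L + qmin)
  cut <- regexpr(pat, reads$quality, perl = TRUE)
  len <- nchar(reads$sequence)
  keep <- ifelse(cut == -1L, len, cut - 1L)
  reads$quality_trimmed <- len - keep
  reads$sequence <- substr(reads$sequence, 1L, keep)
  reads$quality <- substr(reads$quality, 1L, keep)
  reads
}

#' Extract endogenous small-RNA inserts
#'
#' Strips the 5' barcode and the 3' adapter from quality-truncated reads
#' and applies the piRNA length gate.  The adapter is matched as the
#' longest read suffix that equals a prefix of the adapter sequence (i.e.
#' the leftmost match anchored at the read's 3' end); at least
#' `adapter_min_overlap` adapter bases must be removed or the read is
#' discarded.  Inserts of length `<= min_len_exclusive` are discarded and
#' inserts longer than `max_len` are truncated to `max_len`.  `N` bases
#' never match the adapter.
#'
#' @param reads Quality-truncated read table.
#' @param adapter 3' adapter sequence (5'->3').
#' @param barcode_len Length of the 5' barcode (default 4).
#' @param min_len_exclusive Inserts with length less than or equal to this
#'   are discarded (default 24).
#' @param max_len Maximum insert length retained (default 35).
#' @param adapter_min_overlap Minimum number of adapter bases that must be
#'   stripped (default 1).
#' @return A list with `retained` (columns `read_id`, `insert`,
#'   `quality_trimmed`, `barcode_removed`, `adapter_removed`) and
#'   `discarded` (`read_id`, `reason` in `too_short_for_barcode`,
#'   `no_adapter`, `short_insert`).
#' @export
extract_small_rna_insert <- function(reads, adapter,
                                     barcode_len = 4L,
                                     min_len_exclusive = 24L,
                                     max_len = 35L,
                                     adapter_min_overlap = 1L) {
  stopifnot(is_string(adapter), nchar(adapter) >= 1L)
  adapter <- toupper(adapter)
  n <- nrow(reads)
  if (is.null(reads$quality_trimmed)) reads$quality_trimmed <- 0L
  if (n == 0L) {
    return(list(
      retained = data.frame(read_id = character(0), insert = character(0),
                            quality_trimmed = integer(0),
                            barcode_removed = integer(0),
                            adapter_removed = integer(0),
                            stringsAsFactors = FALSE),
      discarded = data.frame(read_id = character(0), reason = character(0),
                             stringsAsFactors = FALSE)))
  }
  len <- nchar(reads$sequence)
  reason <- rep(NA_character_, n)

  reason[len < barcode_len] <- "too_short_for_barcode"
  body <- substr(reads$sequence, barcode_len + 1L, len)
  blen <- nchar(body)

  ## Longest read suffix equal to an adapter prefix == leftmost adapter
  ## match anchored at the 3' end.  Scan suffix lengths from long to short.
  stripped <- integer(n)
  unmatched <- is.na(reason)
  max_k <- min(nchar(adapter), max(blen, 0L))
  if (max_k >= adapter_min_overlap) {
    for (k in seq(max_k, adapter_min_overlap)) {
      if (!any(unmatched)) break
      cand <- unmatched & blen >= k
      if (!any(cand)) next
      hit <- cand
      hit[cand] <- substr(body[cand], blen[cand] - k + 1L, blen[cand]) ==
        substr(adapter, 1L, k)
      stripped[hit] <- k
      unmatched <- unmatched & !hit
    }
  }
  reason[is.na(reason) & stripped < adapter_min_overlap] <- "no_adapter"

  insert <- substr(body, 1L, blen - stripped)
  short <- is.na(reason) & nchar(insert) <= min_len_exclusive
  reason[short] <- "short_insert"

  keep <- is.na(reason)
  insert <- substr(insert, 1L, pmin(nchar(insert), max_len))
  list(
    retained = data.frame(
      read_id = reads$read_id[keep],
      insert = insert[keep],
      quality_trimmed = reads$quality_trimmed[keep],
      barcode_removed = rep(barcode_len, sum(keep)),
      adapter_removed = stripped[keep],
      stringsAsFactors = FALSE),
    discarded = data.frame(
      read_id = reads$read_id[!keep],
      reason = reason[!keep],
      stringsAsFactors = FALSE))
}

#' Trim CAGE forward mates
#'
#' Removes the fixed 9-base prefix (6-base barcode plus the three
#' template-switch guanines) from quality-truncated forward mates without
#' verifying the G content, then discards mates whose remaining length is
#' `<= min_len_exclusive`.
#'
#' @param reads Quality-truncated read table.
#' @param prefix_len Prefix length removed unconditionally (default 9).
#' @param min_len_exclusive Mates of length less than or equal to this are
#'   discarded (default 15).
#' @return A list with `retained` (read table) and `discarded`
#'   (`read_id`, `reason` in `too_short_for_prefix`, `short_mate`).
#' @export
extract_cage_forward_mate <- function(reads, prefix_len = 9L,
                                      min_len_exclusive = 15L) {
  len <- nchar(reads$sequence)
  reason <- rep(NA_character_, nrow(reads))
  reason[len < prefix_len] <- "too_short_for_prefix"
  out_seq <- substr(reads$sequence, prefix_len + 1L, len)
  out_qual <- substr(reads$quality, prefix_len + 1L, len)
  reason[is.na(reason) & nchar(out_seq) <= min_len_exclusive] <- "short_mate"
  keep <- is.na(reason)
  retained <- reads[keep, , drop = FALSE]
  retained$sequence <- out_seq[keep]
  retained$quality <- out_qual[keep]
  rownames(retained) <- NULL
  list(retained = retained,
       discarded = data.frame(read_id = reads$read_id[!keep],
                              reason = reason[!keep],
                              stringsAsFactors = FALSE))
}

#' Full small-RNA preprocessing
#'
#' Quality truncation followed by barcode/adapter stripping and the
#' 25–35-base length gate, with per-reason accounting.
#'
#' @inheritParams truncate_at_low_quality
#' @inheritParams extract_small_rna_insert
#' @return A list with `retained`, `discarded`, and `report` (a one-row
#'   data.frame: input, retained, and per-reason discard counts).
#' @export
preprocess_small_rna <- function(reads, adapter, qmin = 15L,
                                 barcode_len = 4L, min_len_exclusive = 24L,
                                 max_len = 35L, adapter_min_overlap = 1L) {
  trunc <- truncate_at_low_quality(reads, qmin = qmin)
  res <- extract_small_rna_insert(trunc, adapter = adapter,
                                  barcode_len = barcode_len,
                                  min_len_exclusive = min_len_exclusive,
                                  max_len = max_len,
                                  adapter_min_overlap = adapter_min_overlap)
  reasons <- c("too_short_for_barcode", "no_adapter", "short_insert")
  counts <- vapply(reasons, function(r) sum(res$discarded$reason == r), integer(1))
  res$report <- data.frame(input = nrow(reads),
                           retained = nrow(res$retained),
                           t(counts))
  res
}
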