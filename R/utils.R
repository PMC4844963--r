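#' Round half away from zero
#'
#' Decimal rounding where exact halves round up (away from zero), the
#' convention used when reporting read-mapping percentages.  Base R's
#' `round()` rounds half to even, which disagrees on values such as 0.5.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.45), digits = 0)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Reverse complement for plain character vectors (sequencing alphabet,
## T stands for U throughout).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Derive a child seed from a base seed and a label, staying inside the
## 32-bit integer range.  Deterministic and independent of R's RNG state.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 2654435 + h) %% .Machine$integer.max)
}

## sum_{x>=1} x^(-alpha), alpha > 1: direct partial sum plus an
## Euler-Maclaurin tail correction.  Used to convert a total tag count
## into the intercept of the reference power law, because the sum of the
## reverse-cumulative function over integer x equals the total tag count.
powerlaw_zeta <- function(alpha, n = 1e5) {
  if (alpha <= 1) stop("reference exponent must exceed 1 for a finite total")
  x <- seq_len(n)
  sum(x^(-alpha)) + n^(1 - alpha) / (alpha - 1) - 0.5 * n^(-alpha) +
    alpha * n^(-alpha - 1) / 12
}

## Shared input checks -------------------------------------------------

stopifnot_scalar_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("%s must be a single value in [0, 1]", what), call. = FALSE)
  invisible(x)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
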