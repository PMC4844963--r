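## Independent oracles used to freeze expected values; deliberately
## brute-force and separate from the package's code paths.

## Upper hypergeometric tail P(X >= a) for the 2x2 table
## [[a, b], [c, d]] (rows: expressed / not, cols: intergenic / genic),
## by direct enumeration of all tables with the same margins.
oracle_fisher_upper <- function(a, b, c, d) {
  K <- a + c            # intergenic total
  n1 <- a + b           # expressed total
  N <- a + b + c + d
  a_range <- max(0, n1 - (N - K)):min(K, n1)
  probs <- choose(K, a_range) * choose(N - K, n1 - a_range) / choose(N, n1)
  sum(probs[a_range >= a])
}

## Exact two-sided Mann-Whitney p by full enumeration of labelings.
oracle_mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  combs <- utils::combn(nx + ny, nx)
  Us <- apply(combs, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-12)
}

## Brute-force signature scan: slide every guide over every offset of
## every chromosome on both strands, counting mismatches directly.
oracle_guide_sites <- function(guide, genome, seed_len = 10L, budget = 160,
                               qual = NULL) {
  L <- nchar(guide)
  if (is.null(qual)) qual <- rep(30L, L)
  g <- strsplit(toupper(guide), "")[[1]]
  out <- NULL
  for (chrom in names(genome)) {
    s_chr <- strsplit(as.character(genome[[chrom]]), "")[[1]]
    for (start in seq_len(length(s_chr) - L + 1L)) {
      ref <- s_chr[start:(start + L - 1L)]
      ## + strand: read position i pairs with ref[i]
      mm <- which(ref != g)
      if (!any(mm <= seed_len) && sum(qual[mm[mm > seed_len]]) <= budget) {
        out <- rbind(out, data.frame(chrom = chrom, start = start,
                                     end = start + L - 1L, strand = "+"))
      }
      ## - strand: read i pairs with complement(ref[L - i + 1])
      comp <- chartr("ACGT", "TGCA", ref)
      read_ref <- rev(comp)
      mm <- which(read_ref != g)
      if (!any(mm <= seed_len) && sum(qual[mm[mm > seed_len]]) <= budget) {
        out <- rbind(out, data.frame(chrom = chrom, start = start,
                                     end = start + L - 1L, strand = "-"))
      }
    }
  }
  out
}

## Assemble a raw small-RNA read (barcode + insert + adapter prefix) with
## uniform quality, for constructing preprocessing fixtures.
make_raw_read <- function(id, insert, barcode = "ACGT",
                          adapter = "TGGAATTCTCGGGTGCCAAGG",
                          read_len = 40L, q = 30L) {
  s <- substr(paste0(barcode, insert, adapter), 1, read_len)
  data.frame(read_id = id, sequence = s,
             quality = strrep(intToUtf8(33L + q), nchar(s)),
             stringsAsFactors = FALSE)
}

## Phred+33 quality string from integer scores.
qual_string <- function(scores) intToUtf8(33L + scores)

## Small, fast reference shared by module tests.
make_test_reference <- function(seed = 11L, n_clusters = 4L,
                                pools = NULL, genome_length = 3e5) {
  cfg <- simulation_config(genome_length = genome_length, n_chromosomes = 2L,
                           n_clusters = n_clusters,
                           cluster_length_range = c(800L, 1200L),
                           n_genes = 10L, n_repeats = 12L, n_ncrna = 4L,
                           pools = pools, duplicate_fraction = 0,
                           rng_seed = seed)
  generate_reference(cfg)
}
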