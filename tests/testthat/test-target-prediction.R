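test_that("top-hit selection thresholds, restricts and tie-breaks", {
  hits <- data.frame(
    pirna_id = c("p1", "p1", "p1", "p2", "p2", "p3", "p3"),
    gene_id = c("gA", "gB", "gC", "gX", "gY", "gB", "gA"),
    score = c(150, 165, 170, 140, 159, 170, 170))
  out <- select_top_gene_targets(hits)
  expect_equal(out$gene_id[out$pirna_id == "p1"], "gC")
  expect_false("p2" %in% out$pirna_id)      # all hits below 160
  expect_equal(out$gene_id[out$pirna_id == "p3"], "gA")  # tie -> smallest id
  ## expressed-gene restriction
  out <- select_top_gene_targets(hits, expressed_genes = c("gB"))
  expect_equal(out$gene_id, c("gB", "gB"))
  expect_equal(nrow(select_top_gene_targets(hits[0, ])), 0L)
})

test_that("Mann-Whitney exact p equals full enumeration", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.10, tolerance = 1e-12)
  expect_equal(res$method, "exact")
  ## identical single values: midranks give U = 0.5, p = 1
  res <- mann_whitney(5, 5)
  expect_equal(res$U, 0.5)
  expect_equal(res$p_value, 1)
  ## enumeration oracle across several splits
  set.seed(61)
  for (i in 1:8) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(100, nx); y <- sample(200:300, ny)
    vals <- sample(c(x, y))
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    expect_equal(mann_whitney(x, y)$p_value, oracle_mw_exact(x, y),
                 tolerance = 1e-12)
  }
  ## large-sample agreement with the standard implementation
  set.seed(62)
  x <- rnorm(80); y <- rnorm(90, 0.3)
  mine <- mann_whitney(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  ## U centers at nx*ny/2 under the null
  expect_lt(abs(mine$U - 80 * 90 / 2), 3 * sqrt(80 * 90 * (80 + 90 + 1) / 12))
  expect_error(mann_whitney(numeric(0), 1))
})

test_that("deadenylation test drops zero fold changes and detects shifts", {
  gf <- c(t1 = 0, t2 = 0, t3 = -1, n1 = 0, n2 = 1)
  res <- deadenylation_test(c("t1", "t2", "t3"), gf)
  expect_equal(res$n_target, 1L)
  expect_equal(res$n_background, 1L)
  expect_equal(res$median_target, -1)
  expect_equal(res$median_background, 1)
  expect_error(deadenylation_test(c("t1"), c(t1 = 0, n1 = 0)))
  ## strong true shift is detected
  set.seed(71)
  gf2 <- c(setNames(rnorm(200, -1), paste0("t", 1:200)),
           setNames(rnorm(200, +1), paste0("n", 1:200)))
  res2 <- deadenylation_test(paste0("t", 1:200), gf2)
  expect_lt(res2$p_value, 1e-6)
})

test_that("signature scan agrees with the brute-force offset oracle", {
  set.seed(81)
  genome <- Biostrings::DNAStringSet(c(
    chrA = paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = ""),
    chrB = paste(sample(c("A", "C", "G", "T"), 8000, TRUE), collapse = "")))
  ## guides: one perfect complement of a locus, one with 2 non-seed
  ## mismatches, one random
  locus <- as.character(Biostrings::subseq(genome[["chrA"]], 2001, 2027))
  g1 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(locus)))
  g2 <- g1
  for (p in c(15, 20)) substr(g2, p, p) <- setdiff(c("A", "C", "G", "T"),
                                                   substr(g2, p, p))[1]
  g3 <- paste(sample(c("A", "C", "G", "T"), 27, TRUE), collapse = "")
  guides <- c(gu1 = g1, gu2 = g2, gu3 = g3)
  for (gid in names(guides)) {
    got <- pirnadev:::guide_genome_matches(guides[gid], genome)
    want <- oracle_guide_sites(guides[[gid]], genome)
    got_df <- if (length(got)) {
      d <- data.frame(chrom = as.character(GenomicRanges::seqnames(got)),
                      start = GenomicRanges::start(got),
                      end = GenomicRanges::end(got),
                      strand = as.character(GenomicRanges::strand(got)))
      d[order(d$chrom, d$start, d$strand), ]
    } else NULL
    if (is.null(want)) {
      expect_equal(length(got), 0L)
    } else {
      want <- want[order(want$chrom, want$start, want$strand), ]
      rownames(got_df) <- rownames(want) <- NULL
      expect_equal(got_df, want)
    }
  }
})

test_that("signature sites require seed-perfect guides and opposite-strand sense overlap", {
  set.seed(82)
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")))
  locus <- as.character(Biostrings::subseq(genome[["chr1"]], 1001, 1027))
  guide <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(locus)))
  sense <- locus
  sites <- signature_scan(c(g = guide), c(s = sense), genome)
  expect_equal(length(sites), 1L)
  expect_equal(GenomicRanges::start(sites), 1001L)
  expect_equal(sites$sense_ids, "s")
  ## a seed mismatch (read position 5) kills the guide site
  bad <- guide
  substr(bad, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(bad, 5, 5))[1]
  expect_equal(length(signature_scan(c(g = bad), c(s = sense), genome)), 0L)
  ## no sense read on the opposite strand -> no site
  expect_equal(length(signature_scan(c(g = guide),
                                     c(s = as.character(Biostrings::reverseComplement(
                                       Biostrings::DNAString(locus)))), genome)), 0L)
})

test_that("the Q30 mismatch budget allows 5 but not 6 non-seed mismatches", {
  set.seed(83)
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")))
  locus <- as.character(Biostrings::subseq(genome[["chr1"]], 501, 530))  # 30 bases
  guide <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(locus)))
  mutate <- function(g, k) {
    for (p in 10 + seq_len(k) * 3) {  # positions 13,16,... all non-seed
      substr(g, p, p) <- setdiff(c("A", "C", "G", "T"), substr(g, p, p))[1]
    }
    g
  }
  g5 <- mutate(guide, 5)  # budget 150 <= 160
  g6 <- mutate(guide, 6)  # budget 180 > 160
  expect_equal(length(pirnadev:::guide_genome_matches(c(g = g5), genome)), 1L)
  expect_equal(length(pirnadev:::guide_genome_matches(c(g = g6), genome)), 0L)
})

test_that("repeat filtering applies the consensus-length fraction", {
  reps <- data.frame(chrom = "chr1", start = c(0, 1000, 2000), strand = "+",
                     end = c(800, 1740, 2100),
                     family = c("SINE", "LINE", "LTR"),
                     element_length = c(800, 740, 100),
                     consensus_length = c(1000, 1000, NA))
  expect_warning(out <- filter_repeats(reps))
  expect_equal(out$family, "SINE")          # 0.8 kept, 0.74 dropped, NA skipped
  expect_equal(attr(out, "skipped"), 1L)
  ## exact 75% boundary is kept; monotone in the threshold
  reps2 <- data.frame(element_length = c(750, 749), consensus_length = 1000,
                      chrom = "chr1", start = 0, end = 1, strand = "+",
                      family = "SINE")
  expect_equal(nrow(filter_repeats(reps2)), 1L)
  expect_lte(nrow(filter_repeats(reps2, min_fraction = 0.9)),
             nrow(filter_repeats(reps2, min_fraction = 0.75)))
})

test_that("target annotation reports each feature once and tallies families", {
  sites <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(100, 150, 5000), width = 27),
                                  strand = "-",
                                  guide_id = c("g1", "g2", "g3"))
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 400), gene_id = "geneA")
  reps <- data.frame(chrom = "chr1", start = 4990, end = 5100, strand = "+",
                     family = "SINE", element_length = 110, consensus_length = 120)
  res <- annotate_targets(sites, genes, reps)
  expect_equal(res$mrna_targets, "geneA")   # two supporting sites, listed once
  expect_equal(unname(res$repeat_family_counts["SINE"]), 1L)
  expect_equal(res$unannotated, 0L)
  res2 <- annotate_targets(GenomicRanges::GRanges("chr1",
                                                  IRanges::IRanges(9000, 9027)),
                           genes, reps)
  expect_equal(res2$unannotated, 1L)
})
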