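test_that("reference generation honours cluster count, class mix and determinism", {
  cfg <- simulation_config(genome_length = 1.2e6, n_chromosomes = 2L,
                           n_clusters = 214L,
                           cluster_length_range = c(400L, 600L),
                           intergenic_fraction = 0.75,
                           n_genes = 20L, n_repeats = 10L, n_ncrna = 4L,
                           rng_seed = 13L)
  ref <- generate_reference(cfg)
  expect_equal(length(ref$clusters), 214L)
  realized <- mean(ref$clusters$klass == "intergenic")
  expect_lte(abs(realized - 0.75), 1 / 214)
  ## clusters are non-overlapping
  self <- GenomicRanges::findOverlaps(ref$clusters, ref$clusters,
                                      ignore.strand = TRUE)
  expect_equal(length(self), length(ref$clusters))
  ## identical seed => identical bundle
  ref2 <- generate_reference(cfg)
  expect_identical(as.character(ref$genome), as.character(ref2$genome))
  expect_identical(as.data.frame(ref$clusters), as.data.frame(ref2$clusters))
  expect_identical(ref$genes, ref2$genes)
})

test_that("degenerate configurations behave as specified", {
  cfg0 <- simulation_config(genome_length = 5e4, n_chromosomes = 1L,
                            n_clusters = 0L, n_genes = 3L, n_repeats = 2L,
                            n_ncrna = 1L, rng_seed = 3L)
  ref0 <- generate_reference(cfg0)
  expect_equal(length(ref0$clusters), 0L)
  expect_gt(sum(GenomicRanges::width(ref0$genome) > 0), 0)
  ## clusters that cannot fit raise a configuration error
  cfg_bad <- simulation_config(genome_length = 20000, n_chromosomes = 1L,
                               n_clusters = 40L,
                               cluster_length_range = c(800L, 1200L),
                               rng_seed = 3L)
  expect_error(generate_reference(cfg_bad), "fit")
})

test_that("sample simulation honours the profile and records full truth", {
  ref <- make_test_reference()
  ## u1_fraction = 1: every cluster-derived insert starts with T
  prof <- stage_profile("all_t", 2000, cluster_read_fraction = 0.5,
                        u1_fraction = 1.0)
  smp <- simulate_small_rna_sample(ref, prof, seed = 5L)
  from_cl <- smp$truth$origin != "background"
  expect_true(all(substr(smp$truth$seq[from_cl], 1, 1) == "T"))
  ## truth conservation and determinism
  expect_equal(length(smp$truth), nrow(smp$reads))
  smp2 <- simulate_small_rna_sample(ref, prof, seed = 5L)
  expect_identical(smp$reads, smp2$reads)
  expect_identical(as.data.frame(smp$truth), as.data.frame(smp2$truth))
  ## point-mass length mixture
  prof26 <- stage_profile("mono", 500, cluster_read_fraction = 0.3,
                          u1_fraction = 0.5,
                          length_mixture = data.frame(length = 26L, weight = 1))
  smp26 <- simulate_small_rna_sample(ref, prof26, seed = 6L)
  expect_true(all(GenomicRanges::width(smp26$truth) == 26L))
  ## truth intervals reproduce the genome sequence
  idx <- sample(length(smp$truth), 50)
  for (i in idx) {
    g <- smp$truth[i]
    chrom <- as.character(GenomicRanges::seqnames(g))
    s <- as.character(Biostrings::subseq(ref$genome[[chrom]],
                                         GenomicRanges::start(g),
                                         GenomicRanges::end(g)))
    if (as.character(GenomicRanges::strand(g)) == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(g$seq, s)
  }
})

test_that("the in-cluster truth fraction falls in the exact binomial interval", {
  ref <- make_test_reference(seed = 17L)
  prof <- stage_profile("adult_like", 50000, cluster_read_fraction = 0.07,
                        u1_fraction = 0.8)
  smp <- simulate_small_rna_sample(ref, prof, seed = 19L)
  frac <- mean(smp$truth$origin != "background")
  ## central 99% interval of Binomial(50000, 0.07) / 50000:
  ## qbinom(0.005,...) = 3354, qbinom(0.995,...) = 3648
  expect_gte(frac, 3354 / 50000)
  expect_lte(frac, 3648 / 50000)
})

test_that("shared pools share sequences and disjoint pools do not", {
  ref <- make_test_reference(seed = 23L, n_clusters = 6L,
                             pools = list(left = 1:3, right = 4:6),
                             genome_length = 6e5)
  mkprof <- function(id, pool) stage_profile(id, 20000,
                                             cluster_read_fraction = 0.6,
                                             u1_fraction = 0.8,
                                             shared_pool_id = pool)
  a <- simulate_small_rna_sample(ref, mkprof("a", "left"), seed = 1L)
  b <- simulate_small_rna_sample(ref, mkprof("b", "left"), seed = 2L)
  c3 <- simulate_small_rna_sample(ref, mkprof("c", "right"), seed = 3L)
  seqs <- function(s) s$truth$seq[s$truth$origin != "background"]
  expect_gte(shared_sequence_fraction(seqs(a), seqs(b)), 0.8)
  expect_lte(shared_sequence_fraction(seqs(a), seqs(c3)), 0.05)
})

test_that("CTSS simulation places tags only in active promoters, deterministically", {
  ref <- make_test_reference(seed = 29L)
  genes <- unique(ref$genes$gene_id)
  tpm <- setNames(rep(0, length(genes)), genes)
  tpm[seq(1, length(genes), by = 2)] <- c(5, 20, 1, 8, 3)[seq_along(seq(1, length(genes), by = 2))]
  tpm[is.na(tpm)] <- 0
  tab <- simulate_ctss_sample(ref, tpm, alpha = 1.25, total_tags = 5000,
                              seed = 31L)
  expect_gte(sum(tab$count), 5000)
  ## silent genes get no tags in their promoter windows
  silent <- names(tpm)[tpm == 0]
  for (g in silent) {
    rows <- ref$genes[ref$genes$gene_id == g, ]
    for (j in seq_len(nrow(rows))) {
      lo <- rows$tss[j] - 1000; hi <- rows$tss[j] + 1000
      hitting <- tab$chrom == rows$chrom[j] & tab$pos >= lo & tab$pos <= hi
      expect_equal(sum(tab$count[hitting]), 0L)
    }
  }
  tab2 <- simulate_ctss_sample(ref, tpm, alpha = 1.25, total_tags = 5000,
                               seed = 31L)
  expect_identical(tab, tab2)
})

test_that("synthetic bundles round-trip through their file formats", {
  ref <- make_test_reference(seed = 37L)
  prof <- stage_profile("io", 300, cluster_read_fraction = 0.4,
                        u1_fraction = 0.8)
  smp <- simulate_small_rna_sample(ref, prof, seed = 39L)
  dir <- tempfile("bundle")
  paths <- write_synthetic_bundle(ref, smp, dir)
  expect_true(all(file.exists(paths)))
  cl <- read_clusters_bed(paths["clusters"])
  expect_equal(as.character(cl$cluster_id), as.character(ref$clusters$cluster_id))
  expect_equal(as.character(cl$klass), as.character(ref$clusters$klass))
  expect_equal(GenomicRanges::start(cl), GenomicRanges::start(ref$clusters))
  reads <- read_fastq(paths["fastq"])
  expect_equal(reads$sequence, smp$reads$sequence)
  aln <- read_alignments(paths["truth_bed"])
  expect_equal(GenomicRanges::start(aln), GenomicRanges::start(smp$truth))
  expect_equal(as.character(GenomicRanges::strand(aln)),
               as.character(GenomicRanges::strand(smp$truth)))
})

test_that("SAM alignments parse to the same intervals as BED", {
  ## a tiny hand-written SAM with one + and one - strand record
  sam <- c("@HD\tVN:1.6\t SO:unsorted",
           "@SQ\tSN:chr1\tLN:10000",
           paste("r1", 0, "chr1", 101, 42, "27M", "*", 0, 0,
                 strrep("A", 27), strrep("I", 27), sep = "\t"),
           paste("r2", 16, "chr1", 201, 42, "27M", "*", 0, 0,
                 strrep("C", 27), strrep("I", 27), sep = "\t"))
  sam[1] <- "@HD\tVN:1.6\tSO:unsorted"
  f <- tempfile(fileext = ".sam")
  writeLines(sam, f)
  gr <- read_alignments(f)
  expect_equal(GenomicRanges::start(gr), c(101L, 201L))
  expect_equal(GenomicRanges::end(gr), c(127L, 227L))
  expect_equal(as.character(GenomicRanges::strand(gr)), c("+", "-"))
  expect_equal(gr$read_id, c("r1", "r2"))
  expect_equal(gr$seq[1], strrep("A", 27))
})
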