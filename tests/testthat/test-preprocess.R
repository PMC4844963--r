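adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("quality truncation keeps the longest all-high-quality prefix", {
  reads <- data.frame(
    read_id = c("clean", "mid", "first", "boundary"),
    sequence = c("ACGT", "ACGT", "ACG", "ACGT"),
    quality = c(qual_string(c(30, 30, 30, 30)),
                qual_string(c(30, 30, 15, 30)),
                qual_string(c(10, 30, 30)),
                qual_string(c(30, 30, 16, 16))),
    stringsAsFactors = FALSE)
  out <- truncate_at_low_quality(reads, qmin = 15L)
  expect_equal(out$sequence, c("ACGT", "AC", "", "ACGT"))
  expect_equal(out$quality_trimmed, c(0L, 2L, 3L, 0L))
  expect_equal(nchar(out$quality), nchar(out$sequence))
})

test_that("quality truncation is idempotent", {
  set.seed(5)
  n <- 200
  reads <- data.frame(
    read_id = paste0("r", seq_len(n)),
    sequence = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""), character(1)),
    quality = vapply(seq_len(n), function(i)
      qual_string(sample(c(10L, 30L, 35L), 40, TRUE, prob = c(0.1, 0.6, 0.3))),
      character(1)),
    stringsAsFactors = FALSE)
  once <- truncate_at_low_quality(reads)
  twice <- truncate_at_low_quality(once)
  expect_equal(twice$sequence, once$sequence)
  expect_equal(twice$quality, once$quality)
  expect_true(all(twice$quality_trimmed == 0L))
})

test_that("insert extraction strips barcode and adapter and gates length", {
  insert28 <- strrep("ACGTCCA", 4)  # 28 bases
  fixture <- make_raw_read("full", insert28, adapter = adapter)  # 4+28+8 layout
  expect_equal(nchar(fixture$sequence), 40L)
  res <- extract_small_rna_insert(fixture, adapter = adapter)
  expect_equal(res$retained$insert, insert28)
  expect_equal(res$retained$adapter_removed, 8L)

  ## no adapter at the 3' end -> discarded
  no_ad <- data.frame(read_id = "noad",
                      sequence = paste0("ACGT", strrep("ACGTCCA", 4), "CCCCCCCC"),
                      quality = strrep("?", 40), stringsAsFactors = FALSE)
  res <- extract_small_rna_insert(no_ad, adapter = adapter)
  expect_equal(nrow(res$retained), 0L)
  expect_equal(res$discarded$reason, "no_adapter")

  ## insert of exactly 24 discarded, 25 retained
  for (L in c(24L, 25L)) {
    r <- make_raw_read(paste0("len", L), strrep("A", L), adapter = adapter)
    res <- extract_small_rna_insert(r, adapter = adapter)
    if (L == 24L) {
      expect_equal(res$discarded$reason, "short_insert")
    } else {
      expect_equal(nchar(res$retained$insert), 25L)
    }
  }

  ## read shorter than the barcode
  tiny <- data.frame(read_id = "tiny", sequence = "AC", quality = "??",
                     stringsAsFactors = FALSE)
  res <- extract_small_rna_insert(tiny, adapter = adapter)
  expect_equal(res$discarded$reason, "too_short_for_barcode")

  ## N never matches the adapter
  nread <- make_raw_read("n", strrep("A", 27), adapter = adapter)
  substr(nread$sequence, 32, 32) <- "N"  # first adapter base in the read
  res <- extract_small_rna_insert(nread, adapter = adapter)
  expect_true(nrow(res$retained) == 0L || res$retained$adapter_removed < 9L)
})

test_that("preprocessing conserves read counts across categories", {
  set.seed(9)
  n <- 300
  reads <- do.call(rbind, lapply(seq_len(n), function(i) {
    L <- sample(20:35, 1)
    ins <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    r <- make_raw_read(paste0("r", i), ins, adapter = adapter)
    if (runif(1) < 0.2) {  # plant a low-quality tail
      j <- sample(nchar(r$sequence), 1)
      substr(r$quality, j, nchar(r$sequence)) <-
        strrep(qual_string(10L), nchar(r$sequence) - j + 1L)
    }
    r
  }))
  res <- preprocess_small_rna(reads, adapter = adapter)
  expect_equal(res$report$retained +
                 res$report$too_short_for_barcode +
                 res$report$no_adapter +
                 res$report$short_insert,
               res$report$input)
  expect_true(all(nchar(res$retained$insert) >= 25 &
                    nchar(res$retained$insert) <= 35))
})

test_that("CAGE forward-mate trimming is positional with a >15-base gate", {
  mates <- data.frame(
    read_id = c("m25", "m24", "m8", "noG"),
    sequence = c(strrep("A", 25), strrep("A", 24), strrep("A", 8),
                 paste0("ACACACTTT", strrep("G", 20))),
    quality = c(strrep("?", 25), strrep("?", 24), strrep("?", 8), strrep("?", 29)),
    stringsAsFactors = FALSE)
  res <- extract_cage_forward_mate(mates)
  expect_equal(res$retained$read_id, c("m25", "noG"))
  expect_equal(nchar(res$retained$sequence), c(16L, 20L))
  expect_setequal(res$discarded$reason, c("short_mate", "too_short_for_prefix"))
  ## trimming ignores whether positions 7-9 are G
  expect_equal(res$retained$sequence[2], strrep("G", 20))
})

test_that("FASTQ round-trips and Phred+64 input is re-encoded", {
  reads <- make_raw_read("rt", strrep("ACGT", 7), adapter = adapter)
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_equal(back, reads)
  ## re-encode the same scores as Phred+64 and read with the flag
  q64 <- intToUtf8(utf8ToInt(reads$quality) + 31L)
  writeLines(c(paste0("@", reads$read_id), reads$sequence, "+", q64), f)
  back64 <- read_fastq(f, quality_encoding = "phred64")
  expect_equal(back64$quality, reads$quality)
})
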