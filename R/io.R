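## File-format I/O.  Reads are carried as a plain data.frame with columns
## read_id / sequence / quality (quality = Phred+33 string), alignments and
## clusters as GRanges, tag and annotation tables as data.frames.

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (uncompressed or gzip).
#' @param quality_encoding `"phred33"` (default) or `"phred64"`; Phred+64
#'   qualities are re-encoded to Phred+33 on input so all downstream code
#'   works on a single scale.
#' @return A data.frame with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path, quality_encoding = c("phred33", "phred64")) {
  quality_encoding <- match.arg(quality_encoding)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: line count not a multiple of 4")
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  ids <- sub("\\s.*$", "", ids)
  seqs <- lines[seq(2, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  if (quality_encoding == "phred64") quals <- shift_quality(quals, -31L)
  data.frame(read_id = ids, sequence = toupper(seqs), quality = quals,
             stringsAsFactors = FALSE)
}

#' Write a read table as FASTQ (Phred+33)
#'
#' @param reads Read table as returned by [read_fastq()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), by = 4)] <- paste0("@", reads$read_id)
  out[seq(2, length(out), by = 4)] <- reads$sequence
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

## Shift an ASCII-encoded quality string by a fixed offset.
shift_quality <- function(qual, offset) {
  vapply(qual, function(q) {
    intToUtf8(utf8ToInt(q) + offset)
  }, character(1), USE.NAMES = FALSE)
}

## Decode a Phred+33 quality string to integer scores.
quality_scores <- function(qual) {
  lapply(qual, function(q) if (nzchar(q)) utf8ToInt(q) - 33L else integer(0))
}

#' Read a piRNA-cluster BED6 file
#'
#' The BED name field carries `"<cluster_id>;<class>"` where class is
#' `genic` or `intergenic`.
#'
#' @param path BED6 file (0-based half-open).
#' @return A `GRanges` with metadata columns `cluster_id` and `klass`.
#' @export
read_clusters_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- strsplit(as.character(gr$name), ";", fixed = TRUE)
  gr$cluster_id <- vapply(nm, `[`, character(1), 1L)
  gr$klass <- vapply(nm, function(x) if (length(x) > 1L) x[2L] else NA_character_, character(1))
  gr$name <- NULL
  gr
}

#' Write piRNA clusters as BED6
#' @param clusters `GRanges` with `cluster_id` and `klass` metadata columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clusters_bed <- function(clusters, path) {
  out <- clusters
  out$name <- paste(out$cluster_id, out$klass, sep = ";")
  out$score <- 0L
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read genomic alignments from BED6 or SAM
#'
#' BED input is 0-based half-open with the read identifier in the name
#' field; SAM input is parsed through Rsamtools (coordinates converted to
#' the same internal 1-based `GRanges` representation).  Unmapped SAM
#' records are dropped.
#'
#' @param path Alignment file; format chosen by extension (`.bed`, `.sam`,
#'   `.bam`) unless `format` is given.
#' @param format Optional override: `"bed"`, `"sam"` or `"bam"`.
#' @return A `GRanges` with metadata columns `read_id` and (for SAM/BAM)
#'   `seq` holding the read sequence.
#' @export
read_alignments <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    gr$read_id <- as.character(gr$name)
    gr$name <- NULL
    return(gr)
  }
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    path <- bam
  } else if (format != "bam") {
    stop("unsupported alignment format: ", format)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "strand", "seq", "qwidth"),
                               flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  rec <- Rsamtools::scanBam(path, param = p)[[1]]
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(rec$rname),
    ranges = IRanges::IRanges(start = rec$pos, width = rec$qwidth),
    strand = rec$strand,
    read_id = rec$qname
  )
  gr$seq <- as.character(rec$seq)
  gr
}

#' Write alignments as BED6
#' @param alignments `GRanges` with a `read_id` metadata column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignments_bed <- function(alignments, path) {
  out <- alignments
  out$name <- out$read_id
  out$score <- 0L
  keep <- c("name", "score")
  S4Vectors::mcols(out) <- S4Vectors::mcols(out)[, keep]
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read / write a CTSS tag table
#'
#' Four tab-separated columns (`chrom`, `pos`, `strand`, `count`), position
#' 0-based single-base; a fifth `tpm` column is written when present.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_ctss <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_ctss
#' @param ctss CTSS data.frame.
#' @export
write_ctss <- function(ctss, path) {
  write.table(ctss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-model table
#'
#' Tab-separated with columns `gene_id`, `chrom`, `strand`, `tss`
#' (one row per transcription start site; genes repeat across rows).
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_gene_models <- function(path) {
  gm <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "chrom", "strand", "tss") %in% names(gm)))
  gm
}

#' Read a repeat-annotation table
#'
#' Tab-separated columns `chrom`, `start`, `end`, `strand`, `family`,
#' `element_length`, `consensus_length` (0-based half-open intervals).
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_repeats <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
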