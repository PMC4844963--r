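## Synthetic study generator.
##
## Builds a miniature genome with non-overlapping piRNA clusters
## (genic/intergenic), gene models, repeat annotation and an ncRNA set,
## then simulates stage/tissue small-RNA samples (raw FASTQ layout:
## 4-base barcode + endogenous insert + 3' adapter, Phred+33 qualities)
## and CAGE CTSS tag tables, with complete ground truth so every
## downstream stage of the pipeline can be validated.
##
## Sample-to-sample structure is controlled by "pools": a pool is a fixed
## population of candidate insert loci inside a subset of clusters,
## derived deterministically from the reference seed and the pool id.
## Samples sharing a pool id draw inserts from the same candidate
## population and therefore share sequences; samples with different pools
## (e.g. over disjoint cluster subsets) do not.

DEFAULT_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

#' Simulation configuration
#'
#' @param genome_length Total genome size in bases (split across
#'   chromosomes).
#' @param n_chromosomes Number of chromosomes.
#' @param n_clusters Number of piRNA clusters to place (non-overlapping).
#' @param cluster_length_range Two-element integer range of cluster
#'   lengths in bases.
#' @param intergenic_fraction Fraction of clusters labeled intergenic
#'   (the realized fraction is within `1/n_clusters` of this).
#' @param n_genes Number of gene models (genic clusters get an
#'   overlapping gene; the remainder are background genes).
#' @param n_repeats Number of repeat elements.
#' @param n_ncrna Number of ncRNA sequences in the contamination set.
#' @param pools Named list mapping pool id to the integer indices of the
#'   clusters feeding that pool; `NULL` gives a single pool `"all"` over
#'   every cluster.
#' @param pool_candidates_t,pool_candidates_nont Candidate insert loci per
#'   cluster whose first (5') base is / is not T (defaults 20 and 40).
#' @param duplicate_fraction Fraction of clusters whose sequence is
#'   copied to a second locus, so their reads multi-map (default 0.05).
#' @param adapter 3' adapter sequence ligated to every raw read.
#' @param read_length Platform read length in bases (default 40).
#' @param low_quality_rate Per-read probability of a low-quality (Q10)
#'   tail starting at a uniform position (default 0.05); all other bases
#'   are Q30.
#' @param rng_seed Integer seed; identical configuration and seed give
#'   byte-identical output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 5e6,
                              n_chromosomes = 2L,
                              n_clusters = 12L,
                              cluster_length_range = c(1500L, 3000L),
                              intergenic_fraction = 0.75,
                              n_genes = 40L,
                              n_repeats = 30L,
                              n_ncrna = 10L,
                              pools = NULL,
                              pool_candidates_t = 20L,
                              pool_candidates_nont = 40L,
                              duplicate_fraction = 0.05,
                              adapter = DEFAULT_ADAPTER,
                              read_length = 40L,
                              low_quality_rate = 0.05,
                              rng_seed = 1L) {
  stopifnot_scalar_prob(intergenic_fraction, "intergenic_fraction")
  stopifnot_scalar_prob(duplicate_fraction, "duplicate_fraction")
  stopifnot_scalar_prob(low_quality_rate, "low_quality_rate")
  stopifnot(genome_length >= 1000, n_chromosomes >= 1, n_clusters >= 0,
            length(cluster_length_range) == 2L,
            cluster_length_range[1] >= 200,
            cluster_length_range[1] <= cluster_length_range[2],
            is_string(adapter), read_length >= 20)
  if (is.null(pools)) {
    pools <- if (n_clusters > 0) list(all = seq_len(n_clusters)) else list()
  }
  for (p in pools) {
    if (length(p) && (min(p) < 1 || max(p) > n_clusters))
      stop("pool refers to cluster indices outside 1..n_clusters")
  }
  structure(list(genome_length = genome_length, n_chromosomes = n_chromosomes,
                 n_clusters = n_clusters,
                 cluster_length_range = as.integer(cluster_length_range),
                 intergenic_fraction = intergenic_fraction,
                 n_genes = n_genes, n_repeats = n_repeats, n_ncrna = n_ncrna,
                 pools = pools,
                 pool_candidates_t = pool_candidates_t,
                 pool_candidates_nont = pool_candidates_nont,
                 duplicate_fraction = duplicate_fraction,
                 adapter = toupper(adapter), read_length = as.integer(read_length),
                 low_quality_rate = low_quality_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

#' Stage/tissue sample profile
#'
#' Encodes the signal structure of one small-RNA sample: how many reads,
#' what fraction originate inside piRNA clusters, the first-base U bias of
#' the cluster-derived population, the insert-length mixture, and which
#' candidate pool the cluster inserts are drawn from.
#'
#' @param sample_id Sample label, e.g. `"brain_adult"`.
#' @param n_reads Number of raw reads to emit.
#' @param cluster_read_fraction Probability a read originates inside a
#'   cluster (the rest are uniform genomic background).
#' @param u1_fraction Probability a cluster-derived insert begins with
#'   T/U.
#' @param length_mixture data.frame (or 2-column matrix) of `length`
#'   (modal insert lengths, within 25..35) and `weight` (summing to 1).
#' @param shared_pool_id Pool id (must exist in the configuration's
#'   `pools`).
#' @return A list of class `stage_profile`.
#' @export
stage_profile <- function(sample_id, n_reads,
                          cluster_read_fraction, u1_fraction,
                          length_mixture = data.frame(length = c(26L, 27L),
                                                      weight = c(0.5, 0.5)),
                          shared_pool_id = "all") {
  stopifnot_scalar_prob(cluster_read_fraction, "cluster_read_fraction")
  stopifnot_scalar_prob(u1_fraction, "u1_fraction")
  length_mixture <- as.data.frame(length_mixture)
  stopifnot(is_string(sample_id), n_reads >= 1,
            all(c("length", "weight") %in% names(length_mixture)),
            all(length_mixture$length >= 25 & length_mixture$length <= 35))
  if (abs(sum(length_mixture$weight) - 1) > 1e-8)
    stop("length_mixture weights must sum to 1")
  structure(list(sample_id = sample_id, n_reads = as.integer(n_reads),
                 cluster_read_fraction = cluster_read_fraction,
                 u1_fraction = u1_fraction,
                 length_mixture = length_mixture,
                 shared_pool_id = shared_pool_id),
            class = "stage_profile")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate the synthetic reference bundle
#'
#' Genome sequences, non-overlapping cluster annotation with
#' genic/intergenic classes, gene models (every genic cluster overlaps a
#' gene), repeat annotation with family consensus lengths, an ncRNA
#' contamination set, and per-pool candidate insert loci.  A
#' `duplicate_fraction` of clusters have their sequence copied to a
#' reserved spacer region so that their reads multi-map.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_reference`: `genome`
#'   (`DNAStringSet`), `clusters` (`GRanges` with `cluster_id`, `klass`),
#'   `genes` (data.frame `gene_id`, `chrom`, `strand`, `tss`, `start`,
#'   `end`), `repeats` (data.frame), `ncrna` (`DNAStringSet`), `pools`
#'   (per-pool candidate tables), `duplicates` (data.frame mapping
#'   duplicated clusters to their copy locus), `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  chrom_len <- rep(floor(config$genome_length / config$n_chromosomes),
                   config$n_chromosomes)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  genome_chr <- setNames(vapply(chrom_len, random_dna, character(1)), chroms)

  ## --- place non-overlapping clusters (round-robin over chromosomes,
  ## with a reserved tail on chr1 for duplicate copies) ---
  n <- config$n_clusters
  reserve <- 4L * config$cluster_length_range[2]
  cl <- NULL
  if (n > 0) {
    lens <- sample(seq(config$cluster_length_range[1],
                       config$cluster_length_range[2]), n, replace = TRUE)
    chrom_of <- chroms[(seq_len(n) - 1L) %% config$n_chromosomes + 1L]
    starts <- integer(n)
    for (ci in seq_along(chroms)) {
      idx <- which(chrom_of == chroms[ci])
      if (!length(idx)) next
      avail <- chrom_len[ci] - (if (ci == 1L) reserve else 0L)
      need <- sum(lens[idx]) + 100L * (length(idx) + 1L)
      if (need > avail)
        stop("requested clusters do not fit without overlap; enlarge the genome")
      gap_space <- avail - sum(lens[idx])
      gaps <- floor(gap_space * diff(c(0, sort(runif(length(idx))), 1)))
      pos <- 1L
      for (j in seq_along(idx)) {
        pos <- pos + gaps[j]
        starts[idx[j]] <- pos
        pos <- pos + lens[idx[j]]
      }
    }
    n_inter <- round(config$intergenic_fraction * n)
    klass <- rep("genic", n)
    klass[sample.int(n, n_inter)] <- "intergenic"
    cl <- GenomicRanges::GRanges(chrom_of,
                                 IRanges::IRanges(starts, width = lens),
                                 cluster_id = sprintf("cluster_%03d", seq_len(n)),
                                 klass = klass)
  } else {
    cl <- GenomicRanges::GRanges(cluster_id = character(0), klass = character(0))
  }

  ## --- duplicate a fraction of cluster sequences into the reserved tail ---
  dup <- data.frame(cluster_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  n_dup <- if (n > 0) floor(config$duplicate_fraction * n) else 0L
  if (n_dup > 0) {
    pick <- sort(sample.int(n, n_dup))
    pos <- chrom_len[1] - reserve + 50L
    for (i in pick) {
      seq_i <- substr(genome_chr[[as.character(GenomicRanges::seqnames(cl[i]))]],
                      GenomicRanges::start(cl[i]), GenomicRanges::end(cl[i]))
      substr(genome_chr[[1L]], pos, pos + nchar(seq_i) - 1L) <- seq_i
      dup <- rbind(dup, data.frame(cluster_id = cl$cluster_id[i],
                                   chrom = chroms[1L], start = pos,
                                   end = pos + nchar(seq_i) - 1L,
                                   stringsAsFactors = FALSE))
      pos <- pos + nchar(seq_i) + 100L
    }
  }

  ## --- gene models: one gene over each genic cluster + background genes ---
  genes <- list()
  gi <- 0L
  if (n > 0) {
    for (i in which(cl$klass == "genic")) {
      gi <- gi + 1L
      strand <- sample(c("+", "-"), 1L)
      gs <- max(1L, GenomicRanges::start(cl[i]) - 500L)
      ge <- GenomicRanges::end(cl[i]) + 500L
      n_tss <- sample(1:3, 1L)
      tss <- if (strand == "+") gs + sort(sample(0:300, n_tss)) else ge - sort(sample(0:300, n_tss))
      genes[[gi]] <- data.frame(gene_id = sprintf("gene_%03d", gi),
                                chrom = as.character(GenomicRanges::seqnames(cl[i])),
                                strand = strand, tss = tss, start = gs, end = ge,
                                stringsAsFactors = FALSE)
    }
  }
  n_bg <- max(config$n_genes - gi, 0L)
  occupied <- GenomicRanges::reduce(c(GenomicRanges::granges(cl),
                                      GenomicRanges::GRanges(dup$chrom,
                                                             IRanges::IRanges(dup$start, dup$end))))
  tries <- 0L
  while (n_bg > 0 && tries < 50L * config$n_genes) {
    tries <- tries + 1L
    ci <- sample.int(config$n_chromosomes, 1L)
    glen <- sample(2000:6000, 1L)
    gs <- sample.int(max(chrom_len[ci] - glen - 2000L, 1L), 1L) + 1000L
    cand <- GenomicRanges::GRanges(chroms[ci], IRanges::IRanges(gs - 1500L, gs + glen + 1500L))
    if (length(GenomicRanges::findOverlaps(cand, occupied))) next
    occupied <- GenomicRanges::reduce(c(occupied, cand))
    gi <- gi + 1L
    strand <- sample(c("+", "-"), 1L)
    n_tss <- sample(1:2, 1L)
    tss <- if (strand == "+") gs + sort(sample(0:200, n_tss)) else (gs + glen) - sort(sample(0:200, n_tss))
    genes[[gi]] <- data.frame(gene_id = sprintf("gene_%03d", gi),
                              chrom = chroms[ci], strand = strand, tss = tss,
                              start = gs, end = gs + glen,
                              stringsAsFactors = FALSE)
    n_bg <- n_bg - 1L
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(0), chrom = character(0), strand = character(0),
               tss = integer(0), start = integer(0), end = integer(0))

  ## --- repeats: element length drawn relative to family consensus so the
  ## 75%-of-consensus filter has both outcomes ---
  consensus <- c(SINE = 300L, LINE = 6000L, LTR = 500L, other = 1000L)
  reps <- NULL
  if (config$n_repeats > 0) {
    fam <- sample(names(consensus), config$n_repeats, replace = TRUE)
    frac <- runif(config$n_repeats, 0.4, 1.0)
    elen <- pmax(50L, as.integer(round(frac * consensus[fam])))
    ci <- sample.int(config$n_chromosomes, config$n_repeats, replace = TRUE)
    rs <- vapply(seq_len(config$n_repeats), function(i) {
      sample.int(max(chrom_len[ci[i]] - elen[i] - 1L, 1L), 1L)
    }, integer(1))
    reps <- data.frame(chrom = chroms[ci], start = rs - 1L, end = rs - 1L + elen,
                       strand = sample(c("+", "-"), config$n_repeats, replace = TRUE),
                       family = fam, element_length = elen,
                       consensus_length = unname(consensus[fam]),
                       stringsAsFactors = FALSE)
  } else {
    reps <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                       strand = character(0), family = character(0),
                       element_length = integer(0), consensus_length = integer(0))
  }

  ncrna <- Biostrings::DNAStringSet(
    setNames(vapply(rep(150L, config$n_ncrna), random_dna, character(1)),
             if (config$n_ncrna > 0) sprintf("ncRNA_%02d", seq_len(config$n_ncrna)) else NULL))

  ref <- structure(list(genome = Biostrings::DNAStringSet(genome_chr),
                        clusters = cl, genes = genes, repeats = reps,
                        ncrna = ncrna, duplicates = dup, config = config),
                   class = "synthetic_reference")
  ref$pools <- lapply(setNames(names(config$pools), names(config$pools)),
                      function(pid) build_pool(ref, pid))
  ref
}

#' @export
print.synthetic_reference <- function(x, ...) {
  cat("Synthetic reference:", sum(GenomeInfoDb::seqlengths(x$genome)),
      "bp over", length(x$genome), "chromosome(s);",
      length(x$clusters), "clusters (",
      sum(x$clusters$klass == "intergenic"), "intergenic ),",
      length(unique(x$genes$gene_id)), "genes,",
      nrow(x$repeats), "repeats\n")
  invisible(x)
}

## Candidate insert loci for one pool: per cluster, fixed numbers of
## T-starting and non-T-starting 5' positions (strand-aware), each with
## >= 35 bases of room inside the cluster.  Candidates are deterministic
## in the reference seed and the cluster (not the pool id), so pools
## that share clusters share insert populations — e.g. the clusters
## active in brain being a subset of those active in testes.
build_pool <- function(reference, pool_id) {
  cfg <- reference$config
  idx <- cfg$pools[[pool_id]]
  if (is.null(idx)) stop("unknown pool id: ", pool_id)
  out <- list()
  for (i in idx) {
    cl <- reference$clusters[i]
    set.seed(derive_seed(cfg$rng_seed, paste0("cluster-pool:", cl$cluster_id)))
    chrom <- as.character(GenomicRanges::seqnames(cl))
    s <- GenomicRanges::start(cl); e <- GenomicRanges::end(cl)
    seq_fwd <- substr(as.character(reference$genome[[chrom]]), s, e)
    b <- strsplit(seq_fwd, "")[[1]]
    L <- length(b)
    ## + strand candidates need room [pos, pos+34]; - strand need [pos-34, pos]
    plus_ok <- seq_len(L - 35L)
    minus_ok <- seq(36L, L)
    ## first base on + strand is b[pos]; on - strand it is complement(b[pos])
    cand <- rbind(
      data.frame(rel = plus_ok, strand = "+", first = b[plus_ok]),
      data.frame(rel = minus_ok, strand = "-",
                 first = chartr("ACGT", "TGCA", b[minus_ok])))
    t_pool <- cand[cand$first == "T", , drop = FALSE]
    n_pool <- cand[cand$first != "T", , drop = FALSE]
    pick <- function(df, k) df[sample.int(nrow(df), min(k, nrow(df))), , drop = FALSE]
    sel <- rbind(cbind(pick(t_pool, cfg$pool_candidates_t), is_t = TRUE),
                 cbind(pick(n_pool, cfg$pool_candidates_nont), is_t = FALSE))
    sel$chrom <- chrom
    sel$pos <- s + sel$rel - 1L   # genomic 5'-most coordinate (1-based)
    sel$cluster_id <- cl$cluster_id
    out[[cl$cluster_id]] <- sel[, c("cluster_id", "chrom", "pos", "strand", "is_t")]
  }
  out
}

## Extract the read sequence for a candidate locus and insert length.
insert_sequence <- function(genome, chrom, pos, strand, len) {
  if (strand == "+") {
    as.character(Biostrings::subseq(genome[[chrom]], pos, pos + len - 1L))
  } else {
    revcomp(as.character(Biostrings::subseq(genome[[chrom]], pos - len + 1L, pos)))
  }
}

#' Simulate one small-RNA sample
#'
#' Emits raw reads (barcode + insert + adapter, truncated to the platform
#' read length, Phred+33 qualities) together with per-read truth: the
#' originating genomic alignment and cluster (or background).  Cluster
#' reads are drawn from the profile's pool — Bernoulli(u1_fraction)
#' chooses between the pool's T-starting and non-T-starting candidates —
#' with insert lengths from the profile's mixture; background reads come
#' from uniform genomic positions.  Reads from duplicated clusters get an
#' additional alignment at the copy locus (the truth record stays
#' unique).
#'
#' @param reference A [generate_reference()] bundle.
#' @param profile A [stage_profile()].
#' @param seed Integer seed for this sample.
#' @return A list of class `synthetic_sample`: `reads` (FASTQ-ready
#'   data.frame), `truth` (`GRanges`, one record per read, metadata
#'   `read_id`, `origin`), `alignments` (`GRanges` including duplicate
#'   loci), `expressed_clusters` (the pool's cluster ids when
#'   `cluster_read_fraction > 0`), `profile`.
#' @export
simulate_small_rna_sample <- function(reference, profile, seed = 1L) {
  stopifnot(inherits(reference, "synthetic_reference"),
            inherits(profile, "stage_profile"))
  cfg <- reference$config
  pool <- reference$pools[[profile$shared_pool_id]]
  if (profile$cluster_read_fraction > 0 &&
      (is.null(pool) || length(pool) == 0L))
    stop("cluster_read_fraction > 0 but the pool has no clusters")
  set.seed(derive_seed(seed, paste0("sample:", profile$sample_id)))

  n <- profile$n_reads
  chroms <- names(reference$genome)
  chrom_len <- GenomeInfoDb::seqlengths(reference$genome)
  if (is.null(chrom_len) || anyNA(chrom_len))
    chrom_len <- setNames(Biostrings::width(reference$genome), chroms)

  from_cluster <- runif(n) < profile$cluster_read_fraction
  mix <- profile$length_mixture
  lens <- mix$length[sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)]

  chrom <- character(n); pos <- integer(n); strand <- character(n)
  origin <- rep("background", n)
  if (any(from_cluster)) {
    pool_ids <- names(pool)
    want_t <- runif(n) < profile$u1_fraction
    which_cl <- sample(pool_ids, n, replace = TRUE)
    ## draw candidates group-wise (cluster x first-base class) so the
    ## per-read work is vectorized
    for (cid in pool_ids) {
      cand <- pool[[cid]]
      for (tt in c(TRUE, FALSE)) {
        sel <- which(from_cluster & which_cl == cid & want_t == tt)
        if (!length(sel)) next
        sub <- cand[cand$is_t == tt, , drop = FALSE]
        if (nrow(sub) == 0L) sub <- cand
        rows <- sub[sample.int(nrow(sub), length(sel), replace = TRUE), ]
        chrom[sel] <- rows$chrom; pos[sel] <- rows$pos
        strand[sel] <- rows$strand; origin[sel] <- rows$cluster_id
      }
    }
  }
  bg <- which(!from_cluster)
  if (length(bg)) {
    ci <- sample(seq_along(chroms), length(bg), replace = TRUE)
    strand[bg] <- sample(c("+", "-"), length(bg), replace = TRUE)
    L <- lens[bg]
    base <- floor(runif(length(bg)) * (chrom_len[ci] - L)) + 1L
    pos[bg] <- ifelse(strand[bg] == "+", base, base + L - 1L)
    chrom[bg] <- chroms[ci]
  }

  ## vectorized sequence extraction, per chromosome and strand
  inserts <- character(n)
  start1_tmp <- ifelse(strand == "+", pos, pos - lens + 1L)
  end_tmp <- start1_tmp + lens - 1L
  for (ch in chroms) {
    for (st in c("+", "-")) {
      sel <- which(chrom == ch & strand == st)
      if (!length(sel)) next
      v <- Biostrings::DNAStringSet(
        IRanges::Views(reference$genome[[ch]],
                       start = start1_tmp[sel], end = end_tmp[sel]))
      if (st == "-") v <- Biostrings::reverseComplement(v)
      inserts[sel] <- as.character(v)
    }
  }

  ## raw read assembly: barcode + insert + adapter, cut to read length
  barcode <- random_dna(4L)
  raw <- substr(paste0(barcode, inserts, cfg$adapter), 1L, cfg$read_length)
  qual <- strrep(intToUtf8(33L + 30L), nchar(raw))
  low <- runif(n) < cfg$low_quality_rate
  if (any(low)) {
    j <- sample.int(cfg$read_length, sum(low), replace = TRUE)
    j <- pmin(j, nchar(raw[low]))
    qual[low] <- paste0(substr(qual[low], 1L, j - 1L),
                        strrep(intToUtf8(33L + 10L), nchar(raw[low]) - j + 1L))
  }
  read_id <- sprintf("%s_read_%06d", profile$sample_id, seq_len(n))
  reads <- data.frame(read_id = read_id, sequence = raw, quality = qual,
                      stringsAsFactors = FALSE)

  start1 <- ifelse(strand == "+", pos, pos - lens + 1L)
  truth <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, width = lens),
                                  strand = strand, read_id = read_id,
                                  origin = origin)
  ## ("seq" must be assigned after construction: inside GRanges(...) the
  ## name would partially match the seqnames formal)
  truth$seq <- inserts

  alignments <- truth
  if (nrow(reference$duplicates)) {
    for (d in seq_len(nrow(reference$duplicates))) {
      drow <- reference$duplicates[d, ]
      sel <- origin == drow$cluster_id
      if (!any(sel)) next
      cl <- reference$clusters[reference$clusters$cluster_id == drow$cluster_id]
      offset <- drow$start - GenomicRanges::start(cl)
      extra <- truth[sel]
      copy <- GenomicRanges::GRanges(drow$chrom,
                                     IRanges::shift(IRanges::ranges(extra), offset),
                                     strand = GenomicRanges::strand(extra),
                                     read_id = extra$read_id,
                                     origin = extra$origin)
      copy$seq <- extra$seq
      alignments <- c(alignments, copy)
    }
  }

  structure(list(reads = reads, truth = truth, alignments = alignments,
                 expressed_clusters = if (profile$cluster_read_fraction > 0)
                   names(pool) else character(0),
                 profile = profile),
            class = "synthetic_sample")
}

#' Simulate a CAGE CTSS tag table
#'
#' Per-CTSS raw counts follow a discrete power law with reverse-cumulative
#' exponent `alpha` (`P(count >= x) = x^-alpha`); CTSS positions are
#' placed on the gene strand inside the promoter windows of genes with
#' positive truth expression, allocated proportionally to the truth tpm.
#' CTSSs are drawn until the cumulative tag count reaches `total_tags`.
#'
#' @param reference A [generate_reference()] bundle.
#' @param gene_tpm Named non-negative numeric vector of truth expression
#'   per gene id (genes with 0 receive no tags).
#' @param alpha Power-law exponent of the count distribution (> 0).
#' @param total_tags Target total tag count (> 0).
#' @param seed Integer seed.
#' @return A CTSS data.frame (`chrom`, `pos` 0-based, `strand`, `count`)
#'   with attribute `"truth_tpm"`.
#' @export
simulate_ctss_sample <- function(reference, gene_tpm, alpha = 1.25,
                                 total_tags = 1e5, seed = 1L) {
  stopifnot(inherits(reference, "synthetic_reference"),
            alpha > 0, total_tags > 0, !is.null(names(gene_tpm)))
  set.seed(derive_seed(seed, "ctss"))
  gm <- reference$genes
  active <- names(gene_tpm)[gene_tpm > 0]
  active <- intersect(active, gm$gene_id)
  if (!length(active)) stop("no active gene; cannot place tags")

  ## inverse-transform discrete power law: floor(U^(-1/alpha)), capped
  draw_counts <- function(m) pmin(floor(runif(m)^(-1 / alpha)), 1e6)
  counts <- integer(0)
  while (sum(counts) < total_tags) {
    counts <- c(counts, draw_counts(max(1000L, ceiling(total_tags / 10))))
  }
  counts <- counts[seq_len(which(cumsum(counts) >= total_tags)[1])]

  ## candidate single-base positions: +-450 of every TSS of every active
  ## gene, on the gene strand; sampled without replacement (one CTSS per
  ## position) with weight proportional to the gene's truth tpm
  pool <- do.call(rbind, lapply(active, function(g) {
    rows <- gm[gm$gene_id == g, , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(rows)), function(j) {
      data.frame(chrom = rows$chrom[j],
                 pos = rows$tss[j] + (-450L:450L),
                 strand = rows$strand[j],
                 w = gene_tpm[[g]], stringsAsFactors = FALSE)
    }))
  }))
  pool <- pool[!duplicated(pool[, c("chrom", "pos", "strand")]), ]
  if (length(counts) > nrow(pool))
    stop("more CTSSs than available promoter positions; ",
         "increase gene count or reduce total_tags")
  pick <- sample.int(nrow(pool), length(counts), prob = pool$w)
  tab <- pool[pick, c("chrom", "pos", "strand")]
  tab$count <- counts
  tab <- tab[order(tab$chrom, tab$pos, tab$strand), ]
  rownames(tab) <- NULL
  attr(tab, "truth_tpm") <- gene_tpm
  tab
}

#' Write the reference and a sample to disk
#'
#' Plain-text artifacts: genome FASTA, clusters BED6 (name field
#' `id;class`), gene-model and repeat TSVs, ncRNA FASTA, raw-read FASTQ,
#' truth-alignment BED6 and a JSON truth manifest.
#'
#' @param reference A [generate_reference()] bundle.
#' @param sample Optional [simulate_small_rna_sample()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_synthetic_bundle <- function(reference, sample = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             clusters = file.path(dir, "clusters.bed"),
             genes = file.path(dir, "genes.tsv"),
             repeats = file.path(dir, "repeats.tsv"),
             ncrna = file.path(dir, "ncrna.fa"))
  Biostrings::writeXStringSet(reference$genome, paths["genome"])
  write_clusters_bed(reference$clusters, paths["clusters"])
  write.table(reference$genes, paths["genes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(reference$repeats, paths["repeats"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  Biostrings::writeXStringSet(reference$ncrna, paths["ncrna"])
  if (!is.null(sample)) {
    paths <- c(paths,
               fastq = file.path(dir, paste0(sample$profile$sample_id, ".fastq")),
               truth_bed = file.path(dir, paste0(sample$profile$sample_id, "_truth.bed")),
               manifest = file.path(dir, paste0(sample$profile$sample_id, "_truth.json")))
    write_fastq(sample$reads, paths["fastq"])
    write_alignments_bed(sample$truth, paths["truth_bed"])
    origin_counts <- table(sample$truth$origin)
    jsonlite::write_json(
      list(sample_id = sample$profile$sample_id,
           n_reads = nrow(sample$reads),
           expressed_clusters = sample$expressed_clusters,
           origin = setNames(as.list(as.integer(origin_counts)),
                             names(origin_counts))),
      paths["manifest"], auto_unbox = TRUE)
  }
  invisible(paths)
}

#' Plant complementarity-signature target sites
#'
#' Chooses loci inside gene bodies (and optionally repeat elements),
#' emits for each a sense read equal to the genomic sequence and a guide
#' read reverse-complementary to it with a configurable number of
#' non-seed mismatches, so a downstream [signature_scan()] must recover
#' every site.
#'
#' @param reference A [generate_reference()] bundle.
#' @param n_sites Number of planted sites.
#' @param site_len Locus length in bases (default 27).
#' @param n_mismatch Non-seed mismatches introduced into each guide
#'   (default 2; must respect the scan budget to stay recoverable).
#' @param in_repeats Fraction of sites planted inside repeat elements
#'   instead of genes (default 0).
#' @param seed Integer seed.
#' @return A list: `guides`, `senses` (named character vectors), `sites`
#'   (truth `GRanges` with `guide_id`).
#' @export
plant_target_sites <- function(reference, n_sites, site_len = 27L,
                               n_mismatch = 2L, in_repeats = 0, seed = 1L) {
  stopifnot(inherits(reference, "synthetic_reference"), n_sites >= 1)
  set.seed(derive_seed(seed, "plant"))
  gm <- unique(reference$genes[, c("gene_id", "chrom", "start", "end")])
  guides <- senses <- character(n_sites)
  sites <- vector("list", n_sites)
  for (k in seq_len(n_sites)) {
    use_rep <- runif(1) < in_repeats && nrow(reference$repeats) > 0
    if (use_rep) {
      row <- reference$repeats[sample.int(nrow(reference$repeats), 1L), ]
      lo <- row$start + 1L; hi <- row$end; chrom <- row$chrom
    } else {
      row <- gm[sample.int(nrow(gm), 1L), ]
      lo <- row$start; hi <- row$end; chrom <- row$chrom
    }
    s <- sample(seq(lo, hi - site_len), 1L)
    locus <- as.character(Biostrings::subseq(reference$genome[[chrom]],
                                             s, s + site_len - 1L))
    sense <- locus                       # matches the + strand exactly
    guide <- revcomp(locus)              # perfect - strand alignment
    if (n_mismatch > 0) {
      pos <- sample(seq(11L, site_len), n_mismatch)
      gb <- strsplit(guide, "")[[1]]
      for (p in pos) gb[p] <- sample(setdiff(c("A", "C", "G", "T"), gb[p]), 1L)
      guide <- paste(gb, collapse = "")
    }
    guides[k] <- guide
    senses[k] <- sense
    sites[[k]] <- GenomicRanges::GRanges(
      factor(chrom, levels = names(reference$genome)),
      IRanges::IRanges(s, s + site_len - 1L),
      strand = "-", guide_id = sprintf("guide_%03d", k))
  }
  names(guides) <- sprintf("guide_%03d", seq_len(n_sites))
  names(senses) <- sprintf("sense_%03d", seq_len(n_sites))
  list(guides = guides, senses = senses, sites = do.call(c, sites))
}
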