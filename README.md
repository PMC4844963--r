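# pirnadev

Expression calling, characterization and target prediction for
PIWI-interacting RNA (piRNA) populations in bulk small-RNA sequencing
of developing tissues, with CAGE-based gene expression on the side.

## The problem

piRNAs are 24–31 nt small RNAs produced from long genomic *clusters*,
best known from the germline, where they silence transposable
elements. Deciding whether a somatic library (say, postnatal brain at
10 days, 14 days and adult age) genuinely contains piRNAs — rather
than degradation products or snoRNA fragments of the right size —
takes a battery of coordinated analyses: careful read cleaning,
cluster-level expression calling, the 1U first-base bias diagnostic,
length-mode profiling (MILI-bound piRNAs peak at 26–27 nt, MIWI-bound
at 29–30 nt), exact-sequence sharing with a germline reference sample,
an ncRNA contamination screen, and positional coverage comparison
along clusters. `pirnadev` implements that battery, plus the
downstream layers: CAGE CTSS aggregation with power-law normalization
for gene/TF expression, a transcription-factor expression-scenario
filter, and two routes of piRNA target prediction.

## The core statistics

A cluster is called **expressed** when all of

```
read_count >= 100        (alignments fully contained in the cluster)
RPKM       >= 10         RPKM = count / ((len/1e3) * (mapped/1e6))
max_depth / read_count < 0.9     (anti PCR-tower guard)
```

**1U bias** is a one-sided exact binomial test of the first-base T
fraction against background 0.25, significant at p ≤ 0.001.
**Coverage similarity** is the median Pearson correlation of
100-base-window read fractions over clusters expressed in both
samples, keeping only correlations with p ≤ 0.001. **CAGE counts**
are normalized by mapping each library's fitted reverse-cumulative
power law `R(x) = c x^(-α)` onto a reference law (α_ref = 1.25, 10⁶
tags): `tpm = (c_ref/c_s)^(1/α_ref) · x^(α_s/α_ref)`. The
**signature scan** reports loci where a guide piRNA aligns with a
perfect 10-base 5' seed and a ≤ 160 Phred-sum mismatch budget
elsewhere, overlapped on the opposite strand by an exactly matching
sense read.

A deterministic synthetic-data module (`generate_reference()`,
`simulate_small_rna_sample()`, `simulate_ctss_sample()`,
`plant_target_sites()`) generates a miniature genome, annotations, raw
FASTQ-layout reads and CAGE tag tables with full ground truth, so the
whole pipeline is testable end to end without any sequencing data.

## Worked example

Simulate an adult-brain-like sample (50,000 reads, 7% from a
12-cluster, intergenic-dominant expressed set, 80% 1U, 26–27 nt
inserts) and run the pipeline:

```r
library(pirnadev)

probe <- generate_reference(simulation_config(n_clusters = 20,
    intergenic_fraction = 0.6, n_genes = 80, rng_seed = 7))
kl <- as.character(probe$clusters$klass)
bt <- sort(c(head(which(kl == "intergenic"), 11), head(which(kl == "genic"), 1)))
cfg <- simulation_config(n_clusters = 20, intergenic_fraction = 0.6,
    n_genes = 80, pools = list(brain = bt, testes = 1:20), rng_seed = 7)
ref <- generate_reference(cfg)

brain <- stage_profile("brain_adult", n_reads = 50000,
    cluster_read_fraction = 0.07, u1_fraction = 0.8,
    shared_pool_id = "brain")
smp <- simulate_small_rna_sample(ref, brain, seed = 7)
res <- run_small_rna_pipeline(ref, smp)
res
#> Small-RNA pipeline result
#>   reads: 50000 in, 48092 retained
#>   clusters expressed: 12 of 20
#>   1U fraction 0.288 (p = 1.39e-78, significant)
#>   length modes: 27

head(res$expression[, c("cluster_id", "klass", "read_count", "rpkm",
                        "depth_ratio", "expressed")], 4)
#>    cluster_id      klass read_count     rpkm depth_ratio expressed
#> 1 cluster_001 intergenic        293 3940.808  0.13310580      TRUE
#> 2 cluster_002 intergenic        357 3130.861  0.07843137      TRUE
#> 3 cluster_003 intergenic        301 2197.625  0.09302326      TRUE
#> 4 cluster_004      genic        310 2182.858  0.07419355      TRUE

intergenic_enrichment(res$expressed_ids, ref$clusters)$p_value
#> [1] 0.0007700246
```

The pipeline retained 48,092 of 50,000 raw reads (the rest lost their
adapter to quality truncation or fell below the 25-base gate), called
exactly the 12 truth-expressed clusters expressed, found a strongly
significant 1U bias (28.8% of reads start with U against the 25%
background — the cluster-derived 7% of reads carry the bias), and a
26–27 nt length mode. The expressed set is intergenic-dominant
(one-tailed Fisher p ≈ 8×10⁻⁴).

The published per-sample read totals ship with the package, and the
mapping summary reproduces every printed percentage from the raw
counts, including the rounding convention:

```r
mapping_summary(study_read_counts())[, c("sample_id", "mapped_pct", "cluster_pct")]
#>      sample_id mapped_pct cluster_pct
#> 1  brain_10dpp         81        0.46
#> 2  brain_14dpp         85        0.28
#> 3  brain_adult         86           7
#> 4 testes_10dpp         96          28
#> 5 testes_14dpp         96          30
#> 6 testes_adult         99          99
```

See `vignettes/pirna-pipeline.Rmd` for the full account of the models,
parameter choices and the synthetic generator's scope.

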