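---
title: "Calling and characterizing piRNA populations across postnatal development"
author: "pirnadev authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterizing piRNA populations across postnatal development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnadev)
```

## Scope and model

PIWI-interacting RNAs (piRNAs) are 24–31 nt small RNAs, classically
studied in germline tissue, where they are produced from long
single-transcript genomic *clusters* and silence transposable elements.
`pirnadev` implements the computational side of a bulk small-RNA +
CAGE study design that asks whether, and when, piRNAs appear in a
somatic tissue (postnatal brain at 10 dpp, 14 dpp and adult) relative
to testes at the same ages. The package covers:

1. **Read preprocessing** — quality truncation, 5' barcode and 3'
   adapter stripping, a 25–35 nt length gate (`preprocess_small_rna()`).
2. **Cluster expression calling** — read counting by interval
   containment, RPKM, and a three-part expression call
   (`cluster_expression()`).
3. **Population characterization** — positional base composition, the
   1U first-base bias diagnostic of primary piRNAs, read-length modes,
   exact-sequence sharing between samples, and ncRNA contamination
   (`u1_bias_test()`, `length_distribution()`,
   `shared_sequence_fraction()`, `ncrna_match_fraction()`).
4. **Coverage profiles** — per-cluster production profiles in 100-base
   windows compared across samples by Pearson correlation
   (`window_fractions()`, `correlation_summary()`).
5. **CAGE gene expression** — CTSS aggregation, power-law tag
   normalization, promoter-window gene expression and the
   TF expression-scenario filter (`fit_power_law()`,
   `gene_expression()`, `tf_scenario_filter()`).
6. **Target prediction** — top-scoring-hit selection with a
   Mann-Whitney deadenylation test, and a guide/sense
   complementarity-signature genome scan with repeat-consensus
   filtering (`select_top_gene_targets()`, `deadenylation_test()`,
   `signature_scan()`, `filter_repeats()`, `annotate_targets()`).
7. **Synthetic data** — a deterministic generator
   (`generate_reference()`, `simulate_small_rna_sample()`,
   `simulate_ctss_sample()`, `plant_target_sites()`) that emulates the
   statistical structure the analysis assumes and carries full ground
   truth, so every stage is testable without any sequencing download.

Genome alignment itself, motif discovery, miRanda scoring and GFOLD
estimation are out of scope: their outputs (alignments, enrichment
tables, hit tables, fold-change tables) are consumed as inputs, and the
generator produces truth alignments in their place.

## The expression call and its thresholds

A cluster is *expressed* in a sample when all three hold:

* `read_count >= 100` — at least 100 alignments fully contained in the
  cluster interval (multi-mapping reads counted once per containing
  cluster);
* `RPKM >= 10`, with
  `RPKM = count / ((length/10^3) * (total_mapped/10^6))`, the library
  size being the number of *distinct* genome-mapped reads;
* `max_depth / read_count < 0.9` — the deepest single base must not
  carry 90% or more of the cluster's reads, a guard against PCR
  towers masquerading as expression.

The count and RPKM thresholds are inclusive, the depth ratio exclusive.
"Mapped within" is read as full interval containment (an alignment
straddling a cluster boundary does not count); an any-overlap mode is
available via `mode = "any"`. Whether a read aligning twice inside one
cluster counts once or twice is not decidable from the study text;
both are supported (`count_unit = "alignment"` is the default, matching
"keeping multi-mapping reads").

## Characterization choices

**1U bias.** Primary piRNAs begin with uridine far more often than the
~25% a uniform background predicts. The study declares samples to
"lack significant 1U bias" without naming a test; we adopt the simplest
exact test consistent with that claim: a one-sided binomial test of the
first-base T fraction against background 0.25, significant at
`p <= 0.001` *and* observed fraction above background. Both the
background and the threshold are arguments.

**Length modes.** Read-length histograms are summarized by
plateau-aware local maxima (a run of equal counts strictly above both
neighbours is one mode, reported at its first length) with a prominence
floor of 10% of reads. This reports 26 *or* 27 for the MILI-bound
population and adds a second mode at 29–30 for adult testes, where
MIWI-bound piRNAs appear, without inventing sub-modes from noise.

**Sequence sharing.** "Also present in sample B" means exact string
identity of unique sequences: the query is the deduplicated set of
cluster-contained read sequences, the reference the deduplicated set of
*all* genome-mapped reads of the other sample (a cluster-restricted
reference is available by passing that subset). No alignment slack is
allowed, by design — shared mature piRNAs are identical molecules.

**ncRNA contamination.** Reported brain piRNA candidates have
historically turned out to be snoRNA fragments; the check here counts
reads occurring as exact full-length substrings of any ncRNA sequence
or its reverse complement. Because only perfect matches count, exact
substring search is equivalent to (and replaces) a BLAST pass.

## Coverage correlation

Each expressed cluster is cut into non-overlapping 100-base windows
(the trailing window may be short); each contained read is assigned to
exactly one window by its 5'-most genomic coordinate — the study does
not define what happens to straddlers, so the 5' rule is our documented
choice. Window fractions for the same cluster in two samples are
compared by Pearson correlation with the t-distribution p-value on
n−2 degrees of freedom; only clusters expressed in *both* samples
enter, only correlations with `p <= 0.001` are retained, and the
retained set is summarized by its median. At 100-base windows, typical
clusters give 15–30 windows, where the t approximation is adequate; a
permutation test was considered and rejected as needless at these
window counts.

## Power-law CAGE normalization

CTSS counts from CAGE libraries follow an approximate power law: the
reverse-cumulative function R(x) (number of CTSSs with count ≥ x) is
close to `c * x^(-alpha)` over a wide range. Libraries are made
comparable by mapping each raw count onto a *reference* power law with
exponent `alpha_ref` and total `total_ref` tags:

* fit: OLS of `log R(x)` on `log x` over distinct counts in
  `fit_range = [1, 1000]`;
* reference intercept: `c_ref = total_ref / sum_{x>=1} x^(-alpha_ref)`,
  because the sum of the reverse-cumulative function over integer x
  equals the total tag count;
* mapping: `tpm = (c_ref/c_s)^(1/alpha_ref) * x^(alpha_s/alpha_ref)`,
  i.e. matching reverse-cumulatives between the two laws. The mapping
  is strictly monotone and reduces to the identity when the sample law
  equals the reference.

The reference defaults `alpha_ref = 1.25`, `total_ref = 10^6` follow
common practice for this normalization; the study names the method but
not its parameters, so both are arguments. Gene expression is then the
sum of tpm over each *unique* CTSS (once, even if promoter windows of
several TSSs of the gene overlap) inside the strand-oriented union of
`[TSS - 1000, TSS + 500]` windows, inclusive at both ends; a gene is
expressed at `tpm >= 0.5`. CTSS strand must match the gene strand
(CAGE tags are stranded); `strand_match = FALSE` disables this.

The TF scenario filter encodes two regulatory hypotheses for
transcription factors whose motifs discriminate the promoters of
brain-expressed (BT) versus other (non-BT) clusters: an activator of BT
clusters must be expressed (> 0.5 tpm, strict) in adult brain and in
all three testes stages; a repressor of non-BT clusters must be
expressed in adult brain but at or below threshold (≤ 0.5, per "no
more than") in all testes stages.

## Target prediction

**Route 1.** Hits from an upstream hybridization scorer are thresholded
at score 160, restricted to expressed genes, and reduced to the single
top-scoring gene per piRNA (ties broken by the lexicographically
smallest gene id, so the reduction is deterministic). If piRNAs
deadenylate their targets, target genes should shift down in fold
change between 14 dpp and adult: the non-zero fold changes of targets
and non-targets are compared by a two-sided Mann-Whitney test. The U
statistic uses midranks; p is exact (full enumeration) for pooled
n ≤ 12 without ties, else the tie-corrected normal approximation with
continuity correction.

**Route 2.** The complementarity signature: sense piRNA reads are
placed at every exact genomic match (both strands, all occurrences);
guide piRNA reads are aligned requiring zero mismatches in the 5'-most
10 bases (the seed) and a mismatch *quality budget* — the sum of Phred
scores at mismatched non-seed read positions may not exceed 160. With
the generator's uniform Q30 qualities this allows at most 5 non-seed
mismatches; with real qualities the actual scores are summed. A
signature site is a guide alignment overlapped by ≥ 1 base by a sense
alignment on the opposite genomic strand. The precise geometry of
"divergent partial complementarity" is not recoverable from the study
text; overlap-only is the default, and a stricter ping-pong mode
requiring the guide's and sense read's first 10 bases to occupy the
same genomic span is available (`ping_pong = TRUE`). Overlapping mRNAs
and repeat elements at least 75% of their family consensus length are
reported as targets, each once.

## What the generator emulates — and what it does not

`generate_reference()` builds a random-composition genome (default 5 Mb
over 2 chromosomes), places non-overlapping clusters labeled
genic/intergenic at the requested fraction, overlaps every genic
cluster with a gene, adds background genes, repeats with family
consensus lengths, and an ncRNA set. Reads are 4-base barcode +
insert + 3' adapter, Phred+33, with an occasional (5%) Q10 tail so the
truncation rule is exercised.

Cluster-derived inserts are drawn from per-cluster *candidate pools* —
fixed sets of 5' positions (20 starting with T, 40 not, per cluster)
derived deterministically from the reference seed — so that samples
configured with the same pool draw the same sequences and samples with
disjoint pools do not. The per-sample `u1_fraction` chooses between
the T and non-T candidate subsets; insert lengths come from the
profile's mixture (point masses at modal lengths, e.g. {26, 27} for
MILI-type populations, plus {29, 30} for adult testes). Background
reads are uniform over the genome, hence first-base-unbiased — this is
what a 10 dpp brain library looks like to the pipeline. A small
fraction of clusters is duplicated elsewhere in the genome so that
multi-mapping occurs; such reads keep one truth record (their
originating locus) but emit alignments at both loci.

CAGE tables draw per-CTSS counts from a discrete power law
(`floor(U^(-1/alpha))`, so `P(count >= x) = x^(-alpha)` exactly) and
place them, without positional collisions, inside ±450 bases of the
TSSs of genes with positive truth expression, weighted by truth tpm.

The generator does **not** emulate: real mouse sequence composition or
repeat content, sequencing errors beyond quality tails, ping-pong
5'–5' amplification geometry, or paired-end CAGEscan fragments. Tests
passing on this generator therefore demonstrate the *rules* are
implemented correctly (thresholds, boundaries, truth recovery), not
that the pipeline is robust to every artifact of real libraries.

## Numerical and degenerate-input choices

* Percentages are rounded half-up: integer precision for mapping rates
  at or above 1%, two decimals below 1%, one decimal for sharing
  fractions — the conventions needed to reproduce the printed summary
  values exactly from printed counts.
* Zero-variance window profiles make a correlation undefined: the pair
  is skipped with a warning, never imputed.
* Empty sequence sets, empty expressed sets, all-zero fold changes and
  degenerate power-law support are errors, not silent zeros; an empty
  ncRNA database is the one warning-and-zero case (it means "no
  contamination screen", not "no contamination").
* Quality truncation may produce empty reads; they stay in the table
  so that retained + discarded always equals input.
* `sum_{x>=1} x^(-alpha)` is computed by partial sum plus
  Euler–Maclaurin tail; alpha ≤ 1 (divergent total) is rejected.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use a 5 Mb genome with
20 clusters (60% intergenic), 50,000-read samples at the study's
mapped-fraction profile (7% cluster reads in adult brain, 99% in adult
testes), and 2×10^5 CAGE tags (~47,000 CTSSs). These sizes were chosen
so every expressed cluster clears the expression thresholds by at least
2× under the study's stage profiles, the intergenic-enrichment test is
resolvable on a 20-cluster panel, and the power-law exponent estimate
is stable; they are desk-scale stand-ins for the study's 214-cluster,
multi-million-read libraries.

## Known limitations

* The expression call's `total_mapped_reads` counts distinct reads;
  if a caller supplies alignment-level totals the RPKMs scale down
  accordingly.
* The signature scan is exact-search based and meant for the miniature
  genomes of this package's scope; scanning a full mammalian genome
  would need an FM-index aligner upstream, with this module consuming
  its output.
* The deadenylation test inherits whatever bias the upstream
  fold-change estimator has near zero, since exact zeros are dropped
  from both groups by construction.
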