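---
title: "Methods: from chromatin peaks to cis-regulatory candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from chromatin peaks to cis-regulatory candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmark)
library(dplyr)
```

regmark implements the downstream analysis that connects histone-modification
(CUT&Tag) and open-chromatin (ATAC-seq) peak calls to gene expression,
protein evolutionary rates, population nucleotide diversity, and candidate
*cis*-regulatory indels in a two-ecotype design, as used in marine/stream
stickleback comparisons. Upstream steps — read trimming, mapping, peak
calling, SNP calling, transcript quantification, dN/dS estimation — are out
of scope: the package consumes their standard outputs (BED/broadPeak, GFF3,
TSV of TPM, VCF, bedGraph) and everything downstream is reproducible,
file-based and deterministic.

All coordinates are normalized to a single 0-based half-open convention on
ingest (GFF and VCF are 1-based on disk); this removes an entire class of
off-by-one errors and makes interval arithmetic uniform across modules.

## Peak annotation

Each peak is represented by its **center**, `start + floor((end - start)/2)`,
and classified into one of five categories by where the center falls:

* `PROMOTER_TSS` — within −1 kb to +100 bp of a transcription start site,
  in gene orientation;
* `TTS` — within −100 bp to +1 kb of a transcription termination site;
* `EXON` — within the union of the gene's exons across isoforms;
* `INTRON` — within the gene span but no exon;
* `INTERGENIC` — anything else, assigned to the gene with the nearest TSS.

Annotation is gene-level: the gene span is the union of its transcript
spans, and TSS/TTS are the strand-aware ends of that span. When a center
lies in several features (a promoter window typically overlaps exon 1) the
category precedence is PROMOTER_TSS > TTS > EXON > INTRON, with ties across
genes broken by smaller |distance to TSS| and then by gene id — fully
deterministic. The correctness standard in the tests is a brute-force
classifier that re-derives the category of every peak center from per-gene
window arithmetic; the interval-tree implementation must agree exactly.

Category proportions are summarized both by peak count and by summed peak
length (the full length of a peak is attributed to its center's category);
each set of proportions sums to 1.

## Expression and dN/dS association

Transcript-level TPM is summed over isoforms to gene level. For one mark
and sample, genes are partitioned into three categories: `GENE` (at least
one peak center in the promoter/exon/intron/TTS windows), `INTERGENIC`
(only a nearest-gene relationship to intergenic peaks), `NO_PEAKS`. A gene
with both genic and intergenic peaks is `GENE`. Genes on chromosomes where
the annotation saw no peaks at all are excluded rather than called
`NO_PEAKS`, so missing data is not confused with absence of marks.

Expression is compared between categories with two-sided Wilcoxon rank-sum
tests on `ln(TPM + 1)`. `stats::wilcox.test` supplies the exact null
distribution for small untied samples and the tie-corrected normal
approximation otherwise; because the test is rank-based, the log transform
changes nothing about the p-value (a property the tests verify) and is kept
for reporting and plotting. The fully tied case is defined as p = 1. All
three pairwise comparisons are reported without multiplicity correction by
default, matching how such panels are usually annotated; `adjust = "holm"`
is available.

dN/dS values of at least 99 are excluded (inclusive threshold) before any
comparison — such values arise when dS approaches zero and the ratio is
unreliable. The expression–dN/dS relationship is summarized by Spearman's
rank correlation on the raw TPM and dN/dS values.

## Windowed nucleotide diversity

From a two-population genotype matrix of biallelic SNPs, the per-site
statistics are

* within-population diversity
  $\pi = 2c(m-c) / (m(m-1))$ for $m$ called alleles of which $c$ are
  alternate — the unbiased fraction of differing allele pairs;
* between-population divergence
  $D_{XY} = p_1(1-p_2) + p_2(1-p_1)$ with $p_k$ the population allele
  frequencies.

Missing genotypes reduce $m$ at a site instead of removing the site; a site
with fewer than two called alleles in a population is skipped and counted.
Windows tile each chromosome in non-overlapping 10 kb steps (configurable);
per-site values are summed and divided by the window length under the
all-site interpretation — invariant sites contribute zeros — or by the
callable-base count when an accessibility mask is supplied. Windows with
fewer than 10 usable SNPs are excluded. The trailing partial window of a
chromosome is kept with its true length as denominator and flagged
`partial` rather than silently truncated. π is reported per population
(`pi_<population>` columns); peak comparisons use one chosen population
(the first, by default).

A window is `in_peak` when it overlaps any peak of the mark by at least
1 bp (the overlap rule is configurable); π and $D_{XY}$ are then compared
between peak(+) and peak(−) windows with rank-sum tests. The tests validate
the window statistics against an oracle that enumerates every allele pair
per site, to 1e-12.

## Coverage clustering

Fragment intervals (alignment-free; convert BAM externally) are counted
into 5 kb genome-wide bins, a fragment incrementing every bin it overlaps —
mirroring extended-read coverage counting. Pairwise Spearman correlations
of the concatenated bin vectors feed average-linkage hierarchical
clustering on the distance $1 - \rho$. Samples are sorted by id before
clustering so the dendrogram does not depend on input order; zero-coverage
bins are kept by default (`drop_zero_bins` drops bins empty in every
sample). Dendrograms export to Newick.

## The candidate screen

Three criteria define marine-ecotype-specific genes: (1) mean TPM of the
freshwater-acclimated marine samples strictly exceeds 8x the mean of the
freshwater-acclimated stream samples; (2) the minimum TPM of the
seawater-acclimated marine samples is above 10; (3) the gene lies on an
assembled chromosome. The strict `>` in (1) means a zero stream mean passes
whenever any marine expression exists.

Genes passing all three enter an ordered exclusion cascade:

1. gene body absent in the **marine** ecotype → excluded;
2. gene body absent in the **stream** ecotype → excluded (the expression
   difference then reflects gene presence/absence, not *cis*-regulation);
3. no H3K4me1/H3K4me3 peak in the strand-aware upstream window
   `[TSS − 10 kb, TSS + 100 bp)` → no candidate region;
4. otherwise the merged upstream peak intervals are candidate regions, and
   a stream-specific deletion is called when ≥ 80% of a region's bases fall
   below depth 2 in the stream coverage while ≥ 80% reach depth 2 in the
   marine coverage; the maximal zero-depth run is reported as the indel.

Absence calls of this kind are made by eye over read pileups in practice;
regmark formalizes them as coverage-fraction rules (gene body "present"
when ≥ 50% of span bases have depth ≥ 2) so that the cascade is
reproducible and every threshold is an explicit, configurable parameter.
The 10 kb upstream search default comfortably covers enhancers a few kb
upstream of the TSS while staying local. Stage counts
(`attr(result, "stage_counts")`) always satisfy the conservation law:
genes passing the criteria equal the sum over the five dispositions.

## The synthetic-data generator

`sim_config()` fixes the study conditions the tests and the acceptance
script run under; all stages are deterministic given the config (each
generator draws from its own sub-seed, so one stage's draws cannot shift
another's).

* **Genome and genes** — by default 2 chromosomes x 1 Mb with 100
  non-overlapping genes (1–5 kb, 1–5 exons, random strand, ≥ 2 kb gaps);
  scaled-up configurations (1,000 genes on 2 x 3 Mb) are used where a
  property needs them.
* **Peaks** — per-mark counts with category bias weights emulating the
  expected genomic distribution (H3K4me3 and ATAC promoter-enriched,
  H3K9me3 intergenic-enriched). Centers are sampled inside a genome-wide
  category partition built with the same precedence as the classifier, so
  every peak carries an exactly-known true category.
* **Expression** — `ln(TPM+1) ~ Normal(mu + delta_active * active −
  delta_repressive * repressive, sigma)` with defaults mu 1.5, sigma 1.0
  and effect sizes 1.0 on the ln scale; "active" means a genic H3K4me1,
  H3K4me3 or ATAC peak and "repressive" a genic H3K27me3 peak. TPM is
  split over isoforms with uniform random weights. dN/dS is
  `exp(a − b ln(TPM+1) + noise)` with b = 0.3 > 0 planting the negative
  coupling, plus a 1% fraction of inflated values ≥ 99 for the filter to
  remove.
* **Genotypes** — every base is independently polymorphic with probability
  theta_in = 0.01 inside peaks and theta_out = 0.005 outside; allele
  frequencies per population come from a symmetric Beta(0.5, 0.5) and
  diploid genotypes are Binomial(2, p), 4 samples per population. There is
  deliberately no linkage: adequate for window statistics, unusable for
  LD-based analyses.
* **Fragments** — planted per-bin log-normal intensity profiles with
  Poisson sampling; replicates share a profile, so clustering should
  recover replicate pairs as siblings.
* **Screen scenario** — planted marine-specific genes (high marine TPM
  passing both criteria, near-zero stream TPM) assigned to known classes:
  marine-absent, stream-absent, unmarked, deletion-carrying (a stream
  coverage gap over a planted upstream peak), or intact. Planted genes are
  kept ≥ 25 kb apart so one gene's gap cannot fall inside another's
  upstream search window — without this the planted truth would not be
  internally consistent and the closed-loop test (recovered candidates =
  planted candidates) would be ill-posed.

What passing tests on this generator do show: the interval arithmetic,
estimators, test statistics and the cascade logic are correct, and planted
effects of realistic size are recovered at the stated power. What they do
not show: robustness to linkage disequilibrium, mapping artifacts,
batch-structured expression noise, or mis-annotation — none of which the
generator emulates.

## Numerical and design choices

* Peak-center floor rule for even-length peaks; single-base peaks are
  their own center.
* Promoter/TTS windows are clipped at position 0 and (when chromosome
  sizes are known) at the chromosome end.
* Window denominators use the full window length ("all-site") unless a
  mask is given; the trailing partial window keeps its true length.
* Rank-sum p-values: exact for small untied samples, tie-corrected normal
  approximation otherwise; the all-tied case is p = 1 by definition.
* Tie-breaking everywhere (annotation, nearest gene, clustering order) is
  deterministic and documented above.
* Degenerate inputs fail loudly: empty summaries, one-category
  comparisons, constant vectors in correlations, missing chromosomes in
  coverage are errors, not NAs.

## Problem sizes

The shipped test-suite and acceptance-script configurations use genomes of
0.1–6.2 Mb, 10–1,000 genes, up to ~45,000 SNPs, and 100–200 replicates for
the power and calibration checks — sizes chosen so the full statistical
structure (hundreds of windows per group, 500 genes per category) is
present while everything recomputes from scratch in minutes on a laptop.

## Limitations

* Gene-level annotation only; per-isoform annotation is out of scope.
* Two populations exactly for $D_{XY}$; no $F_{ST}$, no phasing.
* The insertion case of the screen (an insertion in the stream ecotype
  replacing marine sequence) is detected only as a stream coverage gap
  with marine marks, like a deletion; the inserted sequence itself is not
  reconstructed.
* The coverage-rule surrogates for gene-body absence and indel calls are
  parameterized defaults, not calibrated against read simulators.
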