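---
title: "Calling and classifying intragenic transcription start sites from 5'-tag data"
author: "intratss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and classifying intragenic transcription start sites from 5'-tag data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intratss)
```

## The model

TSS-seq libraries report, for every genomic base and strand, the number of
sequencing reads whose capped 5′ end maps there. `intratss` treats these
per-base tag counts as the primary observable and builds the analysis in
four layers.

**Candidate support.** A base is a TSS candidate for a genotype when at
least `min_tags` tags support it in at least `min_libraries` libraries of
that genotype (defaults 2 and 2). The rule is deliberately conservative:
with UMI-deduplicated data, a single tag in a single library carries no
replication evidence, and the default thresholds make singleton noise
formally incapable of seeding a cluster. The rule is applied per genotype
so that detection is defined before any cross-genotype comparison.

**Clustering.** Candidate positions from *all* genotypes are pooled into
one coordinate system and merged whenever consecutive positions lie at
most `max_gap = 20` bases apart; strands never merge. Pooling before
merging is a deliberate design choice: genotype categories are then
properties of shared cluster intervals, so "detected in A but not B" never
hinges on slightly different cluster boundaries per genotype. A cluster's
*score* is the total tag count over its bases and all libraries divided by
the total number of libraries in the experiment (not just those where it
was detected), and its *summit* is the base of maximal pooled signal with
ties broken toward the smaller coordinate, which makes output fully
deterministic.

**Annotation.** Each cluster is intersected with feature regions derived
from gene models and resolved to the single highest-priority category via
the fixed hierarchy `intergenic < antisense < intron < exon < threeUTR <
fiveUTR < proximal < promoter`. The promoter is the symmetric 201-base
window centred on the gene's 5′-end base; the proximal region covers bases
101–500 upstream in transcription orientation. Genic categories require
same-strand overlap; `antisense` means overlap with a gene span on the
opposite strand; `intergenic` is the implicit floor. The full cluster
interval (not only the summit) is used for intersection: a cluster is a
contiguous run of supported initiation positions, and any of them inside a
feature is evidence for that feature class. Genic clusters get the nearest
same-strand gene that overlaps them or lies within 500 bases edge to edge,
ties going to the smaller gene start.

**Classification.** Per-genotype detection flags (a cluster is detected in
a genotype when it contains at least one of that genotype's candidate
bases) partition clusters into `basal` (wild type and at least one
mutant), `wt_specific` (wild type only), and `fact_specific` (at least one
mutant, not wild type). The classification is a partition by construction;
the test suite checks this on every random fixture.

## Coordinates

All public file formats keep their native conventions — bedGraph and BED
are 0-based half-open, GFF3 is 1-based inclusive — with conversion at the
boundary handled by `rtracklayer`. Internally the package uses
`GenomicRanges`/`IRanges` containers, i.e. 1-based closed intervals and
run-length-encoded per-base vectors, because that is the representation
the whole Bioconductor interval stack operates on; window semantics (the
201-base promoter, the 400-base proximal window, half-open cluster
boundaries in BED-style output) are independent of this choice and are
tested against 0-based specifications of the same windows.

One genuine ambiguity deserves note: "start −100 bp to start +100 bp"
windows can be read as 200 or 201 bases. We use the symmetric 201-base
closed window around the 5′-end base, which is strand-independent and
introduces no off-by-one bias between plus- and minus-strand genes. The
mirrored-window reading for minus-strand genes is equivalent under this
choice, which is why it was made.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_tags` | 2 | tags per library needed to support a candidate base |
| `min_libraries` | 2 | libraries per genotype needed for a candidate |
| `max_gap` | 20 bases | maximal spacing of merged candidate positions |
| promoter flank | 100 bases | half-width of the promoter window |
| proximal window | 101–500 bases upstream | proximal upstream feature |
| gene distance | 500 bases | nearest-gene assignment cutoff |
| `pseudocount` | 1 | added after CPM scaling, before log2 |
| window width | 20 bases | boxplot window around an anchor |
| metagene width | 400 bases | offsets −200…199 around an anchor |
| CI multiplier | 1.96 | normal-based 95% band on metagene means |

The CPM pseudocount of 1 maps zero counts to exactly 0 on the log2 scale;
it is configurable because ratio-based contrasts are sensitive to the
floor at low counts. Expression values for clusters are `log2(1e6 ·
count/total + 1)` with the *genome-wide* library tag total as denominator,
so CPM values do not change when cluster boundaries change.

The Wilcoxon rank-sum wrapper uses the exact null distribution when both
groups have ≤ 25 values and no ties, and otherwise the large-sample normal
approximation with tie correction and no continuity correction. The
boxplot statistics use linear-interpolation quartiles and 1.5·IQR
whiskers; degenerate all-tied comparisons return p = 1 with an explicit
flag rather than `NaN`.

## Signal aggregation conventions

Windows are centred half-open: the 20-base window at anchor *p* covers
0-based bases [*p*−10, *p*+10), and metagene offsets run −200…199 with the
anchor at offset 0. Minus-strand anchors are mirrored so positive offsets
always point downstream in transcription orientation. Absent track bases
count as 0 (the bedGraph sparsity contract); windows are clipped at
chromosome edges for medians and zero-padded for metagenes (fixed-length
profiles).

Control positions for enrichment contrasts are drawn uniformly over the
exonic bases of a matched gene set from a mandatory seed, and positions
closer than a configurable distance (200 bases for nascent-transcription
data) to the gene's 3′ end can be excluded, because run-on assays show
exaggerated signal near polyadenylation sites. The 3′ end is the default
interpretation of "gene end" for that rule; filtering both ends is
available behind a flag. The eligibility filter is applied before the
uniform draw, which is equivalent in distribution to drawing first and
discarding.

Single-end reads from fragment-based assays are resized to
`floor(insert_size/2)` bases anchored at the read's 3′ end, so coverage
peaks sit at fragment midpoints. The insert size is a required parameter:
estimating it is the job of upstream peak-calling tools with fragment-size
models, and re-estimating it here would duplicate that machinery poorly.

## What the synthetic generator emulates

`simulation_config()` defaults describe the study conditions used
throughout the tests: 2 chromosomes of 200 kb, 200 non-overlapping genes
with alternating strands (2–4 exons of 150–400 bases, introns of 60–150
bases, intergenic gaps of 600–1200 bases), three genotypes (wild type plus
two mutants) with 2 replicates each. Every gene gets a promoter TSS active
in all genotypes with negative-binomial per-library tag counts (mean 50,
dispersion 10); 30% of genes get an intragenic TSS active only in the
mutants at mean 10 — the lower mean encodes the observation that
mutant-induced transcripts are less expressed than basal ones. Tag
positions jitter geometrically (p = 0.7, capped at ±5 bases) so each
planted site forms a single ≤ 20-base cluster by construction, and
intragenic sites are planted > 25 bases from the promoter so planted
clusters never merge. Background noise is Poisson-placed (0.3 positions
per kb per strand) singleton tags — exactly one tag in one random library —
which the support rule must reject; a `confusable_noise` mode with
supra-threshold noise exists for stress testing. Negative-binomial counts
were chosen because overdispersion relative to Poisson is the norm for
sequencing count data.

Signal tracks carry a baseline of 1.0 with Gaussian bumps (amplitude 1.0,
σ = 75 bases) at intragenic planted sites (elongation-mark style), at
promoters (promoter-mark style), or a +0.5 elevation over gene bodies
(nucleosome style), plus Gaussian noise (sd 0.25) truncated at zero.

All randomness flows from one master seed through deterministic per-stage
sub-seeds (`derive_seed()`), so the genome, the planted truth, the
libraries and the tracks can each be regenerated independently and two
runs with the same configuration are byte-identical on disk.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: mappability artefacts, multi-isoform genes and
UTR structure (UTR categories are empty unless supplied), promoter shape
heterogeneity (planted TSSs are single-base sources with symmetric
jitter), correlated noise between replicates, genotype-specific library
depth differences, and broad or bimodal TSS clusters. Recovery statistics
on planted data are upper bounds on real-data performance.

## Numerical choices and degenerate inputs

Reported percentages are rounded half away from zero, to one decimal at
≥ 10% and two below — the convention that reproduces published summary
tables of this analysis type; headline fold ratios are rounded to the
nearest integer. Zero-total libraries, clusters without tags, empty gene
sets in contrasts and genomes that cannot fit the requested genes all
raise immediate errors rather than propagating `NaN`; zero-variance
replicate columns yield `NA` correlations with a message. Windows
extending past chromosome bounds are clipped, never rejected. Feature sets
built from genes whose exons leave the gene span are rejected at
construction time.

## Scale of the validation runs

The default test and acceptance configurations (200 genes, 6 libraries,
400 kb of genome; 1000-fixture oracle sweeps for the calling rules; 2000
null simulations for the rank-sum uniformity check) were chosen so the
planted statistics are stable to the asserted tolerances while the whole
suite stays fast enough to run on every change.

## Known limitations

- One representative transcript model per gene; no isoform-level
  annotation arbitration.
- BigWig is not read or written; bedGraph is the canonical exchange
  format.
- The per-genotype detection flag is defined at cluster level as
  "contains ≥ 1 candidate base of that genotype"; alternative definitions
  (e.g. summit-level detection) would shift boundary cases between the
  `basal` and specific categories.
- The pipeline quantifies and contrasts; it does not fit differential
  expression models — tag-count contrasts beyond the rank-sum tests are
  out of scope.
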