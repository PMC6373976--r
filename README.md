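# intratss

TSS cluster calling and intragenic TSS analysis from stranded 5′-tag data.

## The problem

5′-cap sequencing (TSS-seq, CAGE and relatives) maps transcription start
sites at single-base resolution: the first base of each read is one "tag"
voting for a TSS. Comparing TSS maps between a wild type and mutants of a
chromatin factor (here modelled on knock-downs of the two FACT histone
chaperone subunits, SPT16 and SSRP1) reveals *intragenic* start sites that
are normally repressed: positions inside gene bodies that only fire when
the factor is compromised. `intratss` implements that comparison as a
reusable, tested pipeline for anyone analysing multi-genotype 5′-tag count
tracks:

1. **Calling** — a genomic position is a TSS candidate for a genotype when
   it has ≥ `min_tags` tags (default 2) in ≥ `min_libraries` libraries
   (default 2) of that genotype. Candidates from all genotypes are pooled
   and merged into clusters whenever consecutive positions are ≤ `max_gap`
   (default 20) bases apart. Each cluster gets a **score** (mean tags per
   library over the whole experiment) and a **summit** (leftmost base of
   maximal pooled signal).
2. **Annotation** — each cluster receives the single highest-priority
   feature it intersects, by the fixed hierarchy
   `intergenic < antisense < intron < exon < threeUTR < fiveUTR < proximal
   < promoter`, where the promoter is the ±100 bp window around a gene's 5′
   end and the proximal region is the 401–101 bp upstream window. Genic
   clusters are assigned the nearest same-strand gene within 500 bp.
3. **Classification** — detection flags per genotype partition clusters
   into `basal` (wild type and ≥ 1 mutant), `wt_specific` (wild type only)
   and `fact_specific` (≥ 1 mutant but not wild type).
4. **Quantification** — per-cluster tag counts, `log2(CPM + 1)` expression,
   replicate concordance, and a Wilcoxon contrast of promoter expression
   ratios between genes with and without mutant-specific clusters.
5. **Signal aggregation** — 20 bp window medians (boxplots) and 400 bp
   metagene profiles of chromatin signal (ChIP-seq / MNase-seq / GRO-seq
   style tracks) around TSS categories, with seeded exonic control-position
   sampling and rank-sum contrasts.

A synthetic-data generator (`simulation_config()`, `generate_simulation()`)
plants known promoter and intragenic TSS architecture — negative-binomial
tag counts, sub-threshold singleton noise, Gaussian chromatin-mark bumps —
and records the ground truth, so the entire pipeline is validated end to
end without any external data.

## Worked example

```r
library(intratss)

sim <- generate_simulation(simulation_config(seed = 42), tracks = FALSE)
clusters <- call_tss(sim$libraries)
features <- build_feature_set(sim$annotation)
clusters <- annotate_clusters(clusters, features)
clusters <- classify_clusters(clusters)

summarize_categories(clusters)
#>               count percent
#> basal           200    76.9
#> wt_specific       0     0.0
#> fact_specific    60    23.1
#> total: 260

annotation_breakdown(clusters, "fact_specific")$counts[c("exon", "promoter")]
#>     exon promoter
#>       52        8

rec <- score_recovery(clusters, sim$truth)
rec$per_kind[, c("kind", "n", "recall")]
#>                   kind   n recall
#> 1             promoter 200      1
#> 2 fact_specific_exonic  60      1
```

All 200 planted promoter TSSs are recovered as `basal` clusters and all 60
planted mutant-only intragenic TSSs as `fact_specific` clusters (recall 1,
category agreement 1, zero clusters from the singleton noise). The 8
`promoter`-annotated mutant-specific clusters are intragenic sites planted
within 100 bp of the gene's 5′ end, where the promoter window outranks
`exon` in the hierarchy.

For file-based runs, `write_simulation()` emits a manifest plus stranded
bedGraph pairs, GFF3 gene models and bedGraph signal tracks, and
`run_pipeline(pipeline_config(...))` executes the same stages from disk,
writing `clusters.tsv`, `expression.tsv`, `summary.json` and a run
manifest with parameter and checksum records.

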