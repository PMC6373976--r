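# Genotype-contrast classification of TSS clusters and the derived summary
# statistics: category counts/percentages, annotation breakdowns, the
# two-mutant Venn overlap, and overlap with externally mapped peak summits.

#' Classify clusters by genotype contrast
#'
#' Every cluster falls in exactly one of three classes: `basal` (detected in
#' wild type and in at least one mutant), `wt_specific` (wild type only) and
#' `fact_specific` (at least one mutant but not wild type).
#'
#' @param clusters Cluster `GRanges` with a `detected_in` logical matrix.
#' @param wild_type Column name of the wild-type genotype.
#' @param mutants Column names of the mutant genotypes.
#' @return `clusters` with the `category` column filled in.
#' @export
classify_clusters <- function(clusters, wild_type = "wild_type",
                              mutants = c("spt16", "ssrp1")) {
  flags <- clusters$detected_in
  stopifnot(is.matrix(flags),
            wild_type %in% colnames(flags),
            all(mutants %in% colnames(flags)))
  if (nrow(flags) && any(rowSums(flags) == 0))
    stop("cluster with no detection flag set")
  wt <- flags[, wild_type]
  mut <- rowSums(flags[, mutants, drop = FALSE]) > 0
  clusters$category <- ifelse(wt & mut, "basal",
                              ifelse(wt, "wt_specific", "fact_specific"))
  clusters
}

#' Summarize category counts
#'
#' Counts, reported percentages (half-away-from-zero, one decimal at >= 10%
#' and two below), and the headline mutant-specific over wild-type-specific
#' fold ratio rounded to the nearest integer.
#'
#' @param x Classified cluster `GRanges`, or a named integer vector of
#'   category counts.
#' @return Object of class `CategorySummary`: list with `counts`,
#'   `percentages`, `total`, `fold_ratios`.
#' @export
summarize_categories <- function(x) {
  counts <- if (is(x, "GRanges")) {
    c(table(factor(x$category,
                   levels = c("basal", "wt_specific", "fact_specific"))))
  } else {
    stopifnot(!is.null(names(x)))
    x
  }
  total <- sum(counts)
  if (total == 0) stop("no clusters to summarize")
  pct <- format_percent(100 * counts / total)
  fold <- if (all(c("fact_specific", "wt_specific") %in% names(counts)) &&
              counts[["wt_specific"]] > 0) {
    c(fact_over_wt = round_half_up(
      counts[["fact_specific"]] / counts[["wt_specific"]]))
  } else c(fact_over_wt = NA_real_)
  structure(list(counts = counts, percentages = pct, total = total,
                 fold_ratios = fold),
            class = "CategorySummary")
}

#' @export
print.CategorySummary <- function(x, ...) {
  df <- data.frame(count = as.integer(x$counts), percent = x$percentages)
  rownames(df) <- names(x$counts)
  print(df)
  cat("total:", x$total, "\n")
  if (!is.na(x$fold_ratios[["fact_over_wt"]]))
    cat("fact_specific / wt_specific fold:",
        x$fold_ratios[["fact_over_wt"]], "\n")
  invisible(x)
}

#' Annotation breakdown within a category
#'
#' Per-annotation counts and percentages within one genotype-contrast class
#' (or over all clusters).
#'
#' @param clusters Annotated, classified cluster `GRanges`.
#' @param which One of `"basal"`, `"wt_specific"`, `"fact_specific"`,
#'   `"all"`.
#' @return A `CategorySummary` over annotation categories.
#' @export
annotation_breakdown <- function(clusters, which = "all") {
  sel <- if (which == "all") clusters
  else clusters[!is.na(clusters$category) & clusters$category == which]
  if (length(sel) == 0) stop("no clusters in category ", which)
  counts <- c(table(factor(sel$annotation, levels = ANNOTATION_HIERARCHY)))
  summarize_categories(counts)
}

#' Venn overlap of mutant-specific clusters between two mutants
#'
#' Among mutant-specific clusters restricted to the given annotations,
#' counts how many are detected only in the first mutant, only in the
#' second, or in both, and reports the `both` fraction as a percentage.
#'
#' @param clusters Annotated, classified cluster `GRanges`.
#' @param mutants Character vector of exactly two mutant genotype names.
#' @param annotations Annotations to restrict to (default
#'   `c("exon", "intron", "antisense")`).
#' @return List with `counts` (named: `<m1>_only`, `<m2>_only`, `both`),
#'   `total`, and `pct_both` (one decimal).
#' @export
mutant_venn <- function(clusters, mutants = c("spt16", "ssrp1"),
                        annotations = c("exon", "intron", "antisense")) {
  stopifnot(length(mutants) == 2)
  sel <- clusters[!is.na(clusters$category) &
                    clusters$category == "fact_specific" &
                    clusters$annotation %in% annotations]
  f1 <- sel$detected_in[, mutants[1]]
  f2 <- sel$detected_in[, mutants[2]]
  counts <- c(sum(f1 & !f2), sum(!f1 & f2), sum(f1 & f2))
  names(counts) <- c(paste0(mutants[1], "_only"),
                     paste0(mutants[2], "_only"), "both")
  total <- sum(counts)
  list(counts = counts, total = total,
       pct_both = if (total > 0)
         round_half_up(100 * counts[["both"]] / total, 1) else NA_real_)
}

#' Fraction of clusters containing an external peak summit
#'
#' For each annotation category and cluster group (all / basal /
#' mutant-specific), the fraction of clusters whose interval contains at
#' least one summit point. Strand is matched when the summit carries one
#' (`*` summits match both strands).
#'
#' @param clusters Annotated, classified cluster `GRanges`.
#' @param summits Width-1 `GRanges` of peak summits
#'   (see [read_bed_points()]).
#' @return Data frame with one row per annotation (plus `all`) and columns
#'   `all`, `basal`, `fact_specific` holding overlap fractions (`NaN` where
#'   a group is empty).
#' @export
cage_overlap_fraction <- function(clusters, summits) {
  # "*" summits match both strands under strand-aware overlap semantics
  hit <- overlapsAny(clusters, summits, ignore.strand = FALSE)
  groups <- list(
    all = rep(TRUE, length(clusters)),
    basal = !is.na(clusters$category) & clusters$category == "basal",
    fact_specific = !is.na(clusters$category) &
      clusters$category == "fact_specific"
  )
  rows <- c("all", ANNOTATION_HIERARCHY)
  out <- sapply(groups, function(g) {
    vapply(rows, function(a) {
      sel <- g & (a == "all" | clusters$annotation %in% a)
      if (!any(sel)) NaN else mean(hit[sel])
    }, numeric(1))
  })
  as.data.frame(out)
}

#' Genes carrying at least one cluster of a category
#'
#' @param clusters Annotated, classified cluster `GRanges`.
#' @param category Category to look for (default `"fact_specific"`).
#' @return Character vector of gene ids.
#' @export
genes_with_category <- function(clusters, category = "fact_specific") {
  sel <- !is.na(clusters$category) & clusters$category == category &
    !is.na(clusters$gene_id)
  unique(clusters$gene_id[sel])
}
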