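# Cluster expression quantification: raw tag counts per cluster and library,
# CPM/log2 normalization, replicate concordance, and the promoter-expression
# contrast between genes with and without mutant-specific clusters.

#' Raw tag counts per cluster and library
#'
#' Entry (i, j) is the sum of library j's tags on cluster i's strand within
#' its interval.
#'
#' @param clusters Cluster `GRanges`.
#' @param libraries List of [tag_library()] objects.
#' @return Integer matrix, clusters x libraries (columns named by
#'   `library_id`).
#' @export
cluster_counts <- function(clusters, libraries) {
  counts <- pool_library_counts(libraries)
  ids <- vapply(libraries, function(l) l$library_id, character(1))
  out <- matrix(0L, nrow = length(clusters), ncol = length(libraries),
                dimnames = list(NULL, ids))
  for (j in seq_along(libraries)) {
    for (s in c("+", "-")) {
      rl <- counts[[s]][[j]]
      for (ch in names(rl)) {
        i <- which(as.character(strand(clusters)) == s &
                     as.character(seqnames(clusters)) == ch)
        if (!length(i)) next
        v <- Views(rl[[ch]], start = start(clusters)[i],
                   end = end(clusters)[i])
        out[i, j] <- as.integer(viewSums(v))
      }
    }
  }
  out
}

#' CPM-normalize and log2-transform a count matrix
#'
#' Each count is scaled to counts-per-million of its library's genome-wide
#' tag total, floored with a pseudocount, and log2-transformed:
#' `log2(1e6 * count / total + pseudocount)`.
#'
#' @param counts Integer matrix from [cluster_counts()].
#' @param library_totals Per-library tag totals used as the CPM denominator;
#'   defaults to the matrix column sums (appropriate only when every tag
#'   falls inside a cluster). Pass [library_total()] values for genome-wide
#'   normalization.
#' @param pseudocount Value added after CPM scaling, before the log
#'   (default 1, so zero counts map to 0).
#' @return Numeric matrix of log2 CPM values.
#' @export
cpm_log2 <- function(counts, library_totals = colSums(counts),
                     pseudocount = 1) {
  if (any(library_totals <= 0)) stop("library with zero total tag count")
  log2(sweep(counts, 2, library_totals / 1e6, "/") + pseudocount)
}

#' Pearson correlation between replicates of a genotype
#'
#' @param matrix Expression matrix (clusters x libraries), e.g. from
#'   [cpm_log2()].
#' @param libraries List of [tag_library()] objects matching the columns.
#' @param genotype Genotype whose replicate pairs to correlate.
#' @return Data frame with one row per replicate pair: `library_a`,
#'   `library_b`, `r` (`NA` with a message if a column has zero variance).
#' @export
replicate_correlation <- function(matrix, libraries, genotype) {
  ids <- vapply(libraries, function(l) l$library_id, character(1))
  genos <- vapply(libraries, function(l) l$genotype, character(1))
  cols <- ids[genos == genotype]
  if (length(cols) < 2) stop("genotype ", genotype, " has fewer than 2 replicates")
  pairs <- utils::combn(cols, 2)
  r <- apply(pairs, 2, function(p) {
    a <- matrix[, p[1]]; b <- matrix[, p[2]]
    if (sd(a) == 0 || sd(b) == 0) {
      message("replicate_correlation: zero-variance column, r undefined")
      NA_real_
    } else cor(a, b)
  })
  data.frame(library_a = pairs[1, ], library_b = pairs[2, ], r = r)
}

#' Promoter-expression contrast between gene sets
#'
#' For every gene with a promoter-annotated cluster, computes the per-gene
#' log2 ratio of mean mutant CPM to mean wild-type CPM at that cluster
#' (replicate means, with a pseudocount on both sides), then compares the
#' ratios of genes in `genes_with` against all other genes by a two-sided
#' Wilcoxon rank-sum test. Genes with several promoter clusters use the
#' highest-scoring one.
#'
#' @param clusters Annotated, classified cluster `GRanges`.
#' @param counts Raw count matrix from [cluster_counts()].
#' @param libraries List of [tag_library()] objects matching the columns.
#' @param genes_with Character vector of gene ids forming the "with" set
#'   (e.g. from [genes_with_category()]).
#' @param mutant,wild_type Genotype labels to contrast.
#' @param pseudocount CPM pseudocount on both ratio sides (default 1).
#' @param library_totals Optional per-library tag totals for the CPM
#'   denominator; defaults to each library's genome-wide [library_total()].
#' @return List with `statistic`, `p_value`, `median_with`,
#'   `median_without`, `n_with`, `n_without`, `ratios` (named per gene) and
#'   `n_skipped` (genes in `genes_with` lacking a promoter cluster).
#' @export
promoter_ratio_contrast <- function(clusters, counts, libraries, genes_with,
                                    mutant, wild_type = "wild_type",
                                    pseudocount = 1, library_totals = NULL) {
  idx <- which(!is.na(clusters$annotation) &
                 clusters$annotation == "promoter" &
                 !is.na(clusters$gene_id))
  if (!length(idx)) stop("no promoter-annotated clusters with gene assignment")
  # one promoter cluster per gene: keep the highest-scoring
  idx <- idx[order(-clusters$score[idx])]
  idx <- idx[!duplicated(clusters$gene_id[idx])]

  genos <- vapply(libraries, function(l) l$genotype, character(1))
  totals <- library_totals %||% vapply(libraries, library_total, numeric(1))
  if (any(totals <= 0)) stop("library with zero total tag count")
  cpm <- sweep(counts[idx, , drop = FALSE], 2, totals / 1e6, "/")
  mean_of <- function(g) rowMeans(cpm[, genos == g, drop = FALSE])
  ratios <- log2((mean_of(mutant) + pseudocount) /
                   (mean_of(wild_type) + pseudocount))
  names(ratios) <- clusters$gene_id[idx]

  with_set <- names(ratios) %in% genes_with
  n_skipped <- sum(!(genes_with %in% names(ratios)))
  if (n_skipped > 0)
    message("promoter_ratio_contrast: ", n_skipped,
            " gene(s) without a promoter cluster skipped")
  if (!any(with_set)) stop("empty 'with' gene set among promoter clusters")
  if (!any(!with_set)) stop("empty 'without' gene set among promoter clusters")

  w <- wilcoxon_rank_sum(ratios[with_set], ratios[!with_set])
  list(statistic = w$statistic, p_value = w$p_value,
       median_with = median(ratios[with_set]),
       median_without = median(ratios[!with_set]),
       n_with = sum(with_set), n_without = sum(!with_set),
       ratios = ratios, n_skipped = n_skipped)
}
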