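# Position-anchored signal summarization: windowed medians for boxplots,
# metagene profiles with normal-based confidence bands, seeded control
# position sampling in exons, Wilcoxon contrasts between anchor sets, and
# resizing of single-end reads to half the insert size.

# Extract per-base values for 1-based span [s, e] from a numeric RleList,
# zero-padding bases beyond the chromosome bounds.
extract_span <- function(track, chrom, s, e) {
  if (!chrom %in% names(track)) return(numeric(e - s + 1L))
  r <- track[[chrom]]
  cs <- max(s, 1L)
  ce <- min(e, length(r))
  v <- if (cs > ce) numeric(0) else as.numeric(r[cs:ce])
  c(numeric(max(0L, cs - s)), v, numeric(max(0L, e - ce)))
}

# Extract `width` per-base values centered on a 1-based anchor: bases
# [p - width/2, p + width/2 - 1]. Bases outside the chromosome are absent
# (clipped); with pad = TRUE they come back as 0 instead.
extract_window <- function(track, chrom, pos, width, pad = FALSE) {
  half <- width %/% 2
  s <- pos - half
  e <- pos + width - half - 1L
  if (pad) return(extract_span(track, chrom, s, e))
  if (!chrom %in% names(track)) return(numeric(0))
  r <- track[[chrom]]
  cs <- max(s, 1L)
  ce <- min(e, length(r))
  if (cs > ce) numeric(0) else as.numeric(r[cs:ce])
}

#' Median signal in a window around each anchor
#'
#' The median of the `width` per-base values centered on each anchor
#' (window `[p - width/2, p + width/2)` in 0-based terms). Bases beyond the
#' chromosome edge are clipped out; absent bases inside the track count as 0.
#'
#' @param track Numeric `RleList` signal track (see [read_bedgraph()]).
#' @param anchors Width-1 `GRanges` of anchor positions.
#' @param width Window width in bases (default 20).
#' @return Numeric vector of per-anchor window medians.
#' @export
window_median <- function(track, anchors, width = 20L) {
  vapply(seq_along(anchors), function(i) {
    v <- extract_window(track, as.character(seqnames(anchors)[i]),
                        start(anchors)[i], width, pad = FALSE)
    if (!length(v)) NA_real_ else median(v)
  }, numeric(1))
}

#' Metagene profile around an anchor set
#'
#' Per-offset mean signal across anchors, oriented by anchor strand (the
#' profile of a minus-strand anchor is mirrored so that positive offsets
#' always point downstream in transcription orientation), with a
#' normal-based confidence band `mean +/- z * sd / sqrt(n)`.
#'
#' @param track Numeric `RleList` signal track.
#' @param anchors Width-1 stranded `GRanges`; at least 2 anchors are needed
#'   for the confidence band.
#' @param width Profile width in bases (default 400: offsets -200..199).
#' @param z Normal quantile for the band (default 1.96, a 95% band).
#' @return Object of class `MetageneProfile`: data frame with columns
#'   `offset`, `mean`, `ci_low`, `ci_high`; attribute `n` = number of
#'   anchors.
#' @export
metagene <- function(track, anchors, width = 400L, z = 1.96) {
  if (length(anchors) < 2) stop("metagene needs at least 2 anchors")
  half <- width %/% 2
  offs <- seq(-half, width - half - 1L)
  mat <- t(vapply(seq_along(anchors), function(i) {
    ch <- as.character(seqnames(anchors)[i])
    p <- start(anchors)[i]
    if (as.character(strand(anchors)[i]) == "-") {
      # offset o of a minus-strand anchor reads the base at p - o:
      # extract bases p - max(offs) .. p - min(offs) and reverse
      s <- p - max(offs); e <- p - min(offs)
      v <- rev(extract_span(track, ch, s, e))
    } else {
      s <- p + min(offs); e <- p + max(offs)
      v <- extract_span(track, ch, s, e)
    }
    v
  }, numeric(width)))
  m <- colMeans(mat)
  s <- apply(mat, 2, sd)
  se <- s / sqrt(nrow(mat))
  out <- data.frame(offset = seq(-half, width - half - 1L),
                    mean = m, ci_low = m - z * se, ci_high = m + z * se)
  attr(out, "n") <- length(anchors)
  class(out) <- c("MetageneProfile", class(out))
  out
}

#' Sample control positions in gene exons
#'
#' Draws `n_per_gene` positions uniformly over each gene's exonic bases,
#' then removes positions closer than `min_end_distance` bases to the gene's
#' 3' end (nascent-transcription assays show exaggerated signal near
#' polyadenylation sites). Deterministic for a given seed; genes without an
#' eligible base are skipped with a message.
#'
#' @param annotation A `GeneAnnotation`.
#' @param seed Integer RNG seed (required, for reproducible control sets).
#' @param n_per_gene Positions per gene (default 1).
#' @param min_end_distance Minimum distance to the 3' gene end in bases
#'   (default 0: no filtering).
#' @param gene_ids Optional subset of genes to sample from.
#' @param both_ends If `TRUE`, the distance filter also applies to the 5'
#'   gene end.
#' @return Width-1 stranded `GRanges` of control positions with a `gene_id`
#'   column.
#' @export
sample_control_positions <- function(annotation, seed, n_per_gene = 1L,
                                     min_end_distance = 0L, gene_ids = NULL,
                                     both_ends = FALSE) {
  stopifnot(is(annotation, "GeneAnnotation"))
  genes <- annotation$genes
  if (!is.null(gene_ids)) genes <- genes[genes$gene_id %in% gene_ids]
  exons <- annotation$exons[genes$gene_id]

  with_seed(seed, {
    picked <- lapply(seq_along(genes), function(i) {
      ex <- exons[[i]]
      bases <- unlist(mapply(seq.int, start(ex), end(ex), SIMPLIFY = FALSE))
      # eligibility filter applied before drawing keeps the draw uniform
      # over eligible bases while matching a post-hoc removal in law
      minus <- as.character(strand(genes)[i]) == "-"
      end3 <- if (minus) start(genes)[i] else end(genes)[i]
      keep <- abs(bases - end3) >= min_end_distance
      if (both_ends) {
        end5 <- if (minus) end(genes)[i] else start(genes)[i]
        keep <- keep & abs(bases - end5) >= min_end_distance
      }
      bases <- bases[keep]
      if (!length(bases)) return(NULL)
      bases[sample.int(length(bases), n_per_gene, replace = TRUE)]
    })
    n_skipped <- sum(vapply(picked, is.null, logical(1)))
    if (n_skipped > 0)
      message("sample_control_positions: ", n_skipped,
              " gene(s) without eligible exonic base skipped")
    keep <- !vapply(picked, is.null, logical(1))
    if (!any(keep)) return(GRanges())
    counts <- lengths(picked[keep])
    out <- GRanges(rep(seqnames(genes)[keep], counts),
                   IRanges(unlist(picked[keep]), width = 1L),
                   strand = rep(strand(genes)[keep], counts))
    out$gene_id <- rep(genes$gene_id[keep], counts)
    out
  })
}

#' Compare signal between two anchor sets
#'
#' Two-sided Wilcoxon rank-sum test on the per-anchor window medians of the
#' two sets (see [window_median()] and [wilcoxon_rank_sum()]).
#'
#' @param track Numeric `RleList` signal track.
#' @param set_a,set_b Width-1 `GRanges` anchor sets.
#' @param width Window width in bases (default 20).
#' @return List with `statistic`, `p_value`, `exact`, `degenerate`,
#'   `median_a`, `median_b`.
#' @export
compare_anchor_sets <- function(track, set_a, set_b, width = 20L) {
  a <- window_median(track, set_a, width)
  b <- window_median(track, set_b, width)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("anchor set with no in-bounds anchors")
  w <- wilcoxon_rank_sum(a, b)
  c(w, list(median_a = median(a), median_b = median(b)))
}

#' Boxplot statistics
#'
#' Median, quartile hinges (linear-interpolation percentiles), whiskers at
#' the most extreme data values within 1.5 IQR of the hinges, and the count
#' of values beyond the whiskers.
#'
#' @param values Non-empty numeric vector.
#' @return List with `median`, `lower_hinge`, `upper_hinge`, `whisker_low`,
#'   `whisker_high`, `n_outliers`.
#' @export
boxplot_stats <- function(values) {
  if (!length(values)) stop("no values")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  in_fence <- values >= q[1] - 1.5 * iqr & values <= q[3] + 1.5 * iqr
  list(median = q[2], lower_hinge = q[1], upper_hinge = q[3],
       whisker_low = min(values[in_fence]),
       whisker_high = max(values[in_fence]),
       n_outliers = sum(!in_fence))
}

#' Resize single-end reads to half the insert size
#'
#' Each read is replaced by an interval of `floor(insert_size / 2)` bases
#' anchored at its 3' end and extending back toward its 5' side, so that
#' coverage peaks coincide with the fragment midpoints rather than the read
#' starts. Intervals are clipped at chromosome bounds.
#'
#' @param reads Stranded `GRanges` of aligned single-end reads.
#' @param insert_size Average fragment length in bases (> 0; estimated
#'   upstream, e.g. by a peak-caller's fragment model).
#' @param seqlengths Optional named chromosome lengths for clipping.
#' @return Numeric `RleList` coverage of the resized intervals.
#' @export
resize_single_end <- function(reads, insert_size, seqlengths = NULL) {
  stopifnot(insert_size > 0)
  half <- insert_size %/% 2
  minus <- as.character(strand(reads)) == "-"
  s <- ifelse(minus, start(reads), end(reads) - half + 1L)
  e <- ifelse(minus, start(reads) + half - 1L, end(reads))
  s <- pmax(s, 1L)
  if (!is.null(seqlengths)) {
    lim <- unname(seqlengths[as.character(seqnames(reads))])
    e <- ifelse(is.na(lim), e, pmin(e, lim))
  }
  gr <- GRanges(seqnames(reads), IRanges(s, e))
  if (is.null(seqlengths)) coverage(gr)
  else {
    seqlevels(gr) <- names(seqlengths)
    seqlengths(gr) <- unname(seqlengths)
    coverage(gr)
  }
}
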