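# TSS cluster calling from multi-library 5'-tag counts.
#
# Candidate rule: a genomic position is a TSS candidate for a genotype when at
# least `min_tags` tags support it in at least `min_libraries` libraries of
# that genotype. Candidates from all genotypes are pooled into one shared
# cluster coordinate system (merge gap <= max_gap), then each cluster gets a
# score (mean tags per library), a summit (leftmost base of maximal pooled
# signal) and per-genotype detection flags.

# Library counts padded to a common universe, as list(strand -> list(lib ->
# RleList)). Shared by several stages.
pool_library_counts <- function(libraries) {
  stopifnot(length(libraries) >= 1)
  flat <- harmonize_rlelists(c(lapply(libraries, function(l) l$counts[["+"]]),
                               lapply(libraries, function(l) l$counts[["-"]])))
  n <- length(libraries)
  list("+" = flat[seq_len(n)], "-" = flat[n + seq_len(n)])
}

#' Find candidate TSS positions per genotype
#'
#' A position is a candidate for genotype g when at least `min_libraries` of
#' g's libraries each have at least `min_tags` tags at that base, on the same
#' strand. Singleton noise (one tag in one library) can never seed a
#' candidate at the default thresholds.
#'
#' @param libraries List of [tag_library()] objects; every genotype must have
#'   at least `min_libraries` libraries.
#' @param min_tags Minimum tags per library at a position (default 2).
#' @param min_libraries Minimum supporting libraries per genotype (default 2).
#' @return Object of class `CandidateSet`: list with `positions` (per
#'   genotype, a stranded `GRanges` of runs of candidate bases) and the
#'   thresholds used.
#' @export
find_candidates <- function(libraries, min_tags = 2L, min_libraries = 2L) {
  genotypes <- vapply(libraries, function(l) l$genotype, character(1))
  tab <- table(genotypes)
  if (any(tab < min_libraries))
    stop("genotype(s) with fewer than min_libraries libraries: ",
         paste(names(tab)[tab < min_libraries], collapse = ", "))
  counts <- pool_library_counts(libraries)

  per_geno <- lapply(unique(genotypes), function(g) {
    idx <- which(genotypes == g)
    res <- lapply(c("+", "-"), function(s) {
      support <- Reduce(`+`, lapply(counts[[s]][idx],
                                    function(rl) rl >= min_tags))
      ir <- slice(support, lower = min_libraries, rangesOnly = TRUE)
      gr <- as(ir, "GRanges")
      strand(gr) <- s
      gr
    })
    sort(do.call(c, res))
  })
  structure(list(positions = setNames(per_geno, unique(genotypes)),
                 min_tags = min_tags, min_libraries = min_libraries),
            class = "CandidateSet")
}

#' @export
print.CandidateSet <- function(x, ...) {
  n <- vapply(x$positions, function(g) sum(width(g)), numeric(1))
  cat("CandidateSet (min_tags =", x$min_tags, ", min_libraries =",
      x$min_libraries, "): candidate bases per genotype\n")
  print(n)
  invisible(x)
}

#' Merge candidate positions into cluster intervals
#'
#' Candidate positions from all genotypes are pooled per strand and merged
#' whenever consecutive positions lie at most `max_gap` bases apart; strands
#' never merge. The shared coordinate system lets genotype categories compare
#' like-for-like intervals.
#'
#' @param candidates A `CandidateSet` (or a stranded `GRanges` of candidate
#'   positions/runs).
#' @param max_gap Maximum distance between consecutive member positions
#'   (default 20).
#' @return Sorted stranded `GRanges` of cluster intervals.
#' @export
cluster_candidates <- function(candidates, max_gap = 20L) {
  gr <- if (is(candidates, "CandidateSet")) {
    suppressWarnings(do.call(c, unname(candidates$positions)))
  } else candidates
  # reduce() merges ranges separated by a gap < min.gapwidth, i.e. by
  # positions at distance <= min.gapwidth; strand-aware by default.
  sort(reduce(gr, min.gapwidth = max_gap))
}

#' Score and summit of cluster intervals
#'
#' Score = total tags over all bases of the interval, over all libraries,
#' divided by the number of libraries in the experiment. Summit = base with
#' the maximal pooled count, ties broken towards the smallest coordinate.
#'
#' @param clusters Stranded `GRanges` of cluster intervals.
#' @param libraries List of [tag_library()] objects.
#' @return `clusters` with metadata columns `score` and `summit` added.
#' @export
score_and_summit <- function(clusters, libraries) {
  counts <- pool_library_counts(libraries)
  n_lib <- length(libraries)
  pooled <- lapply(counts, function(per_lib) Reduce(`+`, per_lib))

  score <- numeric(length(clusters))
  summit <- integer(length(clusters))
  for (s in c("+", "-")) {
    for (ch in names(pooled[[s]])) {
      i <- which(as.character(strand(clusters)) == s &
                   as.character(seqnames(clusters)) == ch)
      if (!length(i)) next
      v <- Views(pooled[[s]][[ch]], start = start(clusters)[i],
                 end = end(clusters)[i])
      tot <- viewSums(v)
      if (any(tot == 0))
        stop("cluster interval without any tags (", ch, ":",
             start(clusters)[i][tot == 0][1], ")")
      score[i] <- tot / n_lib
      summit[i] <- start(clusters)[i] + viewWhichMaxs(v) - start(v)
    }
  }
  clusters$score <- score
  clusters$summit <- summit
  clusters
}

#' Per-genotype detection flags for clusters
#'
#' A cluster is detected in genotype g when at least one base inside its
#' interval is a candidate position for g (same strand).
#'
#' @param clusters Stranded `GRanges` of cluster intervals.
#' @param candidates A `CandidateSet`.
#' @return Logical matrix, clusters x genotypes.
#' @export
detection_flags <- function(clusters, candidates) {
  stopifnot(is(candidates, "CandidateSet"))
  genos <- names(candidates$positions)
  flags <- vapply(genos, function(g)
    overlapsAny(clusters, candidates$positions[[g]]),
    logical(length(clusters)))
  if (length(clusters) == 1L) flags <- matrix(flags, nrow = 1,
                                              dimnames = list(NULL, genos))
  flags
}

#' Call TSS clusters from tag libraries
#'
#' Composition of the calling stages: per-genotype candidate finding, pooled
#' merging into clusters, scoring/summit assignment and per-genotype
#' detection flags. Clusters come back sorted by (chromosome, start, strand)
#' with empty annotation/category columns for the downstream stages.
#'
#' @inheritParams find_candidates
#' @inheritParams cluster_candidates
#' @return Stranded `GRanges` of TSS clusters with metadata columns `score`,
#'   `summit`, `detected_in` (logical matrix, one column per genotype),
#'   `annotation`, `category`, `gene_id`, `gene_name`.
#' @export
call_tss <- function(libraries, min_tags = 2L, min_libraries = 2L,
                     max_gap = 20L) {
  cand <- find_candidates(libraries, min_tags, min_libraries)
  clusters <- cluster_candidates(cand, max_gap)
  if (length(clusters) == 0) {
    clusters$score <- numeric(0)
    clusters$summit <- integer(0)
    clusters$detected_in <- matrix(logical(0), nrow = 0,
                                   ncol = length(cand$positions),
                                   dimnames = list(NULL,
                                                   names(cand$positions)))
  } else {
    clusters <- score_and_summit(clusters, libraries)
    clusters$detected_in <- detection_flags(clusters, cand)
  }
  clusters$annotation <- rep(NA_character_, length(clusters))
  clusters$category <- rep(NA_character_, length(clusters))
  clusters$gene_id <- rep(NA_character_, length(clusters))
  clusters$gene_name <- rep(NA_character_, length(clusters))
  sort(clusters)
}

#' Write clusters as a tab-separated table
#'
#' Columns `Chr`, `Start`, `End`, `Strand`, `Score`, `Summit`, `Annotation`,
#' `Category`, `Gene_ID`, `Gene_name`. Coordinates are 1-based inclusive;
#' `Summit` is the 1-based summit base.
#'
#' @param clusters Cluster `GRanges` from [call_tss()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_clusters <- function(clusters, path) {
  df <- data.frame(
    Chr = as.character(seqnames(clusters)),
    Start = start(clusters),
    End = end(clusters),
    Strand = as.character(strand(clusters)),
    Score = clusters$score,
    Summit = clusters$summit,
    Annotation = clusters$annotation %||% NA_character_,
    Category = clusters$category %||% NA_character_,
    Gene_ID = clusters$gene_id %||% NA_character_,
    Gene_name = clusters$gene_name %||% NA_character_,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
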