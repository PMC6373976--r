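# Shared in-code fixtures: tiny genomes, tag libraries and tracks built
# programmatically so every test is self-contained.

library(GenomicRanges)
library(IRanges)
library(S4Vectors)

# A GRanges gene span from 0-based half-open coordinates (the native
# coordinates of the tag tracks), converting to the package's 1-based
# internal representation.
gr0 <- function(chrom, start0, end0, strand = "+", seqlen = NULL) {
  g <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  if (!is.null(seqlen)) seqlengths(g) <- setNames(seqlen, chrom)
  g
}

# Minimal annotation: genes given as list(name = list(chrom, start0, end0,
# strand, exons = list(c(start0, end0), ...)))
make_annotation <- function(genes, seqlen = c(chr1 = 100000L)) {
  spans <- do.call(c, unname(lapply(genes, function(g)
    gr0(g$chrom %||% "chr1", g$start0, g$end0, g$strand %||% "+"))))
  spans$gene_id <- names(genes)
  spans$gene_name <- names(genes)
  seqlengths(spans) <- seqlen[seqlevels(spans)]
  exons <- GRangesList(lapply(genes, function(g) {
    ex <- g$exons %||% list(c(g$start0, g$end0))
    do.call(c, unname(lapply(ex, function(e)
      gr0(g$chrom %||% "chr1", e[1], e[2], g$strand %||% "+"))))
  }))
  gene_annotation(spans, exons, seqlengths = seqlen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Attach the gene_id/gene_name columns feature derivations expect.
within_gene_id <- function(g) {
  g$gene_id <- "g"
  g$gene_name <- "g"
  g
}

# Rle track from a plain numeric vector (chromosome = its full length).
rle_track <- function(values, chrom = "chr1") {
  as(setNames(list(Rle(values)), chrom), "RleList")
}

# A TagLibrary from sparse counts: named list strand -> data.frame(pos
# (1-based), count), on a single chromosome of length `len`.
make_library <- function(id, genotype, replicate, plus = NULL, minus = NULL,
                         len = 10000L, chrom = "chr1") {
  vec <- function(df) {
    v <- integer(len)
    if (!is.null(df) && nrow(df)) v[df$pos] <- as.integer(df$count)
    as(setNames(list(Rle(v)), chrom), "RleList")
  }
  tag_library(id, genotype, replicate, vec(plus), vec(minus))
}

pos_counts <- function(pos, count) data.frame(pos = pos, count = count)

# Six-library (2 reps x 3 genotypes) set from a function(genotype, rep) ->
# list(plus=, minus=) sparse count spec.
make_library_set <- function(spec_fun, len = 10000L) {
  out <- list()
  for (g in c("wild_type", "spt16", "ssrp1")) {
    for (r in 1:2) {
      s <- spec_fun(g, r)
      out[[length(out) + 1L]] <- make_library(
        paste0(g, "_r", r), g, r, plus = s$plus, minus = s$minus, len = len)
    }
  }
  out
}

# Brute-force per-base values of an RleList chromosome (absent = 0) over
# 1-based positions.
naive_values <- function(track, chrom, positions) {
  v <- if (chrom %in% names(track)) as.numeric(track[[chrom]]) else numeric(0)
  vapply(positions, function(p) if (p >= 1 && p <= length(v)) v[p] else 0,
         numeric(1))
}
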