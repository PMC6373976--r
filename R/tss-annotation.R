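# Annotation of TSS clusters: each cluster gets the single highest-priority
# feature category it intersects, and (for genic annotations) the nearest
# same-strand gene within 500 bp.

#' Annotation priority hierarchy
#'
#' Fixed category order from lowest to highest priority used to resolve
#' conflicting feature overlaps.
#'
#' @export
ANNOTATION_HIERARCHY <- c("intergenic", "antisense", "intron", "exon",
                          "threeUTR", "fiveUTR", "proximal", "promoter")

#' Feature categories overlapping each cluster
#'
#' Genic categories (promoter, proximal, fiveUTR, exon, intron, threeUTR)
#' require same-strand overlap of at least one base; `antisense` means
#' overlap with a gene span on the opposite strand. `intergenic` is the
#' implicit floor and is always available.
#'
#' @param clusters Stranded `GRanges` of cluster intervals.
#' @param features A `FeatureSet` from [build_feature_set()].
#' @return Logical matrix, clusters x categories (excluding `intergenic`).
#' @export
overlapping_categories <- function(clusters, features) {
  stopifnot(is(features, "FeatureSet"))
  genic <- c("antisense", "intron", "exon", "threeUTR", "fiveUTR",
             "proximal", "promoter")
  out <- matrix(FALSE, nrow = length(clusters), ncol = length(genic),
                dimnames = list(NULL, genic))
  for (cat in setdiff(genic, "antisense")) {
    f <- features[[cat]]
    if (length(f))
      out[, cat] <- overlapsAny(clusters, f, ignore.strand = FALSE)
  }
  out[, "antisense"] <- overlapsAny(invertStrand(clusters), features$genes,
                                    ignore.strand = FALSE)
  out
}

#' Resolve a category set to a single annotation
#'
#' Picks the highest-priority member of each cluster's category set;
#' an empty set resolves to `intergenic`.
#'
#' @param categories Logical matrix from [overlapping_categories()], or a
#'   character vector of category names for a single cluster.
#' @return Character vector of annotations.
#' @export
resolve_annotation <- function(categories) {
  if (is.character(categories)) {
    unknown <- setdiff(categories, ANNOTATION_HIERARCHY)
    if (length(unknown)) stop("unknown category: ",
                              paste(unknown, collapse = ", "))
    if (!length(categories)) return("intergenic")
    return(ANNOTATION_HIERARCHY[max(match(categories, ANNOTATION_HIERARCHY))])
  }
  unknown <- setdiff(colnames(categories), ANNOTATION_HIERARCHY)
  if (length(unknown)) stop("unknown category: ",
                            paste(unknown, collapse = ", "))
  prio <- match(colnames(categories), ANNOTATION_HIERARCHY)
  apply(categories, 1, function(row) {
    if (!any(row)) "intergenic"
    else ANNOTATION_HIERARCHY[max(prio[row])]
  })
}

#' Assign the nearest same-strand gene to clusters
#'
#' A cluster gets the same-strand gene it overlaps, or else the nearest
#' same-strand gene whose edge-to-edge distance is at most `max_dist` bases;
#' ties go to the gene with the smaller start. Clusters annotated
#' `intergenic` or `antisense` are never assigned a gene.
#'
#' @param clusters Annotated cluster `GRanges` (with an `annotation` column).
#' @param genes Stranded `GRanges` of gene spans with `gene_id`/`gene_name`.
#' @param max_dist Maximum edge distance in bases (default 500).
#' @return `clusters` with `gene_id` and `gene_name` filled in.
#' @export
assign_gene <- function(clusters, genes, max_dist = 500L) {
  gene_id <- rep(NA_character_, length(clusters))
  gene_name <- rep(NA_character_, length(clusters))
  ann <- clusters$annotation
  eligible <- which(!(ann %in% c("intergenic", "antisense")) & !is.na(ann))

  g_chr <- as.character(seqnames(genes))
  g_str <- as.character(strand(genes))
  for (i in eligible) {
    same <- which(g_chr == as.character(seqnames(clusters)[i]) &
                    g_str == as.character(strand(clusters)[i]))
    if (!length(same)) next
    gs <- start(genes)[same]; ge <- end(genes)[same]
    cs <- start(clusters)[i]; ce <- end(clusters)[i]
    # edge-to-edge gap: bases strictly between the two intervals
    d <- pmax(0L, pmax(gs - ce, cs - ge) - 1L)
    ok <- which(d <= max_dist)
    if (!length(ok)) next
    best <- ok[order(d[ok], gs[ok])][1]
    gene_id[i] <- genes$gene_id[same[best]]
    gene_name[i] <- genes$gene_name[same[best]]
  }
  clusters$gene_id <- gene_id
  clusters$gene_name <- gene_name
  clusters
}

#' Annotate clusters through the feature hierarchy
#'
#' Sets each cluster's single `annotation` (via [overlapping_categories()]
#' and [resolve_annotation()]) and its `gene_id`/`gene_name` (via
#' [assign_gene()]).
#'
#' @param clusters Cluster `GRanges` from [call_tss()].
#' @param features A `FeatureSet`.
#' @param max_dist Gene-assignment distance passed to [assign_gene()].
#' @return Annotated cluster `GRanges`.
#' @export
annotate_clusters <- function(clusters, features, max_dist = 500L) {
  if (length(clusters) == 0) return(clusters)
  cats <- overlapping_categories(clusters, features)
  clusters$annotation <- resolve_annotation(cats)
  assign_gene(clusters, features$genes, max_dist = max_dist)
}
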