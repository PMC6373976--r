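# Gene models and derived annotation feature regions.
#
# A gene annotation holds one representative model per gene: a stranded span,
# its exons, and optional UTR sub-features. Feature regions derived from it
# (promoter, proximal upstream, introns, ...) feed the annotation hierarchy.

#' Construct a gene annotation
#'
#' Bundles gene spans with their exon (and optional UTR) structure into a
#' validated container. One representative model per gene; overlapping exons
#' within a gene are unioned before use.
#'
#' @param genes `GRanges` of stranded gene spans with metadata columns
#'   `gene_id` (required, unique) and optionally `gene_name`.
#' @param exons `GRangesList` of exons, named by `gene_id`. Exons must lie
#'   within the gene span; they are sorted and unioned per gene.
#' @param utr5,utr3 Optional `GRangesList` of UTR intervals (named by
#'   `gene_id`), each contained in the gene's exon union.
#' @param seqlengths Optional named integer vector of chromosome lengths;
#'   taken from `genes` if already set there.
#' @return An object of class `GeneAnnotation`: a list with elements `genes`,
#'   `exons`, `utr5`, `utr3`, `seqlengths`.
#' @export
gene_annotation <- function(genes, exons, utr5 = NULL, utr3 = NULL,
                            seqlengths = NULL) {
  stopifnot(is(genes, "GRanges"), is(exons, "GRangesList"))
  if (is.null(genes$gene_id)) stop("genes must carry a 'gene_id' column")
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  if (is.null(genes$gene_name)) genes$gene_name <- genes$gene_id
  if (!setequal(names(exons), genes$gene_id))
    stop("exons must be named by gene_id, one element per gene")
  if (any(lengths(exons) == 0L)) stop("every gene must have at least one exon")

  exons <- reduce(exons)  # sort, merge overlapping exons per gene
  spans <- genes[match(names(exons), genes$gene_id)]
  rep_n <- lengths(exons)
  bad <- any(unlist(start(exons)) < rep(start(spans), rep_n)) ||
    any(unlist(end(exons)) > rep(end(spans), rep_n)) ||
    !all(as.character(unlist(seqnames(exons), use.names = FALSE)) ==
           rep(as.character(seqnames(spans)), rep_n))
  if (bad) stop("malformed gene model: exon outside gene span")

  if (!is.null(seqlengths)) {
    seqlengths(genes) <- seqlengths[seqlevels(genes)]
  }
  for (u in list(utr5, utr3)) {
    if (!is.null(u) && !all(names(u) %in% genes$gene_id))
      stop("UTRs named for unknown gene_id")
  }
  structure(
    list(genes = genes, exons = exons, utr5 = utr5, utr3 = utr3,
         seqlengths = seqlengths(genes)),
    class = "GeneAnnotation"
  )
}

#' @export
print.GeneAnnotation <- function(x, ...) {
  cat("GeneAnnotation:", length(x$genes), "genes on",
      length(seqlevels(x$genes)), "chromosome(s)\n")
  invisible(x)
}

#' Position of the 5' end base of each gene
#'
#' The "gene start" in transcription orientation: the span's first base on the
#' plus strand, its last base on the minus strand.
#'
#' @param genes Stranded `GRanges` of gene spans.
#' @return Integer vector of 1-based positions, one per gene.
#' @export
five_prime_end <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
}

# Clip a window to [1, seqlength] without dropping it. Widths may shrink.
clip_to_chrom <- function(chrom, start, end, strand, seqlen) {
  start <- pmax(start, 1L)
  if (!is.null(seqlen)) {
    lim <- unname(seqlen[as.character(chrom)])
    end <- ifelse(is.na(lim), end, pmin(end, lim))
  }
  GRanges(chrom, IRanges(start, end), strand = strand)
}

#' Promoter windows around gene 5' ends
#'
#' A symmetric window of `flank` bases on each side of the 5'-end base
#' (2*`flank`+1 bases total, 201 by default), identical on both strands and
#' clipped at chromosome bounds.
#'
#' @param genes Stranded `GRanges` of gene spans (with `seqlengths` for
#'   clipping at the right edge).
#' @param flank Bases on each side of the 5'-end base (default 100).
#' @return `GRanges` of promoter windows carrying the source `gene_id`.
#' @export
derive_promoter <- function(genes, flank = 100L) {
  g <- five_prime_end(genes)
  out <- clip_to_chrom(seqnames(genes), g - flank, g + flank,
                       strand(genes), seqlengths(genes))
  out$gene_id <- genes$gene_id
  out
}

#' Proximal upstream windows
#'
#' The window strictly upstream of the promoter, covering bases
#' `flank_near`+1 .. `flank_far` upstream of the 5'-end base in transcription
#' orientation (401..101 upstream by default is excluded/included so the
#' window holds 400 bases), clipped at chromosome bounds.
#'
#' @inheritParams derive_promoter
#' @param flank_far,flank_near Outer and inner upstream distances in bases
#'   (defaults 500 and 100): the window is `[g-flank_far, g-flank_near)` in
#'   transcription orientation.
#' @return `GRanges` of proximal windows carrying the source `gene_id`.
#' @export
derive_proximal <- function(genes, flank_far = 500L, flank_near = 100L) {
  g <- five_prime_end(genes)
  minus <- as.character(strand(genes)) == "-"
  s <- ifelse(minus, g + flank_near + 1L, g - flank_far)
  e <- ifelse(minus, g + flank_far, g - flank_near - 1L)
  out <- clip_to_chrom(seqnames(genes), s, e, strand(genes),
                       seqlengths(genes))
  out$gene_id <- genes$gene_id
  out
}

#' Introns as the exon complement within each gene span
#'
#' @param annotation A `GeneAnnotation`.
#' @return `GRangesList` of intron intervals per gene (empty element for
#'   single-exon genes).
#' @export
derive_introns <- function(annotation) {
  stopifnot(is(annotation, "GeneAnnotation"))
  ex <- annotation$exons
  spans <- unlist(range(ex))  # first-exon start to last-exon end, per gene
  psetdiff(spans, ex[names(spans)])
}

#' Build the feature set used by the annotation hierarchy
#'
#' Derives per-category interval collections (promoter, proximal, fiveUTR,
#' exon, intron, threeUTR) from every gene, plus the stranded gene spans used
#' for antisense determination. Categories may overlap; resolving conflicts is
#' the annotator's job.
#'
#' @param annotation A `GeneAnnotation`.
#' @return Object of class `FeatureSet`: a list of `GRanges`, one per
#'   category, plus `genes` (stranded spans).
#' @export
build_feature_set <- function(annotation) {
  stopifnot(is(annotation, "GeneAnnotation"))
  genes <- annotation$genes
  flat <- function(grl) {
    if (is.null(grl)) return(GRanges())
    gr <- unlist(grl, use.names = TRUE)
    gr$gene_id <- names(gr)
    names(gr) <- NULL
    gr
  }
  structure(
    list(promoter  = derive_promoter(genes),
         proximal  = derive_proximal(genes),
         fiveUTR   = flat(annotation$utr5),
         exon      = flat(annotation$exons),
         intron    = flat(derive_introns(annotation)),
         threeUTR  = flat(annotation$utr3),
         genes     = genes),
    class = "FeatureSet"
  )
}

#' @export
print.FeatureSet <- function(x, ...) {
  n <- vapply(x[setdiff(names(x), "genes")], length, integer(1))
  cat("FeatureSet over", length(x$genes), "genes:\n")
  print(n)
  invisible(x)
}

#' Genome-wide exonic and intronic base composition
#'
#' Total exonic and intronic bases (each a strand-ignored union across genes,
#' so shared bases count once per category) and their ratio. This is the
#' genome-composition baseline against which the exon bias of intragenic TSS
#' locations is judged.
#'
#' @param annotation A `GeneAnnotation`.
#' @return List with `exonic_bases`, `intronic_bases`, `ratio`
#'   (exonic/intronic, `NA` if no introns).
#' @export
base_composition <- function(annotation) {
  ex <- sum(width(reduce(unlist(annotation$exons), ignore.strand = TRUE)))
  intr <- sum(width(reduce(unlist(derive_introns(annotation)),
                           ignore.strand = TRUE)))
  list(exonic_bases = ex, intronic_bases = intr,
       ratio = if (intr > 0) ex / intr else NA_real_)
}

#' Read gene models from a GFF3 file
#'
#' Reads features of type `gene`, `exon`, `five_prime_UTR` and
#' `three_prime_UTR` (other types are ignored with a message). Exons and UTRs
#' are attached to genes via their `Parent` attribute.
#'
#' @param path Path to a GFF3 file.
#' @param seqlengths Optional named chromosome lengths.
#' @return A `GeneAnnotation`.
#' @export
read_gff_genes <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (is.null(seqlengths)) {
    # recover chromosome lengths from sequence-region directives
    hdr <- grep("^##sequence-region", readLines(path, warn = FALSE),
                value = TRUE)
    if (length(hdr)) {
      f <- strsplit(trimws(hdr), "[ \t]+")
      seqlengths <- setNames(
        vapply(f, function(x) as.integer(x[4]), integer(1)),
        vapply(f, function(x) x[2], character(1)))
    }
  }
  keep <- c("gene", "exon", "five_prime_UTR", "three_prime_UTR")
  n_ignored <- sum(!(as.character(gr$type) %in% keep))
  if (n_ignored > 0)
    message("read_gff_genes: ignored ", n_ignored,
            " feature(s) of unhandled type")
  genes <- gr[gr$type == "gene"]
  if (length(genes) == 0) stop("no gene features in ", path)
  ids <- as.character(genes$ID)
  g <- granges(genes)
  g$gene_id <- ids
  g$gene_name <- if (!is.null(genes$Name))
    ifelse(is.na(genes$Name) | genes$Name == "", ids,
           as.character(genes$Name)) else ids

  sub_list <- function(type) {
    f <- gr[gr$type == type]
    if (length(f) == 0) return(NULL)
    parent <- as.character(unlist(f$Parent))
    splt <- split(granges(f), factor(parent, levels = ids))
    splt[lengths(splt) > 0]
  }
  exons <- sub_list("exon")
  if (is.null(exons)) stop("no exon features in ", path)
  gene_annotation(g, exons, utr5 = sub_list("five_prime_UTR"),
                  utr3 = sub_list("three_prime_UTR"),
                  seqlengths = seqlengths)
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [read_gff_genes()]: emits gene and exon (plus UTR, if present)
#' records with `ID`/`Name`/`Parent` attributes.
#'
#' @param annotation A `GeneAnnotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(annotation, path) {
  genes <- annotation$genes
  g <- granges(genes)
  g$type <- "gene"
  g$ID <- genes$gene_id
  g$Name <- genes$gene_name
  recs <- list(g)
  add <- function(grl, type) {
    if (is.null(grl) || length(grl) == 0) return()
    gr <- unlist(grl, use.names = TRUE)
    out <- granges(gr)
    out$type <- type
    out$ID <- NA_character_
    out$Name <- NA_character_
    out$Parent <- names(gr)
    names(out) <- NULL
    recs[[length(recs) + 1L]] <<- out
  }
  add(annotation$exons, "exon")
  add(annotation$utr5, "five_prime_UTR")
  add(annotation$utr3, "three_prime_UTR")
  all <- suppressWarnings(do.call(c, recs))
  all$source <- "intratss"
  rtracklayer::export(sort(all), path, format = "gff3")
  # rtracklayer does not emit sequence-region directives; add them so
  # chromosome lengths survive the round trip
  sl <- annotation$seqlengths
  sl <- sl[!is.na(sl)]
  if (length(sl)) {
    lines <- readLines(path, warn = FALSE)
    directives <- sprintf("##sequence-region %s 1 %d", names(sl),
                          as.integer(sl))
    writeLines(c(lines[1], directives, lines[-1]), path)
  }
  invisible(path)
}
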