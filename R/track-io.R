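# Reading and writing the track/interval formats the pipeline touches:
# bedGraph (stranded 5'-tag counts, unstranded signal), BED points, and the
# library manifest. Per-base values are held as IRanges RleList coverage
# objects (absent base = 0).

# Scan a bedGraph file for the first malformed record and report its line
# number; used to produce a useful diagnostic when parsing fails.
diagnose_bedgraph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "track") ||
        startsWith(ln, "browser")) next
    f <- strsplit(ln, "[ \t]+")[[1]]
    ok <- length(f) >= 4 && !is.na(suppressWarnings(as.numeric(f[2]))) &&
      !is.na(suppressWarnings(as.numeric(f[3]))) &&
      !is.na(suppressWarnings(as.numeric(f[4]))) &&
      as.numeric(f[2]) >= 0 && as.numeric(f[3]) > as.numeric(f[2])
    if (!ok) return(i)
  }
  NA_integer_
}

#' Read a bedGraph file into per-base values
#'
#' Expands 4-column bedGraph records (0-based half-open, as written by
#' coverage tools) into a per-base value map. Track/browser/comment lines are
#' skipped. Overlapping records are an error: a bedGraph track must define one
#' value per base.
#'
#' @param path Path to a bedGraph file.
#' @param seqlengths Optional named chromosome lengths; otherwise each
#'   chromosome extends to its last covered base.
#' @return A numeric `RleList`, one run-length vector per chromosome
#'   (absent bases = 0).
#' @export
read_bedgraph <- function(path, seqlengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) {
      line <- diagnose_bedgraph(path)
      stop("malformed bedGraph record in ", path,
           if (!is.na(line)) paste0(" at line ", line), ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (is.null(gr$score)) gr$score <- numeric(length(gr))
  if (!isDisjoint(gr)) {
    hit <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    stop("overlapping bedGraph records in ", path, " (records ",
         queryHits(hit)[1], " and ", subjectHits(hit)[1], ")")
  }
  if (is.null(seqlengths)) {
    coverage(gr, weight = "score")
  } else {
    if (!all(seqlevels(gr) %in% names(seqlengths)))
      stop("bedGraph chromosome absent from seqlengths: ",
           paste(setdiff(seqlevels(gr), names(seqlengths)), collapse = ", "))
    seqlevels(gr) <- names(seqlengths)
    seqlengths(gr) <- unname(seqlengths)
    coverage(gr, weight = "score")
  }
}

#' Write per-base values as bedGraph
#'
#' Maximal runs of equal adjacent non-zero values are emitted as single
#' records, sorted by chromosome then start. Zero runs are omitted (bedGraph
#' sparsity contract: absent = 0).
#'
#' @param values A numeric `RleList` as returned by [read_bedgraph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, path) {
  gr <- as(values, "GRanges")  # one range per run, score = run value
  gr <- gr[gr$score != 0]
  rtracklayer::export(sort(gr), path, format = "bedGraph")
  invisible(path)
}

#' Read point anchors from a BED file
#'
#' Single-base records yield their base; wider intervals yield their midpoint
#' (floored, in 0-based coordinates). Strand is kept when the BED file has
#' one, `*` otherwise.
#'
#' @param path Path to a BED3/BED6 file.
#' @return A sorted width-1 `GRanges` of points.
#' @export
read_bed_points <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("malformed BED file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  # 0-based floor midpoint: floor((start0 + end0)/2); width-1 records keep
  # their own base.
  mid0 <- floor((start(gr) - 1 + end(gr)) / 2)
  pts <- GRanges(seqnames(gr), IRanges(mid0 + 1L, width = 1L),
                 strand = strand(gr))
  names(pts) <- names(gr)
  sort(pts)
}

#' A tag library: stranded per-base 5'-tag counts
#'
#' @param library_id Unique library identifier.
#' @param genotype Genotype label (e.g. `"wild_type"`, `"spt16"`).
#' @param replicate Positive integer replicate index.
#' @param plus,minus Integer-valued `RleList` of per-base tag counts on each
#'   strand.
#' @return An object of class `TagLibrary`.
#' @export
tag_library <- function(library_id, genotype, replicate, plus, minus) {
  stopifnot(is(plus, "RleList"), is(minus, "RleList"))
  for (rl in list(plus, minus)) {
    v <- unlist(runValue(rl), use.names = FALSE)
    if (length(v) && (any(v < 0) || any(v %% 1 != 0)))
      stop("5'-tag counts must be non-negative integers")
  }
  structure(
    list(library_id = as.character(library_id),
         genotype = as.character(genotype),
         replicate = as.integer(replicate),
         counts = list("+" = plus, "-" = minus)),
    class = "TagLibrary"
  )
}

#' @export
print.TagLibrary <- function(x, ...) {
  cat(sprintf("TagLibrary %s (%s, rep %d): %d tags\n", x$library_id,
              x$genotype, x$replicate, library_total(x)))
  invisible(x)
}

#' Total tag count of a library
#'
#' @param library A `TagLibrary`.
#' @return Integer sum of all per-base counts on both strands.
#' @export
library_total <- function(library) {
  as.integer(sum(vapply(library$counts,
                        function(rl) sum(as.numeric(sum(rl))), numeric(1))))
}

# Pad every RleList in a set to a common chromosome universe/length so that
# element-wise arithmetic across libraries is well defined.
harmonize_rlelists <- function(rls, seqlengths = NULL) {
  if (is.null(seqlengths)) {
    chroms <- unique(unlist(lapply(rls, names)))
    seqlengths <- setNames(integer(length(chroms)), chroms)
    for (rl in rls) {
      ln <- lengths(rl)
      seqlengths[names(ln)] <- pmax(seqlengths[names(ln)], ln)
    }
  }
  lapply(rls, function(rl) {
    as(setNames(lapply(names(seqlengths), function(ch) {
      n <- seqlengths[[ch]]
      if (ch %in% names(rl)) {
        r <- rl[[ch]]
        if (length(r) < n) c(r, Rle(0L, n - length(r)))
        else if (length(r) > n) stop("track longer than chromosome ", ch)
        else r
      } else Rle(0L, n)
    }), names(seqlengths)), "RleList")
  })
}

#' Read a library manifest
#'
#' A tab-separated file with header
#' `library_id genotype replicate plus_path minus_path`; paths are resolved
#' relative to the manifest's directory.
#'
#' @param path Path to the manifest TSV.
#' @return Data frame with absolute `plus_path`/`minus_path`.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("library_id", "genotype", "replicate", "plus_path", "minus_path")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  abs <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m$plus_path <- abs(m$plus_path)
  m$minus_path <- abs(m$minus_path)
  m
}

#' Load tag libraries listed in a manifest
#'
#' Reads each library's stranded bedGraph pair, coerces values to integer tag
#' counts (non-integer values are an error), and pads all libraries to a
#' shared chromosome universe.
#'
#' @param manifest Data frame as returned by [read_manifest()], or a path to
#'   a manifest TSV.
#' @param seqlengths Optional named chromosome lengths.
#' @return List of [tag_library()] objects.
#' @export
load_libraries <- function(manifest, seqlengths = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!is.null(seqlengths)) {
    seqlengths <- seqlengths[!is.na(seqlengths)]
    if (!length(seqlengths)) seqlengths <- NULL
  }
  if (anyDuplicated(manifest$library_id))
    stop("duplicate library_id in manifest")
  if (nrow(manifest) == 0) stop("empty manifest")

  raw <- lapply(seq_len(nrow(manifest)), function(i) {
    list(plus = read_bedgraph(manifest$plus_path[i], seqlengths),
         minus = read_bedgraph(manifest$minus_path[i], seqlengths))
  })
  flat <- harmonize_rlelists(
    c(lapply(raw, `[[`, "plus"), lapply(raw, `[[`, "minus")), seqlengths)
  n <- nrow(manifest)
  lapply(seq_len(n), function(i) {
    pl <- flat[[i]]
    mi <- flat[[n + i]]
    for (rl in list(pl, mi)) {
      v <- unlist(runValue(rl), use.names = FALSE)
      if (length(v) && any(v %% 1 != 0))
        stop("non-integer 5'-tag count in library ",
             manifest$library_id[i], ": tags are counts")
    }
    tag_library(manifest$library_id[i], manifest$genotype[i],
                manifest$replicate[i], pl, mi)
  })
}
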