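# End-to-end orchestration: input validation and a single entry point that
# chains calling, annotation, classification and quantification into a
# reproducible output bundle.

#' Pipeline configuration
#'
#' @param manifest Path to the library manifest TSV (see [read_manifest()]).
#' @param genome Path to the gene-model GFF3.
#' @param outdir Output directory.
#' @param cage Optional path to a BED file of external peak summits.
#' @param tracks Optional named character vector of signal bedGraph paths.
#' @param wild_type,mutants Genotype role labels.
#' @param min_tags,min_libraries,max_gap Calling parameters (see
#'   [call_tss()]).
#' @param pseudocount CPM pseudocount (see [cpm_log2()]).
#' @param seed Integer seed for any sampled quantities.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(manifest, genome, outdir, cage = NULL,
                            tracks = NULL, wild_type = "wild_type",
                            mutants = c("spt16", "ssrp1"),
                            min_tags = 2L, min_libraries = 2L,
                            max_gap = 20L, pseudocount = 1, seed = 1L) {
  stopifnot(min_tags >= 1, min_libraries >= 1, max_gap >= 0)
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Validate pipeline inputs
#'
#' Checks file existence and format, genotype/replicate coverage against the
#' configured roles, and chromosome-namespace consistency between manifest
#' tracks and the genome. Returns the failures found instead of erroring.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of failure descriptions (empty when all checks
#'   pass).
#' @export
validate_inputs <- function(config) {
  fail <- character(0)
  note <- function(msg) fail <<- c(fail, msg)

  man <- tryCatch(read_manifest(config$manifest), error = function(e) {
    note(paste("manifest:", conditionMessage(e))); NULL
  })
  ann <- tryCatch(suppressMessages(read_gff_genes(config$genome)),
                  error = function(e) {
                    note(paste("genome:", conditionMessage(e))); NULL
                  })
  if (!is.null(man)) {
    if (anyDuplicated(man$library_id))
      note("manifest: duplicate library_id")
    if (!(config$wild_type %in% man$genotype))
      note(paste0("manifest: wild-type genotype '", config$wild_type,
                  "' absent"))
    for (m in config$mutants)
      if (!(m %in% man$genotype))
        note(paste0("manifest: mutant genotype '", m, "' absent"))
    tab <- table(man$genotype)
    low <- names(tab)[tab < config$min_libraries]
    if (length(low))
      note(paste("manifest: genotype(s) below min_libraries:",
                 paste(low, collapse = ", ")))
    chroms <- character(0)
    for (i in seq_len(nrow(man))) {
      for (p in c(man$plus_path[i], man$minus_path[i])) {
        if (!file.exists(p)) { note(paste("missing track file:", p)); next }
        cov <- tryCatch(read_bedgraph(p), error = function(e) {
          note(paste0(p, ": ", conditionMessage(e))); NULL
        })
        if (!is.null(cov)) chroms <- union(chroms, names(cov))
      }
    }
    if (!is.null(ann)) {
      missing <- setdiff(seqlevels(ann$genes), chroms)
      if (length(missing) && length(chroms))
        note(paste("genome chromosome(s) absent from tag tracks:",
                   paste(missing, collapse = ", ")))
    }
  }
  if (!is.null(config$cage) && !file.exists(config$cage))
    note(paste("missing CAGE file:", config$cage))
  for (t in config$tracks %||% character(0))
    if (!file.exists(t)) note(paste("missing signal track:", t))
  fail
}

#' Run the full analysis pipeline
#'
#' Loads the libraries and genome, calls, annotates and classifies TSS
#' clusters, quantifies expression, and (when provided) computes external
#' summit overlap fractions. Writes the cluster table, category and
#' annotation summaries, the expression matrix and a run manifest recording
#' all parameters and input checksums. On a stage error, partial outputs are
#' removed and the error names the failing stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with `clusters`, `summary`, `breakdowns`,
#'   `expression`, `cage` (or `NULL`) and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  fails <- validate_inputs(config)
  if (length(fails))
    stop("input validation failed:\n  ", paste(fails, collapse = "\n  "))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- function(name) {
    p <- file.path(config$outdir, name)
    written <<- c(written, p)
    p
  }

  ann <- stage("genome", suppressMessages(read_gff_genes(config$genome)))
  libraries <- stage("libraries",
                     load_libraries(config$manifest,
                                    seqlengths = ann$seqlengths))
  clusters <- stage("calling",
                    call_tss(libraries, config$min_tags,
                             config$min_libraries, config$max_gap))
  features <- stage("features", build_feature_set(ann))
  clusters <- stage("annotation", annotate_clusters(clusters, features))
  clusters <- stage("classification",
                    classify_clusters(clusters, config$wild_type,
                                      config$mutants))
  counts <- stage("quantification", cluster_counts(clusters, libraries))
  totals <- vapply(libraries, library_total, numeric(1))
  expr <- stage("quantification",
                cpm_log2(counts, totals, config$pseudocount))

  summary <- summarize_categories(clusters)
  breakdowns <- lapply(
    setNames(nm = c("all", "basal", "fact_specific")),
    function(w) tryCatch(annotation_breakdown(clusters, w),
                         error = function(e) NULL))
  cage <- NULL
  if (!is.null(config$cage)) {
    summits <- stage("cage", read_bed_points(config$cage))
    cage <- cage_overlap_fraction(clusters, summits)
  }

  export_clusters(clusters, out("clusters.tsv"))
  rownames(expr) <- paste0("cluster_", seq_len(nrow(expr)))
  write.table(data.frame(cluster = rownames(expr), expr,
                         check.names = FALSE),
              out("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  to_list <- function(s) if (is.null(s)) NULL else
    list(counts = as.list(s$counts), percentages = as.list(s$percentages),
         total = s$total, fold_ratios = as.list(s$fold_ratios))
  jsonlite::write_json(
    list(categories = to_list(summary),
         annotation_breakdowns = lapply(breakdowns, to_list),
         cage_overlap = cage),
    out("summary.json"), auto_unbox = TRUE, digits = NA, na = "null")

  inputs <- c(config$manifest, config$genome, config$cage, config$tracks)
  jsonlite::write_json(
    list(parameters = unclass(config)[c("wild_type", "mutants", "min_tags",
                               "min_libraries", "max_gap", "pseudocount",
                               "seed")],
         inputs = as.list(setNames(unname(md5sum(inputs)), inputs))),
    out("run_manifest.json"), auto_unbox = TRUE)

  ok <- TRUE
  invisible(list(clusters = clusters, summary = summary,
                 breakdowns = breakdowns, expression = expr, cage = cage,
                 counts = counts, libraries = libraries, annotation = ann,
                 paths = written))
}
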