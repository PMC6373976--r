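# Synthetic TSS-seq generator.
#
# Emulates a 2-replicate x 3-genotype 5'-tag experiment on a compact genome:
# every gene carries a promoter TSS active in all genotypes; a fraction of
# genes additionally carries an intragenic TSS active only in the mutant
# genotypes, at a lower mean tag count; background noise consists of
# sub-threshold singleton tags. Matching signal tracks plant elongation-mark
# enrichment at the intragenic sites. All randomness flows from one master
# seed through per-stage sub-seeds (see derive_seed()), so each stage is
# reproducible on its own.

#' Simulation configuration
#'
#' Defaults are the study conditions the test suite and acceptance runs use:
#' 200 genes, 2 replicates of 3 genotypes, negative-binomial tag counts with
#' promoter mean 50 and intragenic mean 10 (dispersion 10), an intragenic TSS
#' in 30% of genes, and strictly sub-threshold singleton noise.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bases.
#' @param n_genes Total genes (packed across chromosomes; error if they do
#'   not fit).
#' @param exon_count_range,exon_length_range,intron_length_range,gap_range
#'   Integer ranges (length-2 vectors) for gene structure and intergenic
#'   gaps.
#' @param genotypes Character vector of genotype labels (first = wild type).
#' @param mutants Character vector naming the mutant genotypes.
#' @param n_replicates Replicates per genotype.
#' @param mu_promoter,mu_fact Negative-binomial mean tag count per library at
#'   promoter and intragenic planted TSSs (`mu_fact < mu_promoter`:
#'   mutant-induced transcripts are less expressed).
#' @param dispersion Negative-binomial size parameter.
#' @param fact_fraction Fraction of genes given an intragenic mutant-only
#'   TSS.
#' @param intron_fact_fraction Fraction of those planted intragenically that
#'   go to an intron instead of an exon (0 = exonic only).
#' @param noise_rate Background singleton positions per kilobase per strand.
#' @param jitter_p,jitter_max Geometric jitter of tag positions around a
#'   planted site (success probability and cap in bases).
#' @param signal_baseline,signal_amplitude,signal_sigma,signal_noise_sd
#'   Signal-track parameters: baseline, planted Gaussian bump amplitude and
#'   width, additive noise sd.
#' @param confusable_noise If `TRUE`, noise positions get supra-threshold
#'   counts instead of singletons (stress mode; off by default).
#' @param seed Master seed (mandatory).
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_chrom = 2L, chrom_length = 200000L,
                              n_genes = 200L,
                              exon_count_range = c(2L, 4L),
                              exon_length_range = c(150L, 400L),
                              intron_length_range = c(60L, 150L),
                              gap_range = c(600L, 1200L),
                              genotypes = c("wild_type", "spt16", "ssrp1"),
                              mutants = c("spt16", "ssrp1"),
                              n_replicates = 2L,
                              mu_promoter = 50, mu_fact = 10,
                              dispersion = 10,
                              fact_fraction = 0.3,
                              intron_fact_fraction = 0,
                              noise_rate = 0.3,
                              jitter_p = 0.7, jitter_max = 5L,
                              signal_baseline = 1.0,
                              signal_amplitude = 1.0,
                              signal_sigma = 75,
                              signal_noise_sd = 0.25,
                              confusable_noise = FALSE,
                              seed = 42L) {
  stopifnot(mu_fact < mu_promoter, noise_rate >= 0, fact_fraction >= 0,
            fact_fraction <= 1, !is.null(seed))
  cfg <- as.list(environment())
  structure(cfg, class = "SimulationConfig")
}

#' Generate a synthetic genome annotation
#'
#' Packs non-overlapping genes with alternating strands along the configured
#' chromosomes, drawing exon/intron structure and intergenic gaps uniformly
#' from the configured ranges. A 600-base margin is kept at chromosome starts
#' so upstream feature windows stay on-chromosome.
#'
#' @param config A [simulation_config()].
#' @return A `GeneAnnotation`.
#' @export
generate_genome <- function(config) {
  with_seed(derive_seed(config$seed, 1L), {
    seqlens <- setNames(rep(config$chrom_length, config$n_chrom),
                        paste0("chr", seq_len(config$n_chrom)))
    if (config$n_genes == 0) {
      empty <- GRanges(seqlengths = seqlens)
      empty$gene_id <- character(0)
      empty$gene_name <- character(0)
      return(gene_annotation(empty, GRangesList(), seqlengths = seqlens))
    }
    runif_int <- function(r) sample(seq(r[1], r[2]), 1L)
    chrom <- 1L
    cursor <- 600L  # margin for upstream windows
    rows <- vector("list", config$n_genes)
    for (i in seq_len(config$n_genes)) {
      n_ex <- runif_int(config$exon_count_range)
      ex_len <- vapply(seq_len(n_ex), function(...)
        runif_int(config$exon_length_range), integer(1))
      in_len <- if (n_ex > 1) vapply(seq_len(n_ex - 1L), function(...)
        runif_int(config$intron_length_range), integer(1)) else integer(0)
      glen <- sum(ex_len) + sum(in_len)
      gap <- runif_int(config$gap_range)
      if (cursor + glen + 600L > config$chrom_length) {
        chrom <- chrom + 1L
        cursor <- 600L
        if (chrom > config$n_chrom)
          stop("infeasible packing: genes exceed chromosome space")
      }
      gstart <- cursor
      ex_start <- gstart + cumsum(c(0L, head(ex_len, -1) + in_len))
      rows[[i]] <- list(
        chrom = names(seqlens)[chrom],
        start = gstart, end = gstart + glen - 1L,
        strand = if (i %% 2 == 0) "-" else "+",
        ex_start = ex_start, ex_end = ex_start + ex_len - 1L
      )
      cursor <- gstart + glen + gap
    }
    ids <- sprintf("GENE%04d", seq_len(config$n_genes))
    genes <- GRanges(
      vapply(rows, `[[`, character(1), "chrom"),
      IRanges(vapply(rows, `[[`, numeric(1), "start"),
              vapply(rows, `[[`, numeric(1), "end")),
      strand = vapply(rows, `[[`, character(1), "strand"),
      seqlengths = seqlens
    )
    genes$gene_id <- ids
    genes$gene_name <- sprintf("gene%04d", seq_len(config$n_genes))
    exons <- GRangesList(lapply(seq_along(rows), function(i) {
      GRanges(rows[[i]]$chrom,
              IRanges(rows[[i]]$ex_start, rows[[i]]$ex_end),
              strand = rows[[i]]$strand, seqlengths = seqlens)
    }))
    names(exons) <- ids
    gene_annotation(genes, exons, seqlengths = seqlens)
  })
}

#' Plant ground-truth TSS positions
#'
#' One promoter TSS at every gene's 5' end (active in all genotypes); for a
#' `fact_fraction` of genes, one intragenic TSS at a uniformly random exonic
#' (or, with `intron_fact_fraction`, intronic) base at least
#' `max_gap + jitter_max + 1` bases from the promoter (active in mutants
#' only); plus Poisson background noise positions genome-wide.
#'
#' @param annotation A `GeneAnnotation` from [generate_genome()].
#' @param config The same [simulation_config()].
#' @param max_gap Cluster merge gap the caller will use; planted sites keep
#'   clear of the promoter by more than this (default 20).
#' @return A `PlantedTruth` data frame with columns `chrom`, `position`
#'   (1-based), `strand`, `kind`, `gene_id`, `expected_category`, and
#'   `active` (list of genotype vectors).
#' @export
plant_tss <- function(annotation, config, max_gap = 20L) {
  with_seed(derive_seed(config$seed, 2L), {
    genes <- annotation$genes
    g5 <- five_prime_end(genes)
    rows <- if (length(genes) == 0) {
      data.frame(chrom = character(0), position = integer(0),
                 strand = character(0), kind = character(0),
                 gene_id = character(0), expected_category = character(0),
                 active = I(list()), stringsAsFactors = FALSE)
    } else data.frame(
      chrom = as.character(seqnames(genes)),
      position = g5,
      strand = as.character(strand(genes)),
      kind = "promoter",
      gene_id = genes$gene_id,
      expected_category = "basal",
      stringsAsFactors = FALSE
    )
    rows$active <- I(rep(list(config$genotypes), nrow(rows)))

    n_fact <- round(config$fact_fraction * length(genes))
    if (n_fact > 0) {
      pick <- sort(sample.int(length(genes), n_fact))
      keep_away <- max_gap + config$jitter_max + 1L
      fact <- lapply(pick, function(i) {
        use_intron <- runif(1) < config$intron_fact_fraction
        pool_gr <- if (use_intron)
          derive_introns(annotation)[[genes$gene_id[i]]]
        else annotation$exons[[genes$gene_id[i]]]
        if (is.null(pool_gr) || length(pool_gr) == 0 || use_intron &&
            sum(width(pool_gr)) == 0) {
          pool_gr <- annotation$exons[[genes$gene_id[i]]]
          use_intron <- FALSE
        }
        bases <- unlist(mapply(seq.int, start(pool_gr), end(pool_gr),
                               SIMPLIFY = FALSE))
        bases <- bases[abs(bases - g5[i]) > keep_away]
        if (!length(bases)) return(NULL)
        data.frame(
          chrom = as.character(seqnames(genes)[i]),
          position = bases[sample.int(length(bases), 1L)],
          strand = as.character(strand(genes)[i]),
          kind = if (use_intron) "fact_specific_intronic"
                 else "fact_specific_exonic",
          gene_id = genes$gene_id[i],
          expected_category = "fact_specific",
          stringsAsFactors = FALSE
        )
      })
      fact <- do.call(rbind, fact[!vapply(fact, is.null, logical(1))])
      if (!is.null(fact) && nrow(fact)) {
        fact$active <- I(rep(list(config$mutants), nrow(fact)))
        rows <- rbind(rows, fact)
      }
    }

    # background noise: Poisson(noise_rate per kb) positions per strand
    seqlens <- annotation$seqlengths
    noise <- lapply(names(seqlens), function(ch) {
      out <- lapply(c("+", "-"), function(s) {
        n <- rpois(1, config$noise_rate * seqlens[[ch]] / 1000)
        if (n == 0) return(NULL)
        data.frame(chrom = ch,
                   position = sample.int(seqlens[[ch]], n, replace = TRUE),
                   strand = s, kind = "noise", gene_id = NA_character_,
                   expected_category = NA_character_,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, out[!vapply(out, is.null, logical(1))])
    })
    noise <- do.call(rbind, noise[!vapply(noise, is.null, logical(1))])
    if (!is.null(noise) && nrow(noise)) {
      noise$active <- I(rep(list(character(0)), nrow(noise)))
      rows <- rbind(rows, noise)
    }
    rownames(rows) <- NULL
    class(rows) <- c("PlantedTruth", class(rows))
    rows
  })
}

# Scatter n tags around a center with capped geometric jitter; returns a
# table of positions (clipped to [1, chrom_length]).
jitter_tags <- function(n, center, config, chrom_length) {
  if (n == 0) return(integer(0))
  mag <- pmin(rgeom(n, config$jitter_p), config$jitter_max)
  sgn <- sample(c(-1L, 1L), n, replace = TRUE)
  pmin(pmax(center + sgn * mag, 1L), chrom_length)
}

#' Emit tag libraries from planted truth
#'
#' For every library, each truth position active in the library's genotype
#' receives a negative-binomial tag count (mean `mu_promoter` or `mu_fact`,
#' dispersion `dispersion`) scattered with capped geometric positional
#' jitter; noise positions get exactly one tag in one random library
#' (sub-threshold by construction, unless `confusable_noise` is set, in
#' which case they get `mu_fact`-mean counts in all libraries).
#'
#' @param truth A `PlantedTruth` from [plant_tss()].
#' @param config The same [simulation_config()].
#' @param seqlengths Named chromosome lengths (from the annotation).
#' @return List of [tag_library()] objects.
#' @export
emit_libraries <- function(truth, config, seqlengths) {
  with_seed(derive_seed(config$seed, 3L), {
    libs <- expand.grid(replicate = seq_len(config$n_replicates),
                        genotype = config$genotypes,
                        stringsAsFactors = FALSE)
    libs$library_id <- paste0(libs$genotype, "_r", libs$replicate)
    n_lib <- nrow(libs)
    # accumulate tag positions per (library, strand, chrom); tabulate once
    # at the end so cost scales with tags, not genome size
    acc <- new.env(parent = emptyenv())
    deposit <- function(lib, strand, chrom, positions) {
      if (!length(positions)) return()
      key <- paste(lib, strand, chrom, sep = "\r")
      acc[[key]] <- c(acc[[key]], positions)
    }

    planted <- truth[truth$kind != "noise", , drop = FALSE]
    for (r in seq_len(nrow(planted))) {
      mu <- if (planted$kind[r] == "promoter") config$mu_promoter
            else config$mu_fact
      for (j in seq_len(n_lib)) {
        if (!(libs$genotype[j] %in% planted$active[[r]])) next
        n <- rnbinom(1, size = config$dispersion, mu = mu)
        pos <- jitter_tags(n, planted$position[r], config,
                           seqlengths[[planted$chrom[r]]])
        deposit(j, planted$strand[r], planted$chrom[r], pos)
      }
    }
    noise <- truth[truth$kind == "noise", , drop = FALSE]
    for (r in seq_len(nrow(noise))) {
      if (config$confusable_noise) {
        for (j in seq_len(n_lib)) {
          n <- rnbinom(1, size = config$dispersion, mu = config$mu_fact)
          pos <- jitter_tags(n, noise$position[r], config,
                             seqlengths[[noise$chrom[r]]])
          deposit(j, noise$strand[r], noise$chrom[r], pos)
        }
      } else {
        j <- sample.int(n_lib, 1L)
        deposit(j, noise$strand[r], noise$chrom[r], noise$position[r])
      }
    }

    lapply(seq_len(n_lib), function(j) {
      to_rle <- function(s) {
        as(setNames(lapply(names(seqlengths), function(ch) {
          pos <- acc[[paste(j, s, ch, sep = "\r")]]
          if (is.null(pos)) Rle(0L, seqlengths[[ch]])
          else Rle(tabulate(pos, nbins = seqlengths[[ch]]))
        }), names(seqlengths)), "RleList")
      }
      tag_library(libs$library_id[j], libs$genotype[j], libs$replicate[j],
                  to_rle("+"), to_rle("-"))
    })
  })
}

#' Emit signal tracks with planted enrichment
#'
#' Three unstranded tracks mirroring the chromatin assays the boxplot and
#' metagene machinery consumes: an elongation-mark style track (baseline
#' plus Gaussian bumps of amplitude `signal_amplitude` and width
#' `signal_sigma` at the intragenic planted TSSs), a promoter-mark style
#' track (bumps at promoter TSSs), and a nucleosome-style track (elevated
#' over gene bodies). All tracks carry additive Gaussian noise, truncated at
#' zero.
#'
#' @param truth A `PlantedTruth`.
#' @param config The same [simulation_config()].
#' @param annotation The `GeneAnnotation` (for gene bodies and chromosome
#'   lengths).
#' @return Named list of numeric `RleList` tracks: `h3k4me1_like`,
#'   `h3k4me3_like`, `mnase_like`.
#' @export
emit_signal_tracks <- function(truth, config, annotation) {
  with_seed(derive_seed(config$seed, 4L), {
    seqlens <- annotation$seqlengths
    bump <- function(vec, center, amp, sigma) {
      w <- ceiling(4 * sigma)
      s <- max(1L, center - w); e <- min(length(vec), center + w)
      x <- s:e
      vec[x] <- vec[x] + amp * exp(-(x - center)^2 / (2 * sigma^2))
      vec
    }
    base_track <- function() lapply(seqlens, function(L)
      rep(config$signal_baseline, L))
    add_noise <- function(tr) lapply(tr, function(v)
      pmax(v + rnorm(length(v), sd = config$signal_noise_sd), 0))

    fact <- truth[startsWith(truth$kind, "fact_specific"), , drop = FALSE]
    prom <- truth[truth$kind == "promoter", , drop = FALSE]

    k4me1 <- base_track()
    for (r in seq_len(nrow(fact)))
      k4me1[[fact$chrom[r]]] <- bump(k4me1[[fact$chrom[r]]],
                                     fact$position[r],
                                     config$signal_amplitude,
                                     config$signal_sigma)
    k4me3 <- base_track()
    for (r in seq_len(nrow(prom)))
      k4me3[[prom$chrom[r]]] <- bump(k4me3[[prom$chrom[r]]],
                                     prom$position[r],
                                     config$signal_amplitude,
                                     config$signal_sigma)
    mnase <- base_track()
    genes <- annotation$genes
    for (i in seq_along(genes)) {
      ch <- as.character(seqnames(genes)[i])
      idx <- start(genes)[i]:end(genes)[i]
      mnase[[ch]][idx] <- mnase[[ch]][idx] + config$signal_amplitude / 2
    }

    lapply(list(h3k4me1_like = k4me1, h3k4me3_like = k4me3,
                mnase_like = mnase),
           function(tr) as(lapply(add_noise(tr), Rle), "RleList"))
  })
}

#' Run the whole generator
#'
#' @param config A [simulation_config()].
#' @param tracks If `FALSE`, skip signal-track emission.
#' @return List with `annotation`, `truth`, `libraries`, `tracks`, `config`.
#' @export
generate_simulation <- function(config = simulation_config(),
                                tracks = TRUE) {
  annotation <- generate_genome(config)
  truth <- plant_tss(annotation, config)
  libraries <- emit_libraries(truth, config, annotation$seqlengths)
  list(annotation = annotation, truth = truth, libraries = libraries,
       tracks = if (tracks) emit_signal_tracks(truth, config, annotation),
       config = config)
}

#' Write a simulation to disk in pipeline-ready formats
#'
#' Emits the exact formats the pipeline consumes: a manifest TSV plus one
#' bedGraph pair per library, the genome as GFF3, the planted truth as BED6
#' (score encodes nothing; name = kind), and one bedGraph per signal track.
#'
#' @param sim Output of [generate_simulation()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(
    library_id = vapply(sim$libraries, `[[`, character(1), "library_id"),
    genotype = vapply(sim$libraries, `[[`, character(1), "genotype"),
    replicate = vapply(sim$libraries, `[[`, integer(1), "replicate"),
    stringsAsFactors = FALSE
  )
  manifest$plus_path <- paste0(manifest$library_id, "_plus.bedgraph")
  manifest$minus_path <- paste0(manifest$library_id, "_minus.bedgraph")
  for (i in seq_along(sim$libraries)) {
    write_bedgraph(sim$libraries[[i]]$counts[["+"]],
                   file.path(dir, manifest$plus_path[i]))
    write_bedgraph(sim$libraries[[i]]$counts[["-"]],
                   file.path(dir, manifest$minus_path[i]))
  }
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gff_genes(sim$annotation, file.path(dir, "genes.gff3"))
  truth_gr <- GRanges(sim$truth$chrom,
                      IRanges(sim$truth$position, width = 1L),
                      strand = sim$truth$strand,
                      name = sim$truth$kind)
  rtracklayer::export(truth_gr, file.path(dir, "truth.bed"), format = "BED")
  if (!is.null(sim$tracks)) {
    for (nm in names(sim$tracks))
      write_bedgraph(sim$tracks[[nm]],
                     file.path(dir, paste0(nm, ".bedgraph")))
  }
  invisible(manifest_path)
}

#' Score recovery of planted TSSs by called clusters
#'
#' A planted (non-noise) record is recovered when a called cluster on the
#' same strand lies within `max_dist` bases of its position and, if the
#' clusters are classified, carries the record's expected category.
#' Precision per kind is the fraction of clusters of the matching category
#' that lie near a planted record of that kind. Clusters near no planted
#' record at all are counted as noise-derived.
#'
#' @param clusters Called (optionally classified) cluster `GRanges`.
#' @param truth A `PlantedTruth`.
#' @param max_dist Maximum distance in bases (default 20).
#' @param candidates Optional `CandidateSet`; when given, each planted
#'   record additionally gets a `supra_threshold` flag (a candidate position
#'   of an active genotype lies within `max_dist`) and recall is also
#'   reported restricted to supra-threshold records.
#' @return List with `per_kind` (data frame: kind, n, n_recovered, recall,
#'   precision), `category_agreement` (fraction of recovered records whose
#'   matched cluster category equals the expected one; `NA` if unclassified),
#'   `n_noise_clusters`, and optionally `recall_supra` per kind.
#' @export
score_recovery <- function(clusters, truth, max_dist = 20L,
                           candidates = NULL) {
  planted <- truth[truth$kind != "noise", , drop = FALSE]
  truth_gr <- GRanges(planted$chrom, IRanges(planted$position, width = 1L),
                      strand = planted$strand)
  classified <- length(clusters) > 0 && !all(is.na(clusters$category))

  near <- findOverlaps(truth_gr, clusters, maxgap = max_dist)
  cat_ok <- if (classified)
    planted$expected_category[queryHits(near)] ==
      clusters$category[subjectHits(near)]
  else rep(TRUE, length(near))
  recovered <- rep(FALSE, nrow(planted))
  recovered[unique(queryHits(near)[cat_ok])] <- TRUE
  match_cat <- rep(NA, nrow(planted))
  match_cat[queryHits(near)] <- FALSE
  match_cat[queryHits(near)[cat_ok]] <- TRUE

  # clusters near any planted record / near one of matching kind
  cluster_kind <- rep(NA_character_, length(clusters))
  cluster_kind[subjectHits(near)[cat_ok]] <-
    planted$kind[queryHits(near)[cat_ok]]
  n_noise_clusters <- length(clusters) -
    length(unique(subjectHits(findOverlaps(
      GRanges(truth$chrom, IRanges(truth$position, width = 1L),
              strand = truth$strand), clusters, maxgap = max_dist))))

  supra <- NULL
  if (!is.null(candidates)) {
    supra <- vapply(seq_len(nrow(planted)), function(r) {
      any(vapply(planted$active[[r]], function(g) {
        cand <- candidates$positions[[g]]
        if (is.null(cand) || !length(cand)) return(FALSE)
        length(findOverlaps(truth_gr[r], cand, maxgap = max_dist)) > 0
      }, logical(1)))
    }, logical(1))
  }

  kinds <- unique(planted$kind)
  per_kind <- do.call(rbind, lapply(kinds, function(k) {
    sel <- planted$kind == k
    expected_cat <- planted$expected_category[sel][1]
    n_clust <- if (classified)
      sum(!is.na(clusters$category) & clusters$category == expected_cat)
    else length(clusters)
    data.frame(
      kind = k, n = sum(sel), n_recovered = sum(recovered[sel]),
      recall = if (any(sel)) mean(recovered[sel]) else NA_real_,
      precision = if (n_clust > 0)
        sum(cluster_kind == k, na.rm = TRUE) / n_clust else NA_real_,
      recall_supra = if (!is.null(supra) && any(sel & supra))
        mean(recovered[sel & supra]) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  agreement <- if (classified) {
    considered <- !is.na(match_cat)
    if (any(considered)) mean(match_cat[considered]) else NA_real_
  } else NA_real_
  list(per_kind = per_kind, category_agreement = agreement,
       n_noise_clusters = n_noise_clusters)
}
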