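# The synthetic generator: determinism, planting rules, emission statistics
# and ground-truth bookkeeping.

small_config <- function(...) {
  args <- list(n_genes = 30L, n_chrom = 1L, chrom_length = 80000L)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

test_that("the generator is deterministic per seed, and seeds split per stage", {
  a <- generate_simulation(small_config(seed = 7), tracks = FALSE)
  b <- generate_simulation(small_config(seed = 7), tracks = FALSE)
  expect_identical(a$truth, b$truth)
  expect_identical(granges(a$annotation$genes), granges(b$annotation$genes))
  for (i in seq_along(a$libraries))
    expect_identical(a$libraries[[i]]$counts, b$libraries[[i]]$counts)
  # a different seed changes the genome
  c <- generate_simulation(small_config(seed = 8), tracks = FALSE)
  expect_false(identical(granges(a$annotation$genes),
                         granges(c$annotation$genes)))
  # stages regenerate independently from the config
  expect_identical(plant_tss(a$annotation, small_config(seed = 7)), a$truth)
})

test_that("written simulations are byte-identical across runs", {
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(generate_simulation(small_config(seed = 3),
                                       tracks = FALSE), d1)
  write_simulation(generate_simulation(small_config(seed = 3),
                                       tracks = FALSE), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("generated genomes satisfy the gene-model invariants", {
  ann <- generate_genome(simulation_config(n_genes = 100, n_chrom = 2,
                                           chrom_length = 150000, seed = 2))
  genes <- ann$genes
  expect_length(genes, 100)
  # non-overlapping genes per chromosome
  expect_true(isDisjoint(granges(genes), ignore.strand = TRUE))
  # alternating strands
  expect_equal(length(unique(as.character(strand(genes)))), 2)
  for (id in genes$gene_id) {
    ex <- ann$exons[[id]]
    span <- genes[genes$gene_id == id]
    expect_true(all(start(ex) >= start(span)), label = id)
    expect_true(all(end(ex) <= end(span)), label = id)
    expect_true(isDisjoint(ex))
    expect_false(is.unsorted(start(ex)))
  }
  expect_error(generate_genome(simulation_config(n_genes = 1000, n_chrom = 1,
                                                 chrom_length = 50000)),
               "infeasible packing")
  empty <- generate_genome(simulation_config(n_genes = 0))
  expect_length(empty$genes, 0)
})

test_that("planting: fraction 0 and 1 behave as stated; sites avoid the promoter", {
  cfg0 <- small_config(fact_fraction = 0, seed = 11)
  t0 <- plant_tss(generate_genome(cfg0), cfg0)
  expect_true(all(t0$kind %in% c("promoter", "noise")))

  cfg1 <- small_config(fact_fraction = 1, seed = 12)
  ann1 <- generate_genome(cfg1)
  t1 <- plant_tss(ann1, cfg1)
  fact <- t1[t1$kind == "fact_specific_exonic", ]
  expect_equal(sort(fact$gene_id), sort(ann1$genes$gene_id))
  # every intragenic site is inside its gene body and > max_gap + jitter
  # from the promoter TSS
  g5 <- setNames(five_prime_end(ann1$genes), ann1$genes$gene_id)
  expect_true(all(abs(fact$position - g5[fact$gene_id]) > 25))
  for (r in seq_len(nrow(fact))) {
    g <- ann1$genes[ann1$genes$gene_id == fact$gene_id[r]]
    expect_true(fact$position[r] >= start(g) && fact$position[r] <= end(g))
  }
  # promoter records active everywhere, intragenic only in mutants
  expect_true(all(vapply(t1$active[t1$kind == "promoter"], function(a)
    setequal(a, c("wild_type", "spt16", "ssrp1")), logical(1))))
  expect_true(all(vapply(fact$active, function(a)
    setequal(a, c("spt16", "ssrp1")), logical(1))))
})

test_that("mutant-only sites emit no wild-type tags; singleton noise stays singleton", {
  cfg <- small_config(fact_fraction = 1, noise_rate = 0.5, seed = 13)
  sim <- generate_simulation(cfg, tracks = FALSE)
  fact <- sim$truth[sim$truth$kind == "fact_specific_exonic", ]
  wt <- Filter(function(l) l$genotype == "wild_type", sim$libraries)
  for (r in seq_len(nrow(fact))) {
    for (l in wt) {
      v <- l$counts[[fact$strand[r]]][[fact$chrom[r]]]
      win <- as.numeric(v[max(1, fact$position[r] - 6):(fact$position[r] + 6)])
      expect_equal(sum(win), 0)
    }
  }
  # noise positions carry exactly one tag across all libraries
  noise <- sim$truth[sim$truth$kind == "noise", ]
  for (r in seq_len(min(nrow(noise), 50))) {
    tot <- sum(vapply(sim$libraries, function(l)
      as.numeric(l$counts[[noise$strand[r]]][[noise$chrom[r]]][noise$position[r]]),
      numeric(1)))
    expect_equal(tot, 1)
  }
})

test_that("emitted per-library counts have the configured negative-binomial mean", {
  cfg <- simulation_config(n_genes = 250, n_chrom = 2, chrom_length = 250000,
                           fact_fraction = 1, noise_rate = 0, seed = 14)
  sim <- generate_simulation(cfg, tracks = FALSE)
  planted <- sim$truth[sim$truth$kind == "promoter", ]
  expect_gte(nrow(planted), 250)
  # per planted site and library, total tags within the jitter window
  lib <- sim$libraries[[1]]
  site_totals <- vapply(seq_len(nrow(planted)), function(r) {
    v <- lib$counts[[planted$strand[r]]][[planted$chrom[r]]]
    lo <- max(1, planted$position[r] - 5)
    hi <- min(length(v), planted$position[r] + 5)
    sum(as.numeric(v[lo:hi]))
  }, numeric(1))
  expect_lt(abs(mean(site_totals) - cfg$mu_promoter), 0.1 * cfg$mu_promoter)
  # intragenic sites have the lower mean
  fact <- sim$truth[sim$truth$kind == "fact_specific_exonic", ]
  mut_lib <- Filter(function(l) l$genotype == "spt16", sim$libraries)[[1]]
  fact_totals <- vapply(seq_len(nrow(fact)), function(r) {
    v <- mut_lib$counts[[fact$strand[r]]][[fact$chrom[r]]]
    lo <- max(1, fact$position[r] - 5)
    hi <- min(length(v), fact$position[r] + 5)
    sum(as.numeric(v[lo:hi]))
  }, numeric(1))
  expect_lt(abs(mean(fact_totals) - cfg$mu_fact), 0.1 * cfg$mu_fact)
})

test_that("noise-only genomes yield no clusters", {
  cfg <- small_config(n_genes = 0, noise_rate = 2, seed = 15)
  sim <- generate_simulation(cfg, tracks = FALSE)
  expect_true(all(sim$truth$kind == "noise"))
  expect_length(call_tss(sim$libraries), 0)
})

test_that("planted signal tracks carry the planted amplitude and only there", {
  cfg <- small_config(fact_fraction = 1, signal_noise_sd = 0.05, seed = 16)
  sim <- generate_simulation(cfg)
  fact <- sim$truth[sim$truth$kind == "fact_specific_exonic", ]
  at_fact <- vapply(seq_len(nrow(fact)), function(r)
    as.numeric(sim$tracks$h3k4me1_like[[fact$chrom[r]]][fact$position[r]]),
    numeric(1))
  expect_lt(abs(mean(at_fact) - (cfg$signal_baseline + cfg$signal_amplitude)),
            0.1)
  # promoter-mark track has no bump at intragenic sites (baseline only,
  # except where a promoter bump of a nearby gene bleeds over)
  prom <- sim$truth[sim$truth$kind == "promoter", ]
  far <- fact[vapply(seq_len(nrow(fact)), function(r)
    all(abs(prom$position[prom$chrom == fact$chrom[r]] - fact$position[r]) >
          4 * cfg$signal_sigma), logical(1)), ]
  at_far <- vapply(seq_len(nrow(far)), function(r)
    as.numeric(sim$tracks$h3k4me3_like[[far$chrom[r]]][far$position[r]]),
    numeric(1))
  expect_lt(abs(mean(at_far) - cfg$signal_baseline), 0.1)
  # amplitude 0 -> flat baseline + noise
  flat_cfg <- small_config(signal_amplitude = 0, signal_noise_sd = 0.05,
                           seed = 17)
  flat <- generate_simulation(flat_cfg)
  v <- as.numeric(flat$tracks$h3k4me1_like$chr1)
  expect_lt(abs(mean(v) - flat_cfg$signal_baseline), 0.05)
})

test_that("classification reproduces every expected category on noiseless data", {
  cfg <- small_config(noise_rate = 0, seed = 18)
  sim <- generate_simulation(cfg, tracks = FALSE)
  cl <- classify_clusters(call_tss(sim$libraries))
  rec <- score_recovery(cl, sim$truth)
  expect_equal(rec$category_agreement, 1)
  expect_equal(rec$n_noise_clusters, 0)
  expect_true(all(rec$per_kind$recall == 1))
})

test_that("library totals scale roughly linearly with gene count", {
  tot_at <- function(n) {
    cfg <- simulation_config(n_genes = n, n_chrom = 2,
                             chrom_length = 250000, noise_rate = 0,
                             seed = 19)
    sim <- generate_simulation(cfg, tracks = FALSE)
    mean(vapply(sim$libraries, library_total, numeric(1)))
  }
  t200 <- tot_at(200)
  t100 <- tot_at(100)
  expect_lt(abs(t200 / t100 - 2), 0.2)
})
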