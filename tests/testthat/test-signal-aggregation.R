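# Signal aggregation: windowed medians, metagene profiles, control-position
# sampling, Wilcoxon contrasts, boxplot statistics and read resizing. Naive
# per-base oracles re-derive each summary from the raw vector.

anchor <- function(pos, strand = "+", chrom = "chr1") {
  GRanges(chrom, IRanges(pos, width = 1), strand = strand)
}

test_that("window median matches stated examples", {
  expect_equal(window_median(rle_track(rep(3, 100)), anchor(50)), 3)
  # 10 bases of 0 then 10 bases of 4 inside the window -> even-n median 2
  v <- numeric(100); v[51:60] <- 4
  expect_equal(window_median(rle_track(v), anchor(51)), 2)
})

test_that("window median equals naive sort-and-middle on random tracks", {
  set.seed(81)
  v <- rnorm(10000)^2
  tr <- rle_track(v)
  pos <- sample(50:9950, 100)
  got <- window_median(tr, anchor(pos))
  for (i in seq_along(pos)) {
    w <- v[(pos[i] - 10):(pos[i] + 9)]  # 0-based [p-10, p+10)
    expect_equal(got[i], median(w), tolerance = 1e-9)
  }
  # clipping at the chromosome edge uses only in-bounds bases
  expect_equal(window_median(tr, anchor(3)), median(v[1:12]))
})

test_that("metagene profiles mirror on the minus strand", {
  # asymmetric ramp
  v <- c(numeric(400), seq_len(200), numeric(400))
  tr <- rle_track(v)
  plus <- metagene(tr, anchor(c(500, 500)), width = 400)
  minus <- metagene(tr, anchor(c(500, 500), strand = "-"), width = 400)
  # value at offset o (plus) equals value at offset -o (minus)
  for (o in c(-150, -50, 0, 50, 150)) {
    expect_equal(plus$mean[plus$offset == o],
                 minus$mean[minus$offset == -o], tolerance = 1e-12)
  }
  # identical anchors -> zero-width confidence band
  expect_equal(plus$ci_low, plus$mean, tolerance = 1e-12)
  expect_equal(plus$ci_high, plus$mean, tolerance = 1e-12)
  expect_error(metagene(tr, anchor(500)), "at least 2 anchors")
})

test_that("metagene equals the naive per-offset mean and nails a planted bump", {
  set.seed(82)
  v <- rnorm(20000, sd = 0.1) + 1
  centers <- sample(seq(500, 19500, by = 700), 27)  # spaced: bumps do not overlap
  for (p in centers) {
    idx <- (p - 300):(p + 300)
    v[idx] <- v[idx] + 2 * exp(-((idx - p)^2) / (2 * 50^2))
  }
  tr <- rle_track(v)
  anc <- anchor(centers)
  mg <- metagene(tr, anc, width = 400)
  # naive oracle
  mat <- t(vapply(centers, function(p) v[(p - 200):(p + 199)], numeric(400)))
  expect_equal(mg$mean, colMeans(mat), tolerance = 1e-9)
  se <- apply(mat, 2, sd) / sqrt(length(centers))
  expect_equal(mg$ci_high - mg$mean, 1.96 * se, tolerance = 1e-9)
  # peak near offset 0 (the bump is nearly flat over +/- 5 bases, so noise
  # can move the argmax a few bases), amplitude close to baseline + planted
  expect_lte(abs(mg$offset[which.max(mg$mean)]), 10)
  at0 <- mg[mg$offset == 0, ]
  expect_lt(abs(at0$mean - 3), 0.1)
})

test_that("strand-balanced metagene over symmetric signal is symmetric", {
  set.seed(83)
  v <- rnorm(4000)^2
  tr <- rle_track(v)
  pos <- sample(500:3500, 40)
  anc <- c(anchor(pos, "+"), anchor(pos, "-"))
  mg <- metagene(tr, anc, width = 400)
  m <- setNames(mg$mean, mg$offset)
  for (o in c(1, 7, 50, 150, 199)) {
    expect_equal(unname(m[as.character(o)]), unname(m[as.character(-o)]),
                 tolerance = 1e-9)
  }
})

test_that("control sampling is seeded, uniform, and respects the end filter", {
  ann <- make_annotation(list(
    big = list(start0 = 1000, end0 = 3000,
               exons = list(c(1000, 1800), c(2200, 3000))),
    small = list(start0 = 5000, end0 = 5150),   # 150 bases < 200 filter
    minus = list(start0 = 8000, end0 = 9000, strand = "-")
  ))
  a1 <- sample_control_positions(ann, seed = 9, n_per_gene = 3)
  a2 <- sample_control_positions(ann, seed = 9, n_per_gene = 3)
  expect_identical(a1, a2)  # deterministic per seed
  expect_true(all(table(a1$gene_id) == 3))

  # single-eligible-base gene always yields that base
  one <- make_annotation(list(tiny = list(start0 = 100, end0 = 101)))
  expect_equal(start(sample_control_positions(one, seed = 1)), 101)

  # 150-base gene contributes nothing under a 200-base end filter
  filt <- suppressMessages(
    sample_control_positions(ann, seed = 9, min_end_distance = 200))
  expect_false("small" %in% filt$gene_id)
  # remaining positions keep their distance from the 3' end
  for (i in seq_along(filt)) {
    g <- ann$genes[ann$genes$gene_id == filt$gene_id[i]]
    end3 <- if (as.character(strand(g)) == "-") start(g) else end(g)
    expect_gte(abs(start(filt)[i] - end3), 200)
  }

  # per-gene uniformity over exonic bases (chi-square over 4 bins)
  unif <- make_annotation(list(u = list(start0 = 0, end0 = 4000)),
                          seqlen = c(chr1 = 5000L))
  draws <- sample_control_positions(unif, seed = 10, n_per_gene = 2000)
  bins <- cut(start(draws), breaks = seq(0.5, 4000.5, length.out = 5))
  p <- chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("anchor-set comparison finds a planted shift and handles ties", {
  set.seed(84)
  v <- rnorm(20000)^2
  tr <- rle_track(v)
  a <- anchor(sample(100:9000, 100))
  b <- anchor(sample(10000, 100, replace = FALSE) + 9500)
  # same distribution -> typically non-significant; identical sets -> p = 1
  same <- compare_anchor_sets(tr, a, a)
  expect_equal(same$p_value, 1)
  # planted constant shift on b's windows
  v2 <- v
  for (p in start(b)) v2[(p - 10):(p + 9)] <- v2[(p - 10):(p + 9)] + 5
  shifted <- compare_anchor_sets(rle_track(v2), a, b)
  expect_lt(shifted$p_value, 0.001)
  # all-tied degenerate case flagged with p = 1
  flat <- compare_anchor_sets(rle_track(rep(2, 20000)), a, b)
  expect_true(flat$degenerate)
  expect_equal(flat$p_value, 1)
})

test_that("exact Wilcoxon path matches exhaustive enumeration at n = 3 + 3", {
  set.seed(85)
  for (rep in 1:5) {
    x <- rnorm(3); y <- rnorm(3)
    got <- wilcoxon_rank_sum(x, y)
    expect_true(got$exact)
    # enumerate all 20 assignments of ranks to group A
    pooled <- c(x, y)
    r <- rank(pooled)
    stat_obs <- sum(r[1:3]) - 3 * 4 / 2
    combs <- combn(6, 3)
    stats <- apply(combs, 2, function(idx) sum(r[idx]) - 6)
    p_oracle <- mean(abs(stats - 4.5) >= abs(stat_obs - 4.5) - 1e-12)
    expect_equal(got$p_value, p_oracle, tolerance = 1e-12)
  }
})

test_that("boxplot statistics follow the 1.5 IQR whisker rule", {
  b <- boxplot_stats(1:100)
  expect_equal(b$median, 50.5)
  expect_equal(b$lower_hinge, unname(quantile(1:100, 0.25)))
  expect_equal(b$upper_hinge - b$lower_hinge, 49.5)
  expect_equal(b$n_outliers, 0)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 100)

  const <- boxplot_stats(rep(7, 10))
  expect_equal(const$median, 7)
  expect_equal(const$whisker_low, 7)
  expect_equal(const$whisker_high, 7)
  expect_equal(const$n_outliers, 0)

  out <- boxplot_stats(c(1:99, 1000))
  expect_equal(out$n_outliers, 1)
  expect_equal(out$whisker_high, 99)
  expect_error(boxplot_stats(numeric(0)), "no values")

  # oracle on random data
  set.seed(86)
  v <- rnorm(500)
  b2 <- boxplot_stats(v)
  q <- quantile(v, c(0.25, 0.75), type = 7)
  fence <- c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
  expect_equal(b2$n_outliers, sum(v < fence[1] | v > fence[2]))
  expect_equal(b2$whisker_low, min(v[v >= fence[1]]))
  expect_equal(b2$whisker_high, max(v[v <= fence[2]]))
})

test_that("single-end reads resize to half the insert from their 3' end", {
  sl <- c(chr1 = 1000L)
  # + read 0-based [100,175), insert 100 -> resized 0-based [125,175)
  plus <- resize_single_end(gr0("chr1", 100, 175, "+"), 100, sl)
  expect_equal(which(as.numeric(plus$chr1) == 1), 126:175)
  # - read 0-based [100,175) -> 3' end at 100 -> [100,150)
  minus <- resize_single_end(gr0("chr1", 100, 175, "-"), 100, sl)
  expect_equal(which(as.numeric(minus$chr1) == 1), 101:150)
  # read length equal to half insert is unchanged
  eq <- resize_single_end(gr0("chr1", 100, 150, "+"), 100, sl)
  expect_equal(which(as.numeric(eq$chr1) == 1), 101:150)
  # coverage mass = reads x floor(insert/2) minus clipped bases
  set.seed(87)
  reads <- GRanges("chr1", IRanges(sample.int(900, 50), width = 30),
                   strand = sample(c("+", "-"), 50, replace = TRUE))
  cov <- resize_single_end(reads, 75, sl)
  resized_starts <- ifelse(as.character(strand(reads)) == "-", start(reads),
                           end(reads) - 36)
  clipped <- sum(pmax(0, 1 - resized_starts)) +
    sum(pmax(0, (resized_starts + 36) - 1000))
  expect_equal(sum(as.numeric(cov$chr1)), 50 * 37 - clipped)
})
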