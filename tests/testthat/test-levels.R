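# Level quantification, error calibration, binomial calling, coverage
# filtering and summaries.

test_that("site levels are exact fractions with NA for zero coverage", {
  expect_equal(site_level(0, 10), 0)
  expect_equal(site_level(10, 0), 1)
  expect_equal(site_level(3, 7), 0.3)
  expect_true(is.na(site_level(0, 0)))
  expect_error(site_level(-1, 5), "non-negative")
})

test_that("region levels pool reads rather than averaging site levels", {
  expect_equal(region_level(c(3, 7), c(7, 3)), 0.5)
  expect_equal(region_level(0, 10), 0)
  # weighting matters: {(9,1),(0,10)} pools to 9/20
  expect_equal(region_level(c(9, 0), c(1, 10)), 0.45)
  expect_equal(region_level(c(9, 0), c(1, 10), weighted = FALSE), 0.45)
  expect_equal(region_level(c(9, 1), c(1, 9), weighted = FALSE), 0.5)
  expect_true(is.na(region_level(integer(), integer())))
})

test_that("pooling is associative over disjoint site sets", {
  set.seed(10)
  for (i in 1:20) {
    m <- rbinom(40, 30, 0.4); u <- rbinom(40, 30, 0.6)
    split <- sample(40, 17)
    la <- region_level(m[split], u[split])
    lb <- region_level(m[-split], u[-split])
    ta <- sum(m[split] + u[split]); tb <- sum(m[-split] + u[-split])
    expect_equal(region_level(m, u), (la * ta + lb * tb) / (ta + tb))
  }
})

test_that("spike-in error rate is the pooled methylated fraction", {
  tab <- site_table(data.table::data.table(
    chrom = "lambda", pos = c(10L, 20L, 30L), strand = "+",
    context = "CpG", s_M = c(50L, 50L, 50L),
    s_U = c(9950L, 9950L, 9950L)), "s")
  est <- estimate_error_rate(tab)
  expect_equal(est$rate, 150 / 30000)
  expect_equal(est$total_reads, 30000L)
  empty <- site_table(tab[0], "s")
  expect_error(estimate_error_rate(empty), "spike-in")
})

test_that("binomial calling matches an exact summation oracle", {
  res <- call_methylated(3, 7, 0.01, alpha = 0.01, correction = "none")
  expect_equal(res$p_value, binom_tail_oracle(3, 10, 0.01),
               tolerance = 1e-12)
  expect_equal(res$p_value, 1.1384911791e-04, tolerance = 1e-9)
  expect_true(res$called)
  # random comparisons up to n = 1000
  set.seed(11)
  for (i in 1:25) {
    n <- sample(1000, 1); x <- sample.int(min(n, 40), 1)
    r <- sample(c(0.002, 0.01, 0.05), 1)
    got <- call_methylated(x, n - x, r, correction = "none")$p_value
    expect_equal(got, binom_tail_oracle(x, n, r), tolerance = 1e-12)
  }
})

test_that("binomial calling handles degenerate inputs and bad rates", {
  expect_equal(call_methylated(0, 10, 0.01)$p_value, 1)
  expect_false(call_methylated(0, 10, 0.01)$called)
  r <- call_methylated(10, 0, 0, alpha = 0.01)
  expect_equal(r$p_value, 0)
  expect_true(r$called)
  expect_error(call_methylated(5, 5, 0.6), "calibration")
  expect_error(call_methylated(0, 0, 0.01), "coverage")
})

test_that("false-call rate on simulated lambda stays within alpha", {
  sp <- simulate_spikein(20000L, read_count_model(
    mean_coverage = 30, nonconversion = 0.005, seed = 21))
  est <- estimate_error_rate(sp)
  covered <- sp[sp$spikein_M + sp$spikein_U > 0]
  calls <- call_methylated(covered$spikein_M, covered$spikein_U, est,
                           alpha = 0.01, correction = "BH")
  expect_lte(mean(calls$called), 0.01)
})

test_that("coverage filtering enforces the all-samples depth rule", {
  tab <- site_table(data.table::data.table(
    chrom = "chr1", pos = c(100L, 200L, 300L), strand = "+",
    context = "CpG",
    a_M = c(6L, 5L, 4L), a_U = c(6L, 5L, 5L),
    b_M = c(7L, 5L, 15L), b_U = c(8L, 5L, 15L)),
    c("a", "b"))
  # depths a: 12 10 9; b: 15 10 30
  kept <- filter_by_coverage(tab, 10, "all_samples")
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$pos, c(100L, 200L))
  # a site at (12, 9) across samples is dropped entirely
  tab2 <- site_table(data.table::data.table(
    chrom = "chr1", pos = 100L, strand = "+", context = "CpG",
    a_M = 6L, a_U = 6L, b_M = 4L, b_U = 5L), c("a", "b"))
  expect_equal(nrow(filter_by_coverage(tab2, 10, "all_samples")), 0L)
  # min_depth 0 keeps everything untouched
  expect_equal(nrow(filter_by_coverage(tab, 0)), 3L)
  # per-sample mode masks cells instead of dropping rows
  masked <- filter_by_coverage(tab, 10, "per_sample")
  expect_equal(nrow(masked), 3L)
  expect_true(is.na(masked$a_M[3]))
  expect_false(is.na(masked$b_M[3]))
  D <- site_depths(filter_by_coverage(fixture_counts(), 10))
  expect_true(all(D >= 10))
})

test_that("stage trajectory recovers the simulated means per stage", {
  m <- fixture_methylome()
  filt <- fixture_filtered()
  traj <- stage_trajectory(filt, "CpG")
  keys <- filt[context == "CpG", .(chrom, pos)]
  truth <- m$sites[keys, on = c("chrom", "pos")]
  for (i in seq_along(m$stages)) {
    st <- m$stages[i]
    tot <- sum(filt[context == "CpG"][[paste0(st, "_M")]] +
                 filt[context == "CpG"][[paste0(st, "_U")]])
    se <- pooled_se(traj$level[i], tot)
    expect_lt(abs(traj$level[i] - mean(truth[[st]])), 3 * se + 0.003)
  }
  # CpH trajectory stays low
  trajh <- stage_trajectory(filt, "CpH")
  expect_true(all(trajh$level < 0.08))
})

test_that("window means mark empty windows rather than writing zero", {
  tab <- site_table(data.table::data.table(
    chrom = "chr1", pos = c(100L, 150L, 5100L), strand = "+",
    context = "CpG", s_M = c(5L, 5L, 0L), s_U = c(5L, 5L, 10L)), "s")
  wm <- window_means(tab, c(chr1 = 20000L), window = 5000L)
  expect_equal(nrow(wm), 4L)
  expect_equal(wm$s[1], 0.5)
  expect_equal(wm$s[2], 0)
  expect_true(all(is.na(wm$s[3:4])))
  expect_equal(wm$window_end[4], 20000L)
})

test_that("TSS metagene profiles dip at CGI promoters and mirror strand", {
  g <- fixture_genome()
  filt <- fixture_filtered()
  tp <- tss_profile(filt, g$annotation$genes)
  sp <- tp[sample_id == "sperm"]
  centre <- sp[abs(offset_mid) <= 300, min(level)]
  flank_out <- sp[abs(offset_mid) >= 1500, mean(level)]
  expect_lt(centre, flank_out)
  # a minus-strand gene anchored at the same TSS mirrors the
  # plus-strand profile exactly (positions chosen off bin boundaries)
  tss <- 60000L
  offs <- c(-990L, -450L, -150L, 10L, 130L, 570L, 990L)
  mini <- site_table(data.table::data.table(
    chrom = "chrM", pos = tss + offs, strand = "+", context = "CpG",
    s_M = c(1L, 2L, 3L, 4L, 5L, 6L, 7L),
    s_U = c(9L, 8L, 7L, 6L, 5L, 4L, 3L)), "s")
  gp <- GenomicRanges::GRanges("chrM",
                               IRanges::IRanges(tss, tss + 2999L),
                               strand = "+")
  gm <- GenomicRanges::GRanges("chrM",
                               IRanges::IRanges(tss - 2999L, tss),
                               strand = "-")
  p1 <- tss_profile(mini, gp, flank = 1000L, n_bins = 10L)
  p2 <- tss_profile(mini, gm, flank = 1000L, n_bins = 10L)
  expect_equal(p1[order(bin), level],
               p2[order(-bin), level])
  expect_equal(sort(p1$bin + 0L), sort(9L - p2$bin))
})

test_that("feature profiles separate islands from gene bodies", {
  g <- fixture_genome()
  filt <- fixture_filtered()
  fp <- feature_profile(filt, list(
    cgi = g$annotation$cgis, exon = g$annotation$exon,
    intron = g$annotation$intron))
  sp <- fp[sample_id == "sperm"]
  expect_lt(sp[feature == "cgi", level], sp[feature == "exon", level])
  # feature with no covered sites reports NA, not zero
  far <- GenomicRanges::GRanges("chrNope", IRanges::IRanges(1, 100))
  fp2 <- suppressWarnings(feature_profile(filt, list(nothing = far)))
  expect_true(all(is.na(fp2$level)))
})
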