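# Sliding-window DMR caller: candidate selection, run merging, region
# testing, recovery against planted truth, oracle equivalence and
# structural validation.

make_pair_table <- function(pos, a_m, a_u, b_m, b_u, chrom = "chr1") {
  site_table(data.table::data.table(
    chrom = chrom, pos = as.integer(pos), strand = "+",
    context = "CpG", A_M = as.integer(a_m), A_U = as.integer(a_u),
    B_M = as.integer(b_m), B_U = as.integer(b_u)), c("A", "B"))
}

test_that("candidate sites require depth 5 in both samples", {
  tab <- make_pair_table(c(100, 200), c(10, 4), c(0, 0),
                         c(0, 0), c(10, 50))
  cand <- find_candidate_sites(tab, c("A", "B"))
  # the (4, 50)-depth site is excluded no matter how discordant
  expect_equal(cand$pos, 100L)
  # identical samples yield no candidates
  same <- make_pair_table(c(100, 200), c(5, 5), c(5, 5), c(5, 5),
                          c(5, 5))
  expect_equal(nrow(find_candidate_sites(same, c("A", "B"))), 0L)
})

test_that("a fully discordant 12-site run is significant site by site", {
  pos <- 100 + (0:11) * 50
  tab <- make_pair_table(pos, rep(10, 12), rep(0, 12), rep(0, 12),
                         rep(10, 12))
  cand <- find_candidate_sites(tab, c("A", "B"))
  expect_equal(nrow(cand), 12L)
  expect_true(all(abs(cand$p_value - 2 / 184756) < 1e-12))
  expect_true(all(cand$direction == "hyper_in_a"))
  runs <- merge_candidates(cand)
  expect_equal(length(unique(runs$run_id)), 1L)
  expect_equal(nrow(runs), 12L)
})

test_that("runs respect the gap, direction and minimum-site rules", {
  base <- data.table::data.table(
    chrom = "chr1", pos = 100L + (0:11) * 50L,
    a_meth = 10L, a_unmeth = 0L, b_meth = 0L, b_unmeth = 10L,
    level_a = 1, level_b = 0, p_value = 2 / 184756,
    direction = "hyper_in_a")
  # 9 sites only: no run survives
  expect_equal(nrow(merge_candidates(base[1:9])), 0L)
  # a > 300 bp gap splits the run below the size threshold
  broken <- data.table::copy(base)
  broken[7:12, pos := pos + 400L]
  expect_equal(nrow(merge_candidates(broken)), 0L)
  # gap of exactly 300 bp does not split
  exact <- data.table::copy(base)
  exact[7:12, pos := pos + 250L]   # neighbour distance 300
  expect_equal(nrow(merge_candidates(exact)), 12L)
  # alternating directions never build a run
  alt <- data.table::copy(base)
  alt[seq(2, 12, 2), `:=`(direction = "hypo_in_a", level_a = 0,
                          level_b = 1)]
  expect_equal(nrow(merge_candidates(alt)), 0L)
})

test_that("region test enforces the pooled p and mean difference", {
  # pooled [[120,0],[0,120]]: overwhelming
  run <- data.table::data.table(
    chrom = "chr1", pos = 100L + (0:11) * 50L,
    a_meth = 10L, a_unmeth = 0L, b_meth = 0L, b_unmeth = 10L,
    level_a = 1, level_b = 0, p_value = 2 / 184756,
    direction = "hyper_in_a")
  dmr <- region_test(run)
  expect_false(is.null(dmr))
  expect_equal(dmr$mean_diff, 1)
  expect_lt(dmr$region_p, 1e-10)
  expect_equal(dmr$start, 99L)       # BED half-open over the site run
  expect_equal(dmr$end, 650L)
  # pooled levels 0.55 vs 0.35: difference below 0.3, rejected
  run2 <- data.table::copy(run)
  run2[, `:=`(a_meth = 11L, a_unmeth = 9L, b_meth = 7L,
              b_unmeth = 13L)]
  expect_null(region_test(run2))
  # identical pooled counts: p = 1, rejected
  run3 <- data.table::copy(run)
  run3[, `:=`(a_meth = 5L, a_unmeth = 5L, b_meth = 5L, b_unmeth = 5L)]
  expect_null(region_test(run3))
})

test_that("planted DMRs are recovered and the null stays clean", {
  bm <- simulate_dmr_benchmark(n_dmrs = 8, sites_per_dmr = 15,
                               delta = 0.5, n_background = 6000,
                               seed = 31)
  calls <- call_dmrs(bm$table, c("A", "B"))
  jac <- dmr_recovery(calls, bm$truth_dmrs)
  expect_gte(mean(jac >= 0.8), 0.8)
  # no call further than 300 bp from any planted region
  near <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(bm$truth_dmrs))) {
    tt <- bm$truth_dmrs[i]
    near <- near | (calls$chrom == tt$chrom &
                      calls$end > tt$start - 301L &
                      calls$start < tt$end + 300L)
  }
  expect_true(all(near))
  # direction bookkeeping matches the planted sign
  expect_setequal(unique(calls$direction),
                  unique(bm$truth_dmrs$direction))
  # two resamplings of one truth: zero calls
  null <- simulate_dmr_benchmark(n_dmrs = 0, n_background = 6000,
                                 seed = 32)
  expect_equal(nrow(call_dmrs(null$table, c("A", "B"))), 0L)
  # identical samples trivially give zero calls
  tab <- make_pair_table(100 + (0:20) * 40, rbinom(21, 20, 0.5),
                         rbinom(21, 20, 0.5), 0, 0)
  tab[, `:=`(B_M = A_M, B_U = A_U)]
  expect_equal(nrow(call_dmrs(tab, c("A", "B"))), 0L)
})

test_that("caller output equals brute-force enumeration", {
  for (s in 1:10) {
    tab <- simulate_random_pair(200, seed = 100 + s)
    a <- call_dmrs(tab, c("A", "B"))
    b <- enumerate_dmrs_bruteforce(tab, c("A", "B"))
    expect_identical(
      sort(a[, paste(chrom, start, end, direction, n_sites)]),
      sort(b[, paste(chrom, start, end, direction, n_sites)]))
  }
})

test_that("tightening thresholds never yields more DMRs", {
  tab <- simulate_random_pair(400, seed = 55)
  base <- nrow(call_dmrs(tab, c("A", "B")))
  expect_lte(nrow(call_dmrs(tab, c("A", "B"), min_diff = 0.5)), base)
  expect_lte(nrow(call_dmrs(tab, c("A", "B"), region_alpha = 0.001)),
             base)
  expect_lte(nrow(call_dmrs(tab, c("A", "B"), min_sites = 15L)), base)
})

test_that("emitted DMRs survive the independent validator", {
  bm <- simulate_dmr_benchmark(n_dmrs = 6, sites_per_dmr = 15,
                               delta = 0.5, n_background = 4000,
                               seed = 33)
  calls <- call_dmrs(bm$table, c("A", "B"))
  expect_gt(nrow(calls), 0)
  expect_true(all(validate_dmrs(calls, bm$table, c("A", "B"))))
  # corrupting a DMR is caught
  bad <- data.table::copy(calls)
  bad$direction[1] <- setdiff(c("hyper_in_a", "hypo_in_a"),
                              bad$direction[1])
  expect_false(validate_dmrs(bad, bm$table, c("A", "B"))[1])
})

test_that("non-significant intervening sites can optionally break runs", {
  # 12 strong candidates with a qualified but non-significant CpG in
  # the middle: default merges across it, the strict flag splits
  pos <- c(100 + (0:5) * 50, 420, 100 + (6:11) * 50 + 40)
  a_m <- c(rep(10, 6), 5, rep(10, 6)); a_u <- c(rep(0, 6), 5, rep(0, 6))
  b_m <- c(rep(0, 6), 5, rep(0, 6)); b_u <- c(rep(10, 6), 5, rep(10, 6))
  tab <- make_pair_table(sort(pos), a_m, a_u, b_m, b_u)
  merged <- call_dmrs(tab, c("A", "B"))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_sites, 12L)
  strict <- call_dmrs(tab, c("A", "B"), break_at_nonsig = TRUE)
  expect_equal(nrow(strict), 0L)   # both halves fall below 10 sites
})

test_that("DMR annotation uses midpoint feature precedence", {
  g <- fixture_genome()
  ann <- g$annotation
  # a DMR centred inside a promoter
  pr <- ann$promoters[1]
  mid <- (GenomicRanges::start(pr) + GenomicRanges::end(pr)) %/% 2
  dmrs <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(pr)),
    start = mid - 50L, end = mid + 50L, n_sites = 10L,
    direction = "hyper_in_a", region_p = 1e-5, mean_diff = 0.5,
    level_a = 0.8, level_b = 0.3, sites = list(mid))
  expect_equal(annotate_dmrs(dmrs, ann)$annotation, "promoter")
  # far from any feature: intergenic
  dmrs2 <- data.table::copy(dmrs)
  dmrs2[, `:=`(chrom = "chrEmpty", start = 1000L, end = 1100L)]
  expect_equal(annotate_dmrs(dmrs2, ann)$annotation, "intergenic")
  # spanning an exon/intron boundary with the midpoint in the exon;
  # uses the distal exon, which lies beyond the promoter's 1 kb tail
  e2 <- ann$exon[2]; inn <- ann$intron[1]
  dmrs3 <- data.table::copy(dmrs)
  dmrs3[, chrom := as.character(GenomicRanges::seqnames(e2))]
  if (GenomicRanges::start(e2) == GenomicRanges::end(inn) + 1L) {
    b <- GenomicRanges::start(e2)        # intron | exon, + strand gene
    dmrs3[, `:=`(start = b - 11L, end = b + 30L)]
  } else {
    b <- GenomicRanges::end(e2)          # exon | intron, - strand gene
    dmrs3[, `:=`(start = b - 31L, end = b + 10L)]
  }
  expect_equal(annotate_dmrs(dmrs3, ann)$annotation, "exon")
})

test_that("planted promoter methylation gains are recovered", {
  g <- fixture_genome()
  pr <- g$annotation$promoters
  pick <- pr[1:3]
  planted <- lapply(seq_along(pick), function(i) list(
    chrom = as.character(GenomicRanges::seqnames(pick))[i],
    start = GenomicRanges::start(pick)[i],
    end = GenomicRanges::end(pick)[i],
    pair = c("twocell", "eightcell"), direction = "hyper",
    delta = 0.5))
  m <- simulate_methylomes(g, stage_spec(planted_dmrs = planted,
                                         seed = 91))
  cnt <- simulate_counts(m, read_count_model(
    seed = 92, nonconversion = 0, overconversion = 0))
  filt <- filter_by_coverage(cnt, 10)
  res <- promoter_gain_loss(filt, pr, c("twocell", "eightcell"))
  expect_true(all(pick$gene_id %in% res$gained))
  expect_false(any(pick$gene_id %in% res$lost))
})

test_that("promoter gain/loss classification is antisymmetric", {
  filt <- fixture_filtered()
  g <- fixture_genome()
  ab <- promoter_gain_loss(filt, g$annotation$promoters,
                           c("twocell", "eightcell"))
  ba <- promoter_gain_loss(filt, g$annotation$promoters,
                           c("eightcell", "twocell"))
  expect_setequal(ab$gained, ba$lost)
  expect_setequal(ab$lost, ba$gained)
  # an uncovered promoter is unclassified
  far <- GenomicRanges::GRanges("chrNope", IRanges::IRanges(1, 1000),
                                gene_id = "ghost")
  res <- suppressWarnings(promoter_gain_loss(
    filt, far, c("twocell", "eightcell")))
  expect_equal(res$unclassified, "ghost")
})
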