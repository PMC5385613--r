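# Gamete-specific site tracing, CGI and stage clustering, chromosome
# trajectories.

test_that("gamete-specific membership uses strict thresholds", {
  tab <- site_table(data.table::data.table(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L), strand = "+",
    context = "CpG",
    sperm_M = c(16L, 15L, 20L, 2L), sperm_U = c(4L, 5L, 0L, 18L),
    oocyte_M = c(2L, 5L, 30L, 16L), oocyte_U = c(18L, 15L, 10L, 4L)),
    c("sperm", "oocyte"))
  gs <- gamete_specific_sites(tab, c("sperm", "oocyte"))
  # site 1: 0.80 / 0.10 -> sperm-specific
  expect_true(100L %in% gs$sperm_specific$pos)
  # site 2: sperm level exactly 0.75 is excluded (strict >)
  expect_false(200L %in% gs$sperm_specific$pos)
  # site 3: both high -> neither
  expect_false(300L %in% c(gs$sperm_specific$pos,
                           gs$oocyte_specific$pos))
  # site 4: 0.10 / 0.80 -> oocyte-specific
  expect_true(400L %in% gs$oocyte_specific$pos)
  # oocyte level exactly 0.25 on the hypo side is excluded
  tab2 <- site_table(data.table::data.table(
    chrom = "chr1", pos = 100L, strand = "+", context = "CpG",
    sperm_M = 16L, sperm_U = 4L, oocyte_M = 5L, oocyte_U = 15L),
    c("sperm", "oocyte"))
  gs2 <- gamete_specific_sites(tab2, c("sperm", "oocyte"))
  expect_equal(nrow(gs2$sperm_specific), 0L)
})

test_that("planted gamete-specific sites are recovered at depth", {
  g <- fixture_genome()
  m <- fixture_methylome()
  cnt <- simulate_counts(m, read_count_model(
    mean_coverage = 50, nonconversion = 0, overconversion = 0,
    seed = 77))
  filt <- filter_by_coverage(cnt, 10)
  gs <- gamete_specific_sites(filt, c("sperm", "oocyte"))
  planted <- m$sites[compartment == "sperm_specific",
                     paste(chrom, pos)]
  found <- gs$sperm_specific[, paste(chrom, pos)]
  expect_gte(mean(planted %in% found), 0.95)
  # tracing the defining gamete stays consistent with the thresholds
  tr <- trace_sites(gs$sperm_specific, filt)
  expect_gt(tr[sample_id == "sperm", mean], 0.75)
  expect_lt(tr[sample_id == "oocyte", mean], 0.25)
  # maternal (oocyte-specific) sites barely move after fertilisation
  os <- gamete_specific_sites(filt, c("sperm", "oocyte"))$oocyte_specific
  tro <- trace_sites(os, filt)
  post <- tro[sample_id %in% c("twocell", "eightcell", "morula", "icm"),
              mean]
  expect_lt(max(post) - min(post), 0.1)
  # empty set gives an empty summary
  expect_equal(nrow(trace_sites(gs$sperm_specific[0], filt)), 0L)
})

test_that("CGI k-means recovers planted island archetypes", {
  skip_if_not_installed("mclust")
  g <- fixture_genome()
  m <- fixture_methylome()
  filt <- fixture_filtered()
  cm <- cgi_matrix(filt, g$annotation$cgis)
  km <- kmeans_cluster(cm, k = 3, seed = 9)
  cg <- g$annotation$cgis
  arch <- vapply(seq_along(cg), function(i) {
    sub <- m$sites[chrom == as.character(
      GenomicRanges::seqnames(cg))[i] &
        pos >= GenomicRanges::start(cg)[i] &
        pos <= GenomicRanges::end(cg)[i] & context == "CpG"]
    names(sort(table(sub$compartment), decreasing = TRUE))[1]
  }, character(1))
  rn <- paste0(GenomicRanges::seqnames(cg), ":",
               GenomicRanges::start(cg), "-", GenomicRanges::end(cg))
  keep <- rn %in% names(km$assignment)
  ari <- mclust::adjustedRandIndex(km$assignment[rn[keep]], arch[keep])
  expect_gte(ari, 0.9)
})

test_that("k-means is deterministic and permutation-equivariant", {
  set.seed(3)
  mat <- matrix(rnorm(40 * 5), 40, 5,
                dimnames = list(paste0("r", 1:40), NULL))
  k1 <- kmeans_cluster(mat, 4, seed = 2)
  k2 <- kmeans_cluster(mat, 4, seed = 2)
  expect_identical(k1$assignment, k2$assignment)
  perm <- sample(40)
  k3 <- kmeans_cluster(mat[perm, ], 4, seed = 2)
  # same partition up to relabelling
  tab <- table(k1$assignment[rownames(mat)[perm]], k3$assignment)
  expect_true(all(rowSums(tab > 0) == 1))
  # identical rows with k = 1 collapse to a single zero-inertia cluster
  same <- matrix(0.5, 10, 3, dimnames = list(paste0("r", 1:10), NULL))
  k4 <- kmeans_cluster(same, 1, seed = 1)
  expect_equal(unname(k4$inertia), 0)
  expect_equal(length(unique(k4$assignment)), 1L)
})

test_that("stage clustering merges the two hypomethylated minima first", {
  filt <- fixture_filtered()
  hc <- hierarchical_cluster_stages(filt, "CpG")
  expect_equal(sort(strsplit(hc$merge_order[1], "\\+")[[1]]),
               c("morula", "twocell"))
  # dendrogram heights are non-decreasing under average linkage
  expect_true(all(diff(hc$hclust$height) >= -1e-12))
  # the metric is recorded in the output
  hc2 <- hierarchical_cluster_stages(filt, "CpG", metric = "correlation")
  expect_equal(hc2$metric, "correlation")
  # Newick export round-trips through ape
  f <- tempfile(fileext = ".nwk")
  write_newick(hc, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, st_samples(filt))
})

test_that("a duplicated sample merges first at zero height", {
  filt <- fixture_filtered()
  dup <- data.table::copy(filt)
  dup[, `:=`(sperm2_M = dup$sperm_M, sperm2_U = dup$sperm_U)]
  dup <- site_table(dup, c(st_samples(filt), "sperm2"),
                    validate = FALSE)
  hc <- hierarchical_cluster_stages(dup, "CpG")
  expect_equal(sort(strsplit(hc$merge_order[1], "\\+")[[1]]),
               c("sperm", "sperm2"))
  expect_equal(hc$hclust$height[1], 0)
})

test_that("X-chromosome trajectory shadows the autosomal one", {
  filt <- fixture_filtered()
  ct <- chromosome_trajectory(filt, "chrX")
  expect_equal(nrow(ct), 7L)
  expect_lt(max(abs(ct$subset_level - ct$complement_level)), 0.05)
  expect_error(chromosome_trajectory(filt, c("chr1", "chr2", "chrX")),
               "complement")
  expect_error(chromosome_trajectory(filt, "chr99"), "no sites")
})
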