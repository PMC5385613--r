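# SNP filtering, parent-of-origin assignment, allele trajectories and
# RDL-based ADM classification.

one_snp <- function(...) {
  base <- data.table::data.table(
    chrom = "chr1", pos = 1000L, ref = "A", alt = "C",
    sperm_gt = "A/A", offspring_gt = "A/C",
    base_qual = 20L, var_conf = 30L, geno_qual = 35L,
    ref_depth = 13L, alt_depth = 12L, zygote_depth = 25L,
    gt_zygote = "A/C", gt_morula = "A/C")
  mod <- list(...)
  for (k in names(mod)) data.table::set(base, j = k, value = mod[[k]])
  base
}

test_that("the four quality criteria plus allele depth gate records", {
  expect_equal(nrow(filter_candidate_snps(one_snp())), 1L)
  expect_equal(nrow(filter_candidate_snps(one_snp(zygote_depth = 9L))), 0L)
  expect_equal(nrow(filter_candidate_snps(one_snp(base_qual = 4L))), 0L)
  expect_equal(nrow(filter_candidate_snps(one_snp(var_conf = 19L))), 0L)
  # genotype quality exactly 20 fails the strict inequality
  expect_equal(nrow(filter_candidate_snps(one_snp(geno_qual = 20L))), 0L)
  expect_equal(nrow(filter_candidate_snps(one_snp(geno_qual = 21L))), 1L)
  # both alleles need 10x: 12/5 fails
  expect_equal(nrow(filter_candidate_snps(one_snp(
    ref_depth = 12L, alt_depth = 5L, zygote_depth = 17L))), 0L)
  # genotype must be consistent wherever observed
  expect_equal(nrow(filter_candidate_snps(one_snp(gt_morula = "A/A"))), 0L)
  expect_equal(nrow(filter_candidate_snps(one_snp(gt_morula = "."))), 1L)
  # homozygous offspring records are not usable
  expect_equal(nrow(filter_candidate_snps(one_snp(
    offspring_gt = "A/A", gt_zygote = "A/A", gt_morula = "A/A"))), 0L)
  # bisulfite-confounded pairs are excluded by default, kept on demand
  ct <- one_snp(ref = "C", alt = "T", sperm_gt = "C/C",
                offspring_gt = "C/T", gt_zygote = "C/T",
                gt_morula = "C/T")
  expect_equal(nrow(filter_candidate_snps(ct)), 0L)
  expect_equal(nrow(filter_candidate_snps(ct, exclude_ct = FALSE)), 1L)
})

test_that("filtering is idempotent and order-independent", {
  snpfx <- fixture_snps()
  f1 <- filter_candidate_snps(snpfx$snps)
  f2 <- filter_candidate_snps(f1)
  expect_equal(as.data.frame(f1), as.data.frame(f2),
               ignore_attr = TRUE)
  shuf <- snpfx$snps[sample(nrow(snpfx$snps))]
  f3 <- filter_candidate_snps(shuf)
  data.table::setkeyv(f3, c("chrom", "pos"))
  g1 <- data.table::copy(f1); data.table::setkeyv(g1, c("chrom", "pos"))
  expect_equal(as.data.frame(g1), as.data.frame(f3),
               ignore_attr = TRUE)
  # the filter keeps clean records plus the het-sperm plants (those
  # fail later, at parent assignment, not here)
  expect_equal(nrow(f1),
               sum(is.na(snpfx$truth$fail_reason) |
                     snpfx$truth$fail_reason == "sperm_het"))
  asn <- assign_parent_of_origin(f1)
  expect_equal(nrow(asn$assigned), sum(is.na(snpfx$truth$fail_reason)))
})

test_that("parental origin follows the sperm-genotype rule", {
  a <- assign_parent_of_origin(one_snp())
  expect_equal(a$assigned$paternal_allele, "ref")
  expect_equal(a$assigned$maternal_allele, "alt")
  # sperm matching the alt allele flips the assignment
  b <- assign_parent_of_origin(one_snp(sperm_gt = "C/C"))
  expect_equal(b$assigned$paternal_allele, "alt")
  # heterozygous sperm cannot anchor the assignment
  het <- assign_parent_of_origin(one_snp(sperm_gt = "A/C"))
  expect_equal(nrow(het$assigned), 0L)
  expect_equal(het$unassignable$reason, "sperm_heterozygous")
  # sperm allele absent from the offspring pair
  none <- assign_parent_of_origin(one_snp(sperm_gt = "G/G"))
  expect_equal(none$unassignable$reason, "no_matching_allele")
})

test_that("assignment is fully concordant with planted truth", {
  snpfx <- fixture_snps()
  asn <- assign_parent_of_origin(filter_candidate_snps(snpfx$snps))
  key <- asn$assigned[, paste(chrom, pos)]
  truth <- snpfx$truth[match(key, snpfx$truth[, paste(chrom, pos)])]
  expect_gt(nrow(asn$assigned), 1000)
  expect_equal(mean(asn$assigned$paternal_allele ==
                      truth$paternal_allele), 1)
})

test_that("parental trajectories recover planted levels", {
  snpfx <- fixture_snps()
  asn <- assign_parent_of_origin(filter_candidate_snps(snpfx$snps))
  am <- allele_methylation(asn$assigned, snp_spec()$stage_names)
  key <- asn$assigned[, paste(chrom, pos)]
  truth <- snpfx$truth[match(key, snpfx$truth[, paste(chrom, pos)])]
  for (st in c("sperm", "zygote", "icm")) {
    row <- am[stage == st & parent == "paternal"]
    want <- mean(truth[[paste0("pat_", st)]])
    se <- pooled_se(row$level, row$total_reads)
    # 3 binomial SE plus the finite-site truth dispersion
    expect_lt(abs(row$level - want),
              3 * se + 3 * sd(truth[[paste0("pat_", st)]]) /
                sqrt(nrow(truth)))
  }
  row <- am[stage == "oocyte" & parent == "maternal"]
  want <- mean(truth$mat_oocyte)
  expect_lt(abs(row$level - want), 0.01)
  # shuffled parent labels erase the gamete difference
  shuffled <- data.table::copy(asn$assigned)
  flip <- sample(c(TRUE, FALSE), nrow(shuffled), replace = TRUE)
  shuffled[flip, `:=`(paternal_allele = maternal_allele,
                      maternal_allele = paternal_allele)]
  am2 <- allele_methylation(shuffled, c("twocell"))
  d <- abs(am2[parent == "paternal", level] -
             am2[parent == "maternal", level])
  expect_lt(d, 0.02)
  # zero assigned SNPs warn and return an empty result
  expect_warning(empty <- allele_methylation(
    asn$assigned[0], snp_spec()$stage_names), "no assigned")
  expect_equal(nrow(empty), 0L)
})

test_that("RDL arithmetic, flooring and invariances hold", {
  expect_equal(compute_rdl(0.8, 0.2), 0.75)
  expect_equal(compute_rdl(0.5, 0.5), 0)
  expect_equal(compute_rdl(0.5, 0.8), 0)      # floored, not negative
  expect_true(is.na(compute_rdl(0, 0.1)))
  # monotone decreasing in the post level
  post <- seq(0, 1, 0.05)
  expect_true(all(diff(compute_rdl(rep(0.9, length(post)), post)) <= 0))
  # scale invariance
  expect_equal(compute_rdl(0.8, 0.2), compute_rdl(0.4, 0.1))
})

test_that("ADM classification is inclusive at the 0.6 threshold", {
  rec <- data.table::data.table(
    chrom = "chr1", pos = 1:3, parent = "paternal",
    level_pre = c(1, 1, 1), level_post = c(0.4, 0.41, 0.39))
  rec[, rdl := compute_rdl(level_pre, level_post)]
  cls <- classify_adm_sites(rec, 0.6)
  expect_equal(cls$is_adm, c(TRUE, FALSE, TRUE))
})

test_that("planted ADM fractions are recovered from read counts", {
  snpfx <- fixture_snps()
  asn <- assign_parent_of_origin(filter_candidate_snps(snpfx$snps))
  rec <- classify_adm_sites(rdl_records(asn$assigned))
  key <- asn$assigned[, paste(chrom, pos)]
  truth <- snpfx$truth[match(key, snpfx$truth[, paste(chrom, pos)])]
  for (par in c("paternal", "maternal")) {
    planted <- if (par == "paternal") mean(truth$pat_adm)
               else mean(truth$mat_adm)
    got <- mean(rec[parent == par, is_adm])
    se <- sqrt(planted * (1 - planted) / nrow(truth))
    expect_lt(abs(got - planted), 3 * se + 0.02)
  }
})

test_that("ADM genomic distribution sums to one and flags planted bias", {
  g <- fixture_genome()
  ann <- g$annotation
  intron <- ann$intron[1:5]
  # intron midpoints: clear of the 1 kb promoter tail past the TSS
  imid <- (GenomicRanges::start(intron) +
             GenomicRanges::end(intron)) %/% 2L
  rec <- data.table::data.table(
    chrom = c(as.character(GenomicRanges::seqnames(intron)),
              rep("chr1", 3)),
    pos = c(imid, c(5L, 15L, 25L)),
    parent = "paternal", level_pre = 0.9, level_post = 0.1)
  rec[, rdl := compute_rdl(level_pre, level_post)]
  rec <- classify_adm_sites(rec)
  dist <- adm_genomic_distribution(rec, ann)
  expect_equal(dist[, sum(fraction), by = parent]$V1, 1)
  expect_equal(dist[which.max(fraction), feature], "intron")
  # empty annotation: everything intergenic
  empty_ann <- list()
  dist2 <- adm_genomic_distribution(rec, empty_ann)
  expect_equal(dist2$feature, "intergenic")
  expect_equal(dist2$fraction, 1)
})
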