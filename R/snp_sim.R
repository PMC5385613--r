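# Simulated candidate-SNP tables with planted parental truth.
#
# Each record is a biallelic variant: the sperm is homozygous for one
# allele (the paternal allele in the offspring) and the offspring is
# heterozygous.  Allele-linked CpG methylation counts are sampled per
# stage from paternal/maternal true trajectories; a configurable
# fraction of gamete-high sites is planted as actively demethylated in
# the zygote.  A `fail_fraction` of records violates one filtering
# criterion each, so the filter chain is exercised end to end; the
# planted truth (parent labels, ADM flags, violated criterion) is
# returned alongside.

#' Specification of simulated candidate SNPs
#'
#' @param n_snps number of candidate records.
#' @param per_allele_depth_range min/max reads per allele per stage.
#' @param pat_pre,mat_pre mean methylation of the paternal allele in
#'   sperm and the maternal allele in the oocyte.
#' @param adm_fraction fraction of sites (per parent) actively
#'   demethylated in the zygote.
#' @param adm_rdl planted relative demethylation level at ADM sites.
#' @param offsets per-stage paternal-minus-maternal level offset for
#'   post-zygotic stages (named by stage); 0 keeps the two parental
#'   genomes identical after the 2-cell stage, as observed.
#' @param post_levels named per-stage base level for post-zygotic
#'   stages (paternal = base + offset/2, maternal = base - offset/2).
#' @param stage_names the seven ordered stage names.
#' @param sperm_genotype must be `"hom"`; a heterozygous sperm
#'   genotype cannot anchor parent-of-origin assignment and is rejected
#'   at construction.
#' @param fail_fraction fraction of records planted to violate one
#'   filter criterion.
#' @param seed RNG seed.
#' @return a `snp_spec` list.
#' @export
snp_spec <- function(n_snps = 2000L,
                     per_allele_depth_range = c(30L, 60L),
                     pat_pre = 0.8, mat_pre = 0.7,
                     adm_fraction = 0.3, adm_rdl = 0.75,
                     offsets = NULL,
                     post_levels = c(twocell = 0.35, eightcell = 0.45,
                                     morula = 0.32, icm = 0.40),
                     stage_names = c("sperm", "oocyte", "zygote",
                                     "twocell", "eightcell", "morula",
                                     "icm"),
                     sperm_genotype = "hom",
                     fail_fraction = 0.2, seed = 1L) {
  if (!identical(sperm_genotype, "hom"))
    stop("sperm genotype must be homozygous to anchor parental origin")
  stopifnot(n_snps >= 0, length(per_allele_depth_range) == 2,
            per_allele_depth_range[1] <= per_allele_depth_range[2],
            pat_pre >= 0, pat_pre <= 1, mat_pre >= 0, mat_pre <= 1,
            adm_fraction >= 0, adm_fraction <= 1,
            fail_fraction >= 0, fail_fraction <= 1)
  post_stages <- setdiff(stage_names, c("sperm", "oocyte", "zygote"))
  if (is.null(offsets))
    offsets <- setNames(rep(0, length(post_stages)), post_stages)
  stopifnot(all(post_stages %in% names(post_levels)),
            all(post_stages %in% names(offsets)))
  structure(list(n_snps = n_snps,
                 per_allele_depth_range = per_allele_depth_range,
                 pat_pre = pat_pre, mat_pre = mat_pre,
                 adm_fraction = adm_fraction, adm_rdl = adm_rdl,
                 offsets = offsets, post_levels = post_levels,
                 stage_names = stage_names,
                 fail_fraction = fail_fraction, seed = seed),
            class = "snp_spec")
}

rdepth <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

#' Simulate candidate-SNP records with allele-linked methylation
#'
#' @param spec a [snp_spec()].
#' @param genome_obj optional `synthetic_genome`; SNP positions are
#'   placed uniformly on its chromosomes (otherwise on a nominal
#'   `chr1`).
#' @return list with `snps` (the candidate table consumed by
#'   [filter_candidate_snps()]) and `truth` (parent labels, per-parent
#'   true levels, ADM flags, planted filter violations).
#' @export
simulate_snp_data <- function(spec = snp_spec(), genome_obj = NULL) {
  stopifnot(inherits(spec, "snp_spec"))
  set.seed(spec$seed)
  n <- spec$n_snps
  stages <- spec$stage_names
  if (!is.null(genome_obj)) {
    lens <- genome_obj$annotation$seqlengths
    chrom <- sample(names(lens), n, replace = TRUE)
    pos <- vapply(chrom, function(ch) sample.int(lens[[ch]] - 2L, 1),
                  integer(1))
    o <- order(chrom, pos)
    chrom <- chrom[o]; pos <- pos[o]
  } else {
    chrom <- rep("chr1", n)
    pos <- sort(sample.int(10000000L, n))
  }

  # alleles: avoid planting bisulfite-confounded pairs except where a
  # violation is planted
  pairs_ok <- list(c("A", "C"), c("A", "T"), c("C", "G"), c("G", "T"))
  pk <- sample(length(pairs_ok), n, replace = TRUE)
  ref <- vapply(pk, function(i) pairs_ok[[i]][1], character(1))
  alt <- vapply(pk, function(i) pairs_ok[[i]][2], character(1))
  pat_is_ref <- runif(n) < 0.5
  pat_allele <- ifelse(pat_is_ref, ref, alt)
  mat_allele <- ifelse(pat_is_ref, alt, ref)
  sperm_gt <- paste(pat_allele, pat_allele, sep = "/")
  offspring_gt <- paste(ref, alt, sep = "/")

  # true parental level trajectories per site
  pat_adm <- runif(n) < spec$adm_fraction
  mat_adm <- runif(n) < spec$adm_fraction
  pre_p <- rbeta(n, 30 * spec$pat_pre, 30 * (1 - spec$pat_pre))
  pre_m <- rbeta(n, 30 * spec$mat_pre, 30 * (1 - spec$mat_pre))
  lv_pat <- list(sperm = pre_p, oocyte = rep(NA_real_, n),
                 zygote = ifelse(pat_adm, pre_p * (1 - spec$adm_rdl),
                                 pre_p))
  lv_mat <- list(sperm = rep(NA_real_, n), oocyte = pre_m,
                 zygote = ifelse(mat_adm, pre_m * (1 - spec$adm_rdl),
                                 pre_m))
  for (st in setdiff(stages, c("sperm", "oocyte", "zygote"))) {
    base <- spec$post_levels[[st]]; off <- spec$offsets[[st]]
    lv_pat[[st]] <- clamp01(rbeta(n, 30 * (base + off / 2),
                                  30 * (1 - base - off / 2)))
    lv_mat[[st]] <- clamp01(rbeta(n, 30 * (base - off / 2),
                                  30 * (1 - base + off / 2)))
  }

  dr <- spec$per_allele_depth_range
  snps <- data.table::data.table(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    sperm_gt = sperm_gt, offspring_gt = offspring_gt,
    base_qual = sample(20:40, n, replace = TRUE),
    var_conf = sample(30:60, n, replace = TRUE),
    geno_qual = sample(25:60, n, replace = TRUE),
    ref_depth = rdepth(n, dr), alt_depth = rdepth(n, dr))
  snps[, zygote_depth := ref_depth + alt_depth]
  # stage genotype columns for the diploid (embryo) stages; the gamete
  # genotypes are carried by sperm_gt (anchor) and the offspring alleles
  for (st in setdiff(stages, c("sperm", "oocyte")))
    snps[, paste0("gt_", st) := offspring_gt]

  # allele-linked methylation counts per stage
  for (st in stages) {
    for (al in c("ref", "alt")) {
      is_pat <- (al == "ref") == pat_is_ref
      lv <- ifelse(is_pat, lv_pat[[st]], lv_mat[[st]])
      d <- rdepth(n, dr)
      # gametes carry a single parental genome
      if (st == "sperm") d[!is_pat] <- 0L
      if (st == "oocyte") d[is_pat] <- 0L
      d[is.na(lv)] <- 0L
      M <- ifelse(d > 0, rbinom(n, d, ifelse(is.na(lv), 0, lv)), 0L)
      snps[, paste0(st, "_", al, "_M") := as.integer(M)]
      snps[, paste0(st, "_", al, "_U") := as.integer(d - M)]
    }
  }

  # planted filter violations
  n_fail <- round(spec$fail_fraction * n)
  fail_reason <- rep(NA_character_, n)
  if (n_fail) {
    kinds <- c("depth", "base_qual", "var_conf", "geno_qual",
               "allele_depth", "inconsistent", "sperm_het", "ct_pair")
    rows <- sample(n, n_fail)
    kind <- sample(kinds, n_fail, replace = TRUE)
    fail_reason[rows] <- kind
    for (i in seq_len(n_fail)) {
      r <- rows[i]
      switch(kind[i],
        depth = snps[r, c("ref_depth", "alt_depth", "zygote_depth") :=
                       .(4L, 5L, 9L)],
        base_qual = snps[r, base_qual := 3L],
        var_conf = snps[r, var_conf := 12L],
        geno_qual = snps[r, geno_qual := 20L],      # boundary: strict >
        allele_depth = snps[r, c("alt_depth", "zygote_depth") :=
                              .(5L, ref_depth + 5L)],
        inconsistent = snps[r, gt_morula :=
                              paste(ref, ref, sep = "/")],
        sperm_het = snps[r, sperm_gt := paste(ref, alt, sep = "/")],
        ct_pair = snps[r, c("ref", "alt", "sperm_gt", "offspring_gt") :=
                         .("C", "T", "C/C", "C/T")])
    }
  }

  truth <- data.table::data.table(
    chrom = chrom, pos = pos,
    paternal_allele = ifelse(pat_is_ref, "ref", "alt"),
    pat_adm = pat_adm, mat_adm = mat_adm,
    pat_pre = pre_p, mat_pre = pre_m,
    fail_reason = fail_reason)
  for (st in stages) {
    truth[, paste0("pat_", st) := lv_pat[[st]]]
    truth[, paste0("mat_", st) := lv_mat[[st]]]
  }
  list(snps = snps[], truth = truth[])
}

#' Read / write the candidate-SNP table format (TSV)
#' @param snps candidate table.
#' @param path file path.
#' @export
write_snp_table <- function(snps, path) {
  data.table::fwrite(snps, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_snp_table
#' @export
read_snp_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  data.table::fread(path, sep = "\t", header = TRUE)
}
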