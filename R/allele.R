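# Parent-of-origin methylation tracking through heterozygous SNPs.
#
# Candidate SNPs (quality fields from an upstream bisulfite-aware
# genotyper) are filtered on the zygote call (>= 10 reads, base quality
# >= 5, variant confidence >= 20, heterozygote genotype quality strictly
# > 20, both alleles >= 10x) and on genotype consistency across stages;
# a surviving heterozygote whose allele set contains the homozygous
# sperm allele assigns that allele as paternal and the other as
# maternal.  Allele-linked CpG counts then give per-parent methylation
# trajectories, and the gamete-to-zygote relative demethylation level
# RDL = (pre - post)/pre (floored at 0) classifies actively
# demethylated (ADM) sites at RDL >= 0.6.

split_gt <- function(gt) strsplit(gt, "/", fixed = TRUE)

is_het <- function(gt) {
  parts <- split_gt(gt)
  vapply(parts, function(p) length(unique(p)) == 2L, logical(1))
}

is_hom <- function(gt) !is_het(gt)

#' Filter candidate heterozygous SNPs
#'
#' @param snps data.table of candidate records (see
#'   [simulate_snp_data()] for the column schema).
#' @param min_depth minimum zygote read depth.
#' @param min_base_qual minimum base quality used in calling.
#' @param min_var_conf minimum phred-scaled variant confidence.
#' @param min_geno_qual heterozygote genotype quality must strictly
#'   exceed this.
#' @param min_allele_depth both alleles must reach this depth.
#' @param allele_depth_all_stages apply the per-allele depth rule in all
#'   stages rather than the zygote only.
#' @param exclude_ct drop records whose ref/alt pair is bisulfite-
#'   confounded on the + strand duplex (C/T, or its bottom-strand image
#'   G/A).
#' @param stages stage names whose `gt_<stage>` columns are checked for
#'   genotype consistency (defaults to every `gt_` column present).
#' @return the passing subset (a data.table); the number removed by
#'   each criterion is stored in `attr(, "filter_summary")`.
#' @export
filter_candidate_snps <- function(snps, min_depth = 10,
                                  min_base_qual = 5, min_var_conf = 20,
                                  min_geno_qual = 20,
                                  min_allele_depth = 10,
                                  allele_depth_all_stages = FALSE,
                                  exclude_ct = TRUE, stages = NULL) {
  snps <- data.table::as.data.table(snps)
  gt_cols <- if (is.null(stages)) grep("^gt_", names(snps), value = TRUE)
             else paste0("gt_", stages)
  ok_depth <- snps$zygote_depth >= min_depth
  ok_bq <- snps$base_qual >= min_base_qual
  ok_conf <- snps$var_conf >= min_var_conf
  ok_gq <- snps$geno_qual > min_geno_qual       # strict
  ok_het <- is_het(snps$offspring_gt)
  ok_ad <- snps$ref_depth >= min_allele_depth &
           snps$alt_depth >= min_allele_depth
  if (allele_depth_all_stages) {
    ad_cols <- grep("_(ref|alt)_depth$", names(snps), value = TRUE)
    if (length(ad_cols))
      ok_ad <- ok_ad &
        rowSums(as.matrix(snps[, ad_cols, with = FALSE]) <
                  min_allele_depth) == 0
  }
  ok_consist <- rep(TRUE, nrow(snps))
  for (g in gt_cols) {
    norm <- function(gt) vapply(split_gt(gt), function(p)
      paste(sort(p), collapse = "/"), character(1))
    obs <- snps[[g]]
    has <- !is.na(obs) & obs != "."
    ok_consist <- ok_consist &
      (!has | norm(obs) == norm(snps$offspring_gt))
  }
  ok_ct <- rep(TRUE, nrow(snps))
  if (exclude_ct) {
    pair <- paste(pmin(snps$ref, snps$alt), pmax(snps$ref, snps$alt))
    ok_ct <- !(pair %in% c("C T", "A G"))
  }
  keep <- ok_depth & ok_bq & ok_conf & ok_gq & ok_het & ok_ad &
    ok_consist & ok_ct
  out <- snps[keep]
  data.table::setattr(out, "filter_summary", c(
    depth = sum(!ok_depth), base_qual = sum(!ok_bq),
    var_conf = sum(!ok_conf), geno_qual = sum(!ok_gq),
    not_het = sum(!ok_het), allele_depth = sum(!ok_ad),
    inconsistent = sum(!ok_consist), ct_confounded = sum(!ok_ct)))
  out
}

#' Assign parental origin of the two alleles by the sperm genotype
#'
#' The allele identical to the homozygous sperm genotype is paternal;
#' the other allele is maternal.  Records with a heterozygous sperm
#' genotype, or where neither (or both) offspring alleles match the
#' sperm base, are unassignable and excluded.
#'
#' @param snps filtered heterozygous records.
#' @return list with `assigned` (records plus `paternal_allele` /
#'   `maternal_allele`, each `"ref"` or `"alt"`) and `unassignable`
#'   (excluded records with a `reason` column).
#' @export
assign_parent_of_origin <- function(snps) {
  snps <- data.table::as.data.table(snps)
  sperm_parts <- split_gt(snps$sperm_gt)
  sperm_hom <- vapply(sperm_parts, function(p)
    length(unique(p)) == 1L, logical(1))
  sperm_allele <- vapply(sperm_parts, `[`, character(1), 1)
  pat <- rep(NA_character_, nrow(snps))
  pat[sperm_hom & sperm_allele == snps$ref] <- "ref"
  pat[sperm_hom & sperm_allele == snps$alt] <- "alt"
  reason <- rep(NA_character_, nrow(snps))
  reason[!sperm_hom] <- "sperm_heterozygous"
  reason[sperm_hom & is.na(pat)] <- "no_matching_allele"
  assigned <- snps[!is.na(pat)]
  assigned[, `:=`(paternal_allele = pat[!is.na(pat)],
                  maternal_allele = ifelse(pat[!is.na(pat)] == "ref",
                                           "alt", "ref"))]
  un <- snps[is.na(pat)]
  if (nrow(un)) un[, reason := reason[is.na(pat)]]
  list(assigned = assigned, unassignable = un)
}

allele_count_cols <- function(stage, allele, what = c("M", "U")) {
  what <- match.arg(what)
  paste0(stage, "_", allele, "_", what)
}

#' Per-parent pooled methylation levels across stages
#'
#' Pools allele-linked CpG counts over all assigned SNPs, split by
#' parental origin, for each requested stage.
#'
#' @param assigned output `assigned` of [assign_parent_of_origin()].
#' @param stages stage names (matching the count column prefixes).
#' @return data.table `stage` x `parent` with pooled `level` and
#'   `total_reads`.
#' @export
allele_methylation <- function(assigned, stages) {
  if (!nrow(assigned)) {
    warning("no assigned SNPs: empty allele trajectory")
    return(data.table::data.table(stage = character(),
                                  parent = character(),
                                  level = numeric(),
                                  total_reads = integer()))
  }
  out <- list()
  for (st in stages) {
    for (par in c("paternal", "maternal")) {
      al <- if (par == "paternal") assigned$paternal_allele
            else assigned$maternal_allele
      Mc <- ifelse(al == "ref",
                   assigned[[allele_count_cols(st, "ref", "M")]],
                   assigned[[allele_count_cols(st, "alt", "M")]])
      Uc <- ifelse(al == "ref",
                   assigned[[allele_count_cols(st, "ref", "U")]],
                   assigned[[allele_count_cols(st, "alt", "U")]])
      tot <- sum(Mc, na.rm = TRUE) + sum(Uc, na.rm = TRUE)
      out[[length(out) + 1L]] <- data.table::data.table(
        stage = st, parent = par,
        level = if (tot > 0) sum(Mc, na.rm = TRUE) / tot else NA_real_,
        total_reads = tot)
    }
  }
  data.table::rbindlist(out)
}

#' Relative demethylation level
#'
#' `RDL = (level_pre - level_post) / level_pre`, floored at 0 (a gain of
#' methylation is not negative demethylation).  Defined only for
#' `level_pre > 0`; other entries return `NA`.
#'
#' @param level_pre methylation level in the gamete.
#' @param level_post methylation level in the zygote.
#' @return numeric vector of RDL values in \[0, 1\].
#' @export
compute_rdl <- function(level_pre, level_post) {
  ifelse(!is.na(level_pre) & level_pre > 0,
         pmax(0, (level_pre - level_post) / level_pre),
         NA_real_)
}

#' Per-site gamete-to-zygote RDL records
#'
#' For each assigned SNP the paternal pre-level is the paternal allele's
#' level in sperm and the maternal pre-level the maternal allele's level
#' in the oocyte; post-levels are the corresponding allele levels in the
#' zygote.
#'
#' @param assigned output `assigned` of [assign_parent_of_origin()].
#' @param gamete_stage named stages of the gametes,
#'   `c(paternal = "sperm", maternal = "oocyte")`.
#' @param zygote_stage zygote stage name.
#' @return data.table `chrom`, `pos`, `parent`, `level_pre`,
#'   `level_post`, `rdl`.
#' @export
rdl_records <- function(assigned,
                        gamete_stage = c(paternal = "sperm",
                                         maternal = "oocyte"),
                        zygote_stage = "zygote") {
  out <- list()
  for (par in c("paternal", "maternal")) {
    al <- if (par == "paternal") assigned$paternal_allele
          else assigned$maternal_allele
    g <- gamete_stage[[par]]
    lv <- function(st) {
      M <- ifelse(al == "ref",
                  assigned[[allele_count_cols(st, "ref", "M")]],
                  assigned[[allele_count_cols(st, "alt", "M")]])
      U <- ifelse(al == "ref",
                  assigned[[allele_count_cols(st, "ref", "U")]],
                  assigned[[allele_count_cols(st, "alt", "U")]])
      site_level(M, U)
    }
    out[[par]] <- data.table::data.table(
      chrom = assigned$chrom, pos = assigned$pos, parent = par,
      level_pre = lv(g), level_post = lv(zygote_stage))
  }
  res <- data.table::rbindlist(out)
  res[, rdl := compute_rdl(level_pre, level_post)]
  res[]
}

#' Classify actively demethylated (ADM) sites
#'
#' A site is ADM when its gamete-to-zygote RDL is at least `threshold`
#' (the zygote precedes any cell division, so the loss is
#' replication-independent).
#'
#' @param records output of [rdl_records()].
#' @param threshold RDL cut-off (inclusive).
#' @return `records` with an `is_adm` column.
#' @export
classify_adm_sites <- function(records, threshold = 0.6) {
  records <- data.table::copy(records)
  records[, is_adm := !is.na(rdl) & rdl >= threshold]
  records[]
}

#' Genomic feature distribution of ADM sites
#'
#' @param adm classified records (rows with `is_adm = TRUE` are used).
#' @param annotation a `genome_annotation`.
#' @return data.table `parent` x `feature` with counts and fractions
#'   (fractions sum to 1 within a parent).
#' @export
adm_genomic_distribution <- function(adm, annotation) {
  adm <- adm[is_adm == TRUE]
  if (!nrow(adm))
    return(data.table::data.table(parent = character(),
                                  feature = character(),
                                  n = integer(), fraction = numeric()))
  adm <- data.table::copy(adm)
  adm[, feature := label_position(chrom, pos, annotation)]
  out <- adm[, .(n = .N), by = .(parent, feature)]
  out[, fraction := n / sum(n), by = parent]
  data.table::setkeyv(out, c("parent", "feature"))
  out[]
}
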