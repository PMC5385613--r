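# Pairwise sliding-window DMR identification.
#
# Procedure: (1) candidate sites are CpGs covered >= 5x in both samples
# whose two-sided Fisher (or chi-square) test on the 2x2 methylated/
# unmethylated table gives P < 0.05, each carrying a direction from the
# level comparison; (2) candidates are merged left-to-right into maximal
# runs while consecutive candidates are <= 300 bp apart and share the
# same direction, and runs with fewer than 10 candidates are dropped;
# (3) each surviving run is re-tested by a Fisher test on its pooled
# counts and kept only when the region p-value is <= 0.01 and the
# absolute difference of its pooled mean levels is >= 0.3.

#' Per-site differential methylation test
#'
#' @param a_meth,a_unmeth,b_meth,b_unmeth counts for samples A and B
#'   (vectorised).
#' @param method `"fisher"` (exact, default) or `"chi2"` (expected
#'   cells >= 5, exact fallback below that).
#' @param site_alpha significance threshold defining a directional
#'   candidate.
#' @return data.table with `level_a`, `level_b`, `p_value`,
#'   `direction` (`hyper_in_a`, `hypo_in_a`, `none`).
#' @export
site_test <- function(a_meth, a_unmeth, b_meth, b_unmeth,
                      method = c("fisher", "chi2"), site_alpha = 0.05) {
  method <- match.arg(method)
  p <- if (method == "fisher")
    fisher_test_2x2(a_meth, a_unmeth, b_meth, b_unmeth)
  else
    chisq_test_2x2(a_meth, a_unmeth, b_meth, b_unmeth)
  la <- site_level(a_meth, a_unmeth)
  lb <- site_level(b_meth, b_unmeth)
  dir <- rep("none", length(p))
  sig <- p < site_alpha
  dir[sig & la > lb] <- "hyper_in_a"
  dir[sig & la < lb] <- "hypo_in_a"
  data.table::data.table(level_a = la, level_b = lb, p_value = p,
                         direction = dir)
}

#' Candidate differentially methylated sites for a sample pair
#'
#' Sites below `min_depth` in either sample are excluded before testing
#' (not tested and failed).
#'
#' @param x a `site_table`.
#' @param pair character vector `c(sample_a, sample_b)`.
#' @param min_depth candidate-site depth requirement in both samples.
#' @param site_alpha per-site significance threshold.
#' @param method see [site_test()].
#' @param context restrict to a methylation context.
#' @return position-ordered data.table of significant directional sites
#'   with counts, levels, p-values and directions.
#' @export
find_candidate_sites <- function(x, pair, min_depth = 5,
                                 site_alpha = 0.05, method = "fisher",
                                 context = "CpG") {
  stopifnot(length(pair) == 2, all(pair %in% st_samples(x)))
  am <- paste0(pair[1], "_M"); au <- paste0(pair[1], "_U")
  bm <- paste0(pair[2], "_M"); bu <- paste0(pair[2], "_U")
  sub <- x[x$context == context]
  da <- sub[[am]] + sub[[au]]; db <- sub[[bm]] + sub[[bu]]
  keep <- !is.na(da) & !is.na(db) & da >= min_depth & db >= min_depth
  sub <- sub[keep]
  if (!nrow(sub))
    return(data.table::data.table(
      chrom = character(), pos = integer(), a_meth = integer(),
      a_unmeth = integer(), b_meth = integer(), b_unmeth = integer(),
      level_a = numeric(), level_b = numeric(), p_value = numeric(),
      direction = character()))
  res <- site_test(sub[[am]], sub[[au]], sub[[bm]], sub[[bu]],
                   method = method, site_alpha = site_alpha)
  out <- data.table::data.table(
    chrom = sub$chrom, pos = sub$pos,
    a_meth = sub[[am]], a_unmeth = sub[[au]],
    b_meth = sub[[bm]], b_unmeth = sub[[bu]])
  out <- cbind(out, res)
  out <- out[direction != "none"]
  data.table::setkeyv(out, c("chrom", "pos"))
  out[]
}

#' Merge candidate sites into maximal same-direction runs
#'
#' A run extends greedily left to right while each next candidate shares
#' the run's direction and lies within `max_gap` of the previous one; a
#' direction change or larger gap terminates the run and the next
#' candidate seeds a new one.  Runs with fewer than `min_sites`
#' candidates are discarded.
#'
#' @param cand output of [find_candidate_sites()].
#' @param max_gap maximum distance between neighbouring candidates (bp).
#' @param min_sites minimum candidates per run.
#' @return `cand` rows belonging to retained runs, with a `run_id`
#'   column.
#' @export
merge_candidates <- function(cand, max_gap = 300L, min_sites = 10L) {
  if (!nrow(cand)) return(cbind(cand, run_id = integer()))
  cand <- data.table::copy(cand)
  data.table::setkeyv(cand, c("chrom", "pos"))
  cand[, run_id := {
    newrun <- c(TRUE, diff(pos) > max_gap |
                  direction[-1] != direction[-.N])
    cumsum(newrun)
  }, by = chrom]
  cand[, run_id := cumsum(c(TRUE, diff(run_id) != 0 |
                              chrom[-1] != chrom[-.N]))]
  sizes <- cand[, .N, by = run_id]
  keep <- sizes[N >= min_sites, run_id]
  out <- cand[run_id %in% keep]
  data.table::setkeyv(out, c("chrom", "pos"))
  out[]
}

#' Region-level test of a candidate run
#'
#' Fisher test on the counts pooled over the run's candidate sites;
#' emitted as a DMR only when the region p-value is at most
#' `region_alpha` and the absolute difference of the pooled mean levels
#' is at least `min_diff`.
#'
#' @param run data.table of one run's candidate rows.
#' @param region_alpha region p-value threshold.
#' @param min_diff minimum absolute pooled level difference.
#' @return one-row data.table (the DMR) or `NULL` when rejected.
#' @export
region_test <- function(run, region_alpha = 0.01, min_diff = 0.3) {
  am <- sum(run$a_meth); au <- sum(run$a_unmeth)
  bm <- sum(run$b_meth); bu <- sum(run$b_unmeth)
  la <- region_level(run$a_meth, run$a_unmeth)
  lb <- region_level(run$b_meth, run$b_unmeth)
  p <- fisher_test_2x2(am, au, bm, bu)
  diff <- la - lb
  if (p > region_alpha || abs(diff) < min_diff) return(NULL)
  data.table::data.table(
    chrom = run$chrom[1],
    start = run$pos[1] - 1L,          # BED: 0-based half-open
    end = run$pos[nrow(run)],
    n_sites = nrow(run),
    direction = run$direction[1],
    region_p = p,
    mean_diff = diff,
    level_a = la, level_b = lb,
    sites = list(run$pos))
}

#' Call differentially methylated regions between two samples
#'
#' Composition of [find_candidate_sites()], [merge_candidates()] and
#' [region_test()], per chromosome.  Output regions are position-sorted
#' and non-overlapping.
#'
#' @inheritParams find_candidate_sites
#' @inheritParams merge_candidates
#' @inheritParams region_test
#' @param break_at_nonsig when `TRUE`, a depth-qualified but
#'   non-significant CpG lying between two candidates also terminates a
#'   run (the default keeps the study's literal rule: only candidate
#'   sites count).
#' @return data.table of DMRs (`chrom`, `start`, `end` 0-based
#'   half-open, `n_sites`, `direction`, `region_p`, `mean_diff`,
#'   `level_a`, `level_b`, `sites` list-column of candidate positions).
#' @export
call_dmrs <- function(x, pair, min_depth = 5, site_alpha = 0.05,
                      max_gap = 300L, min_sites = 10L,
                      region_alpha = 0.01, min_diff = 0.3,
                      method = "fisher", break_at_nonsig = FALSE,
                      context = "CpG") {
  cand <- find_candidate_sites(x, pair, min_depth = min_depth,
                               site_alpha = site_alpha, method = method,
                               context = context)
  if (break_at_nonsig && nrow(cand)) {
    # positions of depth-qualified tested sites that were not candidates
    am <- paste0(pair[1], "_M"); au <- paste0(pair[1], "_U")
    bm <- paste0(pair[2], "_M"); bu <- paste0(pair[2], "_U")
    sub <- x[x$context == context]
    da <- sub[[am]] + sub[[au]]; db <- sub[[bm]] + sub[[bu]]
    tested <- sub[!is.na(da) & !is.na(db) & da >= min_depth &
                    db >= min_depth, .(chrom, pos)]
    nonsig <- tested[!cand[, .(chrom, pos)], on = c("chrom", "pos")]
    cand <- break_runs_at(cand, nonsig)
  }
  runs <- merge_candidates(cand, max_gap = max_gap,
                           min_sites = min_sites)
  if (!nrow(runs)) return(empty_dmrs())
  if (break_at_nonsig)
    runs[, direction := sub("#.*$", "", direction)]
  out <- runs[, region_test(.SD, region_alpha = region_alpha,
                            min_diff = min_diff),
              by = run_id]
  if (!nrow(out)) return(empty_dmrs())
  out[, run_id := NULL]
  data.table::setkeyv(out, c("chrom", "start"))
  out[]
}

empty_dmrs <- function() {
  data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    n_sites = integer(), direction = character(), region_p = numeric(),
    mean_diff = numeric(), level_a = numeric(), level_b = numeric(),
    sites = list())
}

break_runs_at <- function(cand, nonsig) {
  # marks candidates so that an intervening non-significant site starts
  # a new run: encode by shifting positions into separate "segments"
  if (!nrow(nonsig)) return(cand)
  cand <- data.table::copy(cand)
  cand[, segment := {
    brk <- nonsig[chrom == .BY$chrom, pos]
    findInterval(pos, sort(brk))
  }, by = chrom]
  # a segment change acts like an oversized gap: fold it into direction
  cand[, direction := paste0(direction, "#", segment)]
  cand[, segment := NULL]
  cand
}

#' The study's seven stage-pair comparisons
#'
#' Labels a-g: sperm-oocyte, sperm-zygote, oocyte-zygote, zygote-2cell,
#' 2cell-8cell, 8cell-morula, morula-ICM.
#'
#' @param stages the seven ordered stage names.
#' @return named list of sample pairs.
#' @export
default_stage_pairs <- function(stages = c("sperm", "oocyte", "zygote",
                                           "twocell", "eightcell",
                                           "morula", "icm")) {
  stopifnot(length(stages) == 7)
  list(a = stages[c(1, 2)], b = stages[c(1, 3)], c = stages[c(2, 3)],
       d = stages[c(3, 4)], e = stages[c(4, 5)], f = stages[c(5, 6)],
       g = stages[c(6, 7)])
}

#' Exhaustive brute-force DMR enumeration (validation oracle)
#'
#' Independent quadratic reference: enumerates every window of
#' candidate sites, keeps windows that are structurally valid (same
#' direction throughout, all neighbour gaps within `max_gap`, at least
#' `min_sites` sites) and maximal (no valid extension on either side),
#' then applies the pooled region test.  Intended for equivalence
#' checks against [call_dmrs()] on small chromosomes.
#'
#' @inheritParams call_dmrs
#' @return data.table with the same columns as [call_dmrs()].
#' @export
enumerate_dmrs_bruteforce <- function(x, pair, min_depth = 5,
                                      site_alpha = 0.05,
                                      max_gap = 300L, min_sites = 10L,
                                      region_alpha = 0.01,
                                      min_diff = 0.3,
                                      method = "fisher") {
  cand <- find_candidate_sites(x, pair, min_depth = min_depth,
                               site_alpha = site_alpha, method = method)
  res <- list()
  for (ch in unique(cand$chrom)) {
    cc <- cand[chrom == ch]
    n <- nrow(cc)
    valid <- function(i, j) {
      if (j - i + 1L < 2L) return(TRUE)
      all(diff(cc$pos[i:j]) <= max_gap) &&
        length(unique(cc$direction[i:j])) == 1L
    }
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (j - i + 1L < min_sites) next
        if (!valid(i, j)) next
        left_ext <- i > 1L && valid(i - 1L, j)
        right_ext <- j < n && valid(i, j + 1L)
        if (left_ext || right_ext) next    # not maximal
        dmr <- region_test(cc[i:j], region_alpha = region_alpha,
                           min_diff = min_diff)
        if (!is.null(dmr)) res[[length(res) + 1L]] <- dmr
      }
    }
  }
  if (!length(res)) return(empty_dmrs())
  out <- data.table::rbindlist(res)
  data.table::setkeyv(out, c("chrom", "start"))
  out[]
}

#' Independent structural validation of emitted DMRs
#'
#' Re-checks, from the raw count table, each DMR's five invariants:
#' at least `min_sites` candidate sites, neighbour gaps within
#' `max_gap`, a single shared direction, region p-value at most
#' `region_alpha`, and absolute pooled level difference at least
#' `min_diff`.
#'
#' @param dmrs output of [call_dmrs()].
#' @param x,pair the table and sample pair the DMRs were called on.
#' @inheritParams call_dmrs
#' @return logical vector, one entry per DMR.
#' @export
validate_dmrs <- function(dmrs, x, pair, min_depth = 5,
                          site_alpha = 0.05, max_gap = 300L,
                          min_sites = 10L, region_alpha = 0.01,
                          min_diff = 0.3) {
  if (!nrow(dmrs)) return(logical())
  am <- paste0(pair[1], "_M"); au <- paste0(pair[1], "_U")
  bm <- paste0(pair[2], "_M"); bu <- paste0(pair[2], "_U")
  vapply(seq_len(nrow(dmrs)), function(i) {
    ps <- dmrs$sites[[i]]
    if (length(ps) < min_sites) return(FALSE)
    if (any(diff(ps) > max_gap)) return(FALSE)
    sub <- x[.(dmrs$chrom[i], ps), on = c("chrom", "pos")]
    if (any(is.na(sub$pos))) return(FALSE)
    st <- site_test(sub[[am]], sub[[au]], sub[[bm]], sub[[bu]],
                    site_alpha = site_alpha)
    if (any(st$direction == "none")) return(FALSE)
    if (length(unique(st$direction)) != 1L) return(FALSE)
    if (unique(st$direction) != dmrs$direction[i]) return(FALSE)
    p <- fisher_test_2x2(sum(sub[[am]]), sum(sub[[au]]),
                         sum(sub[[bm]]), sum(sub[[bu]]))
    if (p > region_alpha) return(FALSE)
    la <- region_level(sub[[am]], sub[[au]])
    lb <- region_level(sub[[bm]], sub[[bu]])
    abs(la - lb) >= min_diff
  }, logical(1))
}

#' Annotate DMRs by genomic feature
#'
#' Midpoint overlap with precedence promoter > 5'UTR > exon > intron >
#' 3'UTR > CGI > repeat > intergenic.
#'
#' @param dmrs output of [call_dmrs()].
#' @param annotation a `genome_annotation`.
#' @return `dmrs` with an `annotation` column.
#' @export
annotate_dmrs <- function(dmrs, annotation) {
  if (!nrow(dmrs)) return(cbind(dmrs, annotation = character()))
  mid <- (dmrs$start + dmrs$end) %/% 2L + 1L   # back to 1-based
  dmrs <- data.table::copy(dmrs)
  dmrs[, annotation := label_position(chrom, mid, annotation)]
  dmrs[]
}

#' Promoter methylation gain/loss between two stages
#'
#' Per promoter, the pooled level difference from stage A to stage B;
#' promoters covered in both stages are classified `gained` when the
#' level rises by at least `min_diff`, `lost` when it falls by at least
#' `min_diff`.
#'
#' @param x a `site_table`.
#' @param promoters `GRanges` with a `gene_id` column.
#' @param pair `c(stage_a, stage_b)`.
#' @param min_diff classification threshold.
#' @return list with `gained`, `lost` (gene ids), and `unclassified`
#'   (uncovered promoters).
#' @export
promoter_gain_loss <- function(x, promoters, pair, min_diff = 0.3) {
  stopifnot(length(pair) == 2)
  sites <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(sites, promoters))
  am <- paste0(pair[1], "_M"); au <- paste0(pair[1], "_U")
  bm <- paste0(pair[2], "_M"); bu <- paste0(pair[2], "_U")
  gained <- character(); lost <- character(); uncl <- character()
  for (j in seq_along(promoters)) {
    rows <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]
    gid <- promoters$gene_id[j]
    if (!length(rows)) { uncl <- c(uncl, gid); next }
    sub <- x[rows]
    la <- region_level(sub[[am]], sub[[au]])
    lb <- region_level(sub[[bm]], sub[[bu]])
    if (is.na(la) || is.na(lb)) { uncl <- c(uncl, gid); next }
    d <- lb - la
    if (d >= min_diff) gained <- c(gained, gid)
    else if (d <= -min_diff) lost <- c(lost, gid)
  }
  list(gained = gained, lost = lost, unclassified = uncl)
}

#' Write DMRs as BED6+ with auxiliary columns
#'
#' Name = direction, score = -10 log10(region p) capped at 1000, then
#' `n_sites`, `mean_diff`, `region_p`, `annotation`.
#'
#' @param dmrs (annotated) DMR table.
#' @param path output file.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.table::data.table(
    chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    name = dmrs$direction,
    score = pmin(1000, round(-10 * log10(pmax(dmrs$region_p, 1e-100)))),
    strand = ".",
    n_sites = dmrs$n_sites,
    mean_diff = round(dmrs$mean_diff, 4),
    region_p = signif(dmrs$region_p, 4),
    annotation = if ("annotation" %in% names(dmrs)) dmrs$annotation
                 else ".")
  write_bed_table(bed, path)
}
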