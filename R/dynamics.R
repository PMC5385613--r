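# Cross-stage dynamics: gamete-specific hypermethylated site sets and
# their developmental tracing, CGI-level k-means clustering, stage-level
# hierarchical clustering, and chromosome-subset (X vs autosome)
# trajectories.

#' Gamete-specific hypermethylated CpG sites
#'
#' Sperm-specific sites have level strictly above `hyper` in sperm and
#' strictly below `hypo` in oocytes (and vice versa); both gametes must
#' reach `min_depth` at the site.
#'
#' @param x a `site_table`.
#' @param gametes `c(sperm_sample, oocyte_sample)`.
#' @param hyper,hypo defining thresholds (strict inequalities).
#' @param min_depth coverage requirement in both gametes.
#' @return list of two data.tables (`sperm_specific`, `oocyte_specific`)
#'   with `chrom`, `pos` and the two gamete levels.
#' @export
gamete_specific_sites <- function(x, gametes = c("sperm", "oocyte"),
                                  hyper = 0.75, hypo = 0.25,
                                  min_depth = 10) {
  sm <- paste0(gametes[1], "_M"); su <- paste0(gametes[1], "_U")
  om <- paste0(gametes[2], "_M"); ou <- paste0(gametes[2], "_U")
  ds <- x[[sm]] + x[[su]]; do <- x[[om]] + x[[ou]]
  covered <- !is.na(ds) & !is.na(do) & ds >= min_depth & do >= min_depth
  ls <- site_level(x[[sm]], x[[su]])
  lo <- site_level(x[[om]], x[[ou]])
  base <- data.table::data.table(chrom = x$chrom, pos = x$pos,
                                 sperm_level = ls, oocyte_level = lo)
  list(
    sperm_specific = base[covered & ls > hyper & lo < hypo],
    oocyte_specific = base[covered & lo > hyper & ls < hypo])
}

#' Trace a site set across stages
#'
#' Box-plot style distribution summaries (quartiles and mean of
#' per-site levels) per stage over the set's covered sites.
#'
#' @param sites data.table with `chrom`, `pos` (e.g. one element of
#'   [gamete_specific_sites()]).
#' @param x a `site_table`.
#' @return data.table `sample_id`, `n`, `mean`, `q25`, `median`, `q75`.
#' @export
trace_sites <- function(sites, x) {
  samples <- st_samples(x)
  if (!nrow(sites))
    return(data.table::data.table(sample_id = character(), n = integer(),
                                  mean = numeric(), q25 = numeric(),
                                  median = numeric(), q75 = numeric()))
  sub <- x[sites[, .(chrom, pos)], on = c("chrom", "pos"), nomatch = NULL]
  data.table::rbindlist(lapply(samples, function(s) {
    lv <- site_level(sub[[paste0(s, "_M")]], sub[[paste0(s, "_U")]])
    lv <- lv[!is.na(lv)]
    data.table::data.table(
      sample_id = s, n = length(lv),
      mean = mean(lv), q25 = unname(quantile(lv, 0.25)),
      median = unname(median(lv)), q75 = unname(quantile(lv, 0.75)))
  }))
}

#' CGI-by-sample pooled methylation matrix
#'
#' Rows with any uncovered cell are dropped; the number dropped is
#' reported in `attr(, "n_dropped")`.
#'
#' @param x a `site_table`.
#' @param cgis `GRanges` of CpG islands.
#' @return numeric matrix CGIs x samples.
#' @export
cgi_matrix <- function(x, cgis) {
  samples <- st_samples(x)
  sites <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos))
  ov <- GenomicRanges::findOverlaps(sites, cgis)
  mat <- matrix(NA_real_, length(cgis), length(samples),
                dimnames = list(
                  paste0(GenomicRanges::seqnames(cgis), ":",
                         GenomicRanges::start(cgis), "-",
                         GenomicRanges::end(cgis)),
                  samples))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  for (j in seq_along(cgis)) {
    rows <- qh[sh == j]
    if (!length(rows)) next
    sub <- x[rows]
    for (s in seq_along(samples)) {
      mat[j, s] <- region_level(sub[[paste0(samples[s], "_M")]],
                                sub[[paste0(samples[s], "_U")]])
    }
  }
  keep <- rowSums(is.na(mat)) == 0
  out <- mat[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Seeded k-means clustering of a level matrix
#'
#' Deterministic under a fixed seed; the within-cluster sum of squares
#' (inertia) is returned alongside the assignment.
#'
#' @param mat numeric matrix (items x samples).
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param nstart random restarts.
#' @return a `cluster_result` list: `assignment` (named), `centers`,
#'   `inertia`, `k`, `seed`.
#' @export
kmeans_cluster <- function(mat, k = 6L, seed = 1L, nstart = 10L) {
  stopifnot(nrow(mat) >= k)
  if (nrow(mat) == k) {   # one item per cluster; stats::kmeans needs k < n
    return(structure(list(
      assignment = setNames(seq_len(k), rownames(mat)),
      centers = mat, inertia = 0, k = k, seed = seed),
      class = "cluster_result"))
  }
  set.seed(seed)
  km <- kmeans(mat, centers = k, nstart = nstart, iter.max = 100L)
  structure(list(assignment = setNames(km$cluster, rownames(mat)),
                 centers = km$centers, inertia = km$tot.withinss,
                 k = k, seed = seed),
            class = "cluster_result")
}

#' Hierarchical clustering of stages on shared covered sites
#'
#' Stage-level agglomerative clustering of per-site level vectors over
#' sites covered at `min_depth` in every sample; deterministic.
#'
#' @param x a `site_table`.
#' @param context `"CpG"` or `"CpH"`.
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param linkage agglomeration method for [stats::hclust()].
#' @param min_depth per-sample coverage requirement.
#' @return list with `hclust`, `merge_order` (stage labels in merge
#'   sequence), `metric`, `linkage`, `n_sites`.
#' @export
hierarchical_cluster_stages <- function(x, context = "CpG",
                                        metric = c("euclidean",
                                                   "correlation"),
                                        linkage = "average",
                                        min_depth = 10) {
  metric <- match.arg(metric)
  samples <- st_samples(x)
  keep <- if (context == "CpG") x$context == "CpG"
          else x$context %in% c("CHG", "CHH")
  sub <- filter_by_coverage(x[keep], min_depth, "all_samples")
  mat <- vapply(samples, function(s)
    site_level(sub[[paste0(s, "_M")]], sub[[paste0(s, "_U")]]),
    numeric(nrow(sub)))
  d <- if (metric == "euclidean") dist(t(mat))
       else as.dist(1 - cor(mat))
  hc <- hclust(d, method = linkage)
  merge_order <- apply(hc$merge, 1, function(m) {
    lab <- vapply(m, function(e)
      if (e < 0) samples[-e] else paste0("node", e), character(1))
    paste(lab, collapse = "+")
  })
  list(hclust = hc, merge_order = merge_order, metric = metric,
       linkage = linkage, n_sites = nrow(sub))
}

#' Write a stage dendrogram in Newick format
#' @param hc an `hclust` object (or the list from
#'   [hierarchical_cluster_stages()]).
#' @param path output file.
#' @export
write_newick <- function(hc, path) {
  if (is.list(hc) && !inherits(hc, "hclust")) hc <- hc$hclust
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Pooled trajectories for a chromosome subset vs its complement
#'
#' @param x a `site_table`.
#' @param chroms chromosome subset (e.g. `"chrX"`).
#' @return data.table `sample_id`, `subset_level`, `complement_level`.
#' @export
chromosome_trajectory <- function(x, chroms) {
  samples <- st_samples(x)
  in_sub <- x$chrom %in% chroms
  if (!any(in_sub)) stop("chromosome subset matches no sites")
  if (all(in_sub))
    stop("chromosome subset covers every site: complement is empty")
  sub <- x[in_sub]; comp <- x[!in_sub]
  data.table::rbindlist(lapply(samples, function(s) {
    data.table::data.table(
      sample_id = s,
      subset_level = region_level(sub[[paste0(s, "_M")]],
                                  sub[[paste0(s, "_U")]]),
      complement_level = region_level(comp[[paste0(s, "_M")]],
                                      comp[[paste0(s, "_U")]]))
  }))
}
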