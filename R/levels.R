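# Methylation-level quantification and binomial methylated-cytosine
# calling.  A site level is the fraction of reads reporting 'C' among
# reads reporting 'C' or 'T'; a region level pools reads over all covered
# sites (read-weighted) rather than averaging per-site fractions.

#' Per-site methylation level
#'
#' `meth / (meth + unmeth)`.  A site with zero total coverage has an
#' undefined level and returns `NA` (never silently 0).
#'
#' @param meth,unmeth non-negative read counts (vectorised).
#' @return numeric vector in \[0, 1\] with `NA` for uncovered sites.
#' @export
site_level <- function(meth, unmeth) {
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  tot <- meth + unmeth
  ifelse(!is.na(tot) & tot > 0, meth / tot, NA_real_)
}

#' Pooled (read-weighted) methylation level of a region
#'
#' The average percentage methylation over a genomic region is the pooled
#' fraction sum(meth) / sum(meth + unmeth) over its covered sites, i.e.
#' sites contribute in proportion to their read depth.  An unweighted
#' mean of per-site levels is available for cross-checks.
#'
#' @param meth,unmeth read-count vectors over the region's sites.
#' @param weighted pool reads (default) or average per-site levels.
#' @return a single level in \[0, 1\], or `NA` when no site is covered.
#' @export
region_level <- function(meth, unmeth, weighted = TRUE) {
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  if (weighted) {
    tot <- sum(meth, na.rm = TRUE) + sum(unmeth, na.rm = TRUE)
    if (tot == 0) return(NA_real_)
    sum(meth, na.rm = TRUE) / tot
  } else {
    lv <- site_level(meth, unmeth)
    if (all(is.na(lv))) return(NA_real_)
    mean(lv, na.rm = TRUE)
  }
}

#' Estimate the bisulfite error rate from an unmethylated lambda spike-in
#'
#' The phage spike-in is fully unmethylated, so its pooled methylated-read
#' fraction estimates the combined non-conversion + sequencing error rate
#' used as the null rate of the binomial caller.
#'
#' @param lambda_table a `site_table` of spike-in cytosines.
#' @return an `error_rate` object with fields `rate`, `n_sites`,
#'   `total_reads`.
#' @export
estimate_error_rate <- function(lambda_table) {
  samples <- st_samples(lambda_table)
  if (nrow(lambda_table) == 0L)
    stop("no spike-in sites: cannot estimate the error rate")
  M <- sum(as.matrix(lambda_table[, m_cols(samples), with = FALSE]),
           na.rm = TRUE)
  U <- sum(as.matrix(lambda_table[, u_cols(samples), with = FALSE]),
           na.rm = TRUE)
  if (M + U == 0) stop("spike-in table has zero total reads")
  structure(list(rate = M / (M + U), n_sites = nrow(lambda_table),
                 total_reads = M + U),
            class = "error_rate")
}

#' @export
print.error_rate <- function(x, ...) {
  cat(sprintf("bisulfite error rate: %.5f (%d sites, %d reads)\n",
              x$rate, x$n_sites, x$total_reads))
  invisible(x)
}

#' Binomial methylated-cytosine calling
#'
#' For each covered cytosine, the p-value is the upper-tail binomial
#' probability P(X >= meth | n = meth + unmeth, p = error rate): the
#' chance of observing at least that many methylated reads if the site
#' were truly unmethylated and only conversion/sequencing error produced
#' 'C' reads.  Calls are made after Benjamini-Hochberg correction at
#' `alpha`.
#'
#' @param meth,unmeth read counts (vectorised); totals must be positive.
#' @param error_rate an `error_rate` object or a plain rate in \[0, 0.5).
#' @param alpha FDR threshold for calling.
#' @param correction multiple-testing correction passed to
#'   [stats::p.adjust()] (default `"BH"`; `"none"` disables).
#' @return data.table with `p_value`, `q_value`, `called`.
#' @export
call_methylated <- function(meth, unmeth, error_rate, alpha = 0.01,
                            correction = "BH") {
  rate <- if (inherits(error_rate, "error_rate")) error_rate$rate
          else as.numeric(error_rate)
  if (rate >= 0.5)
    stop("error rate >= 0.5: bisulfite conversion calibration failed")
  if (rate < 0) stop("error rate must be non-negative")
  n <- meth + unmeth
  if (any(n <= 0)) stop("call_methylated requires positive coverage")
  p <- pbinom(meth - 1L, n, rate, lower.tail = FALSE)
  q <- p.adjust(p, method = correction)
  data.table::data.table(p_value = p, q_value = q,
                         called = q <= alpha)
}

#' Pooled per-stage methylation trajectory
#'
#' Region level over all retained sites of a context, per sample, in the
#' table's sample (stage) order.
#'
#' @param x a `site_table`.
#' @param context `"CpG"` or `"CpH"` (CHG + CHH).
#' @return data.table with `sample_id` and `level`.
#' @export
stage_trajectory <- function(x, context = c("CpG", "CpH")) {
  context <- match.arg(context)
  keep <- if (context == "CpG") x$context == "CpG"
          else x$context %in% c("CHG", "CHH")
  sub <- x[keep]
  samples <- st_samples(x)
  lv <- vapply(samples, function(s) {
    region_level(sub[[paste0(s, "_M")]], sub[[paste0(s, "_U")]])
  }, numeric(1))
  data.table::data.table(sample_id = samples, level = unname(lv))
}

#' Pooled methylation level in fixed genomic windows
#'
#' Half-open windows tiled from the chromosome start; the last window is
#' truncated at the chromosome end.  Windows without covered sites carry
#' `NA`, never 0.
#'
#' @param x a `site_table`.
#' @param seqlengths named vector of chromosome lengths (bases).
#' @param window window width in bases (default 500 kb).
#' @return data.table with `chrom`, `window_start` (0-based),
#'   `window_end`, and one level column per sample.
#' @export
window_means <- function(x, seqlengths, window = 500000L) {
  samples <- st_samples(x)
  grid <- data.table::rbindlist(lapply(names(seqlengths), function(ch) {
    starts <- seq(0L, max(0L, seqlengths[[ch]] - 1L), by = window)
    data.table::data.table(chrom = ch, window_start = starts,
                           window_end = pmin(starts + window,
                                             seqlengths[[ch]]))
  }))
  xx <- data.table::copy(x)[, window_start := ((pos - 1L) %/% window) * window]
  agg <- xx[, {
    out <- lapply(samples, function(s)
      region_level(.SD[[paste0(s, "_M")]], .SD[[paste0(s, "_U")]]))
    setNames(out, samples)
  }, by = .(chrom, window_start)]
  out <- merge(grid, agg, by = c("chrom", "window_start"), all.x = TRUE)
  data.table::setkeyv(out, c("chrom", "window_start"))
  out[]
}

#' Pooled methylation level over annotated feature sets
#'
#' @param x a `site_table`.
#' @param features a named list of `GRanges` (e.g. exon, intron, CGI) or
#'   a single `GRanges`.
#' @return data.table `feature` x `sample_id` with pooled `level` and the
#'   number of covered sites; features with no covered site report `NA`.
#' @export
feature_profile <- function(x, features) {
  if (inherits(features, "GRanges")) features <- list(feature = features)
  samples <- st_samples(x)
  sites <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos))
  data.table::rbindlist(lapply(names(features), function(f) {
    hit <- unique(S4Vectors::queryHits(suppressWarnings(
      GenomicRanges::findOverlaps(sites, features[[f]]))))
    sub <- x[hit]
    data.table::rbindlist(lapply(samples, function(s) {
      m <- sub[[paste0(s, "_M")]]; u <- sub[[paste0(s, "_U")]]
      data.table::data.table(
        feature = f, sample_id = s,
        level = if (nrow(sub)) region_level(m, u) else NA_real_,
        n_sites = if (nrow(sub)) sum(!is.na(m + u) & (m + u) > 0) else 0L)
    }))
  }))
}

#' Strand-aware metagene profile around transcription start sites
#'
#' Sites within `flank` bases of a TSS are assigned to `n_bins` equal
#' bins oriented 5' to 3' along the gene, and pooled per bin per sample.
#'
#' @param x a `site_table`.
#' @param genes `GRanges` of gene models with strand.
#' @param flank half-width of the window around each TSS (bases).
#' @param n_bins number of bins across the 2 x `flank` window.
#' @return data.table with `bin`, `offset_mid` (bases relative to TSS,
#'   negative = upstream), `sample_id`, `level`.
#' @export
tss_profile <- function(x, genes, flank = 2000L, n_bins = 20L) {
  samples <- st_samples(x)
  tss <- ifelse(as.character(GenomicRanges::strand(genes)) == "-",
                GenomicRanges::end(genes), GenomicRanges::start(genes))
  gch <- as.character(GenomicRanges::seqnames(genes))
  neg <- as.character(GenomicRanges::strand(genes)) == "-"
  pieces <- lapply(seq_along(tss), function(i) {
    sub <- x[chrom == gch[i] & pos >= tss[i] - flank & pos < tss[i] + flank]
    if (!nrow(sub)) return(NULL)
    rel <- if (neg[i]) tss[i] - sub$pos else sub$pos - tss[i]
    sub <- sub[rel >= -flank & rel < flank]
    rel <- rel[rel >= -flank & rel < flank]
    cbind(sub, bin = as.integer(floor((rel + flank) / (2 * flank / n_bins))))
  })
  all <- data.table::rbindlist(pieces)
  if (!nrow(all))
    return(data.table::data.table(bin = integer(), offset_mid = numeric(),
                                  sample_id = character(), level = numeric()))
  out <- data.table::rbindlist(lapply(samples, function(s) {
    agg <- all[, .(level = region_level(.SD[[paste0(s, "_M")]],
                                        .SD[[paste0(s, "_U")]])),
               by = bin]
    agg[, sample_id := s][]
  }))
  width <- 2 * flank / n_bins
  out[, offset_mid := -flank + (bin + 0.5) * width]
  data.table::setkeyv(out, c("sample_id", "bin"))
  out[]
}
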