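# Per-site bisulfite count container.
#
# A site table is a data.table with one row per analysis unit (a CpG duplex
# keyed to the + strand coordinate of its C, or a + strand CpH cytosine)
# and, for every sample S, two integer columns "<S>_M" (methylated reads)
# and "<S>_U" (unmethylated reads).  Positions are 1-based and strictly
# increasing within a chromosome.

#' Construct a site count table
#'
#' @param dt data.frame/data.table with columns `chrom`, `pos`, `strand`,
#'   `context` plus `<sample>_M` / `<sample>_U` count pairs.
#' @param samples character vector of sample names in presentation order;
#'   inferred from the count columns when omitted.
#' @param validate run structural checks (non-negative counts, sorted
#'   positions).
#' @return a `site_table` (a keyed data.table with a `samples` attribute).
#' @export
site_table <- function(dt, samples = NULL, validate = TRUE) {
  dt <- data.table::as.data.table(dt)
  req <- c("chrom", "pos", "strand", "context")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("site table lacks required column(s): ", paste(miss, collapse = ", "))
  if (is.null(samples)) {
    m <- grep("_M$", names(dt), value = TRUE)
    samples <- sub("_M$", "", m)
  }
  for (s in samples) {
    for (col in paste0(s, c("_M", "_U")))
      if (!col %in% names(dt)) stop("missing count column: ", col)
  }
  data.table::setkeyv(dt, c("chrom", "pos"))
  data.table::setattr(dt, "samples", samples)
  data.table::setattr(dt, "class",
                      unique(c("site_table", class(dt))))
  if (validate) validate_site_table(dt)
  dt
}

#' Samples stored in a site table
#' @param x a `site_table`.
#' @export
st_samples <- function(x) attr(x, "samples", exact = TRUE)

m_cols <- function(samples) paste0(samples, "_M")
u_cols <- function(samples) paste0(samples, "_U")

#' Validate a site table
#'
#' Checks non-negative counts, strictly increasing positions within each
#' chromosome, and (when a genome is supplied) that each site's context
#' matches the underlying sequence.
#'
#' @param x a `site_table`.
#' @param genome optional `DNAStringSet` for context verification.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_site_table <- function(x, genome = NULL) {
  samples <- st_samples(x)
  cnt <- as.matrix(x[, c(m_cols(samples), u_cols(samples)), with = FALSE])
  if (any(cnt < 0, na.rm = TRUE)) {
    bad <- which(rowSums(cnt < 0, na.rm = TRUE) > 0)[1]
    stop("negative count at row ", bad)
  }
  if (any(x[, any(diff(pos) <= 0), by = chrom]$V1))
    stop("positions must be strictly increasing within a chromosome")
  if (!all(x$context %in% c("CpG", "CHG", "CHH")))
    stop("context must be CpG, CHG or CHH")
  if (!is.null(genome)) {
    for (ch in unique(x$chrom)) {
      s <- genome[[ch]]
      p <- x[chrom == ch, pos]
      ctx <- x[chrom == ch, context]
      seqc <- as.character(s)
      b1 <- substring(seqc, p, p)
      b2 <- substring(seqc, p + 1, p + 1)
      b3 <- substring(seqc, p + 2, p + 2)
      want <- ifelse(b2 == "G", "CpG", ifelse(b3 == "G", "CHG", "CHH"))
      if (any(b1 != "C"))
        stop("site not on a cytosine in ", ch)
      if (any(want != ctx))
        stop("context disagrees with genome sequence in ", ch)
    }
  }
  invisible(TRUE)
}

#' Per-sample sequencing depth matrix
#' @param x a `site_table`.
#' @return integer matrix, one column per sample.
#' @export
site_depths <- function(x) {
  samples <- st_samples(x)
  M <- as.matrix(x[, m_cols(samples), with = FALSE])
  U <- as.matrix(x[, u_cols(samples), with = FALSE])
  D <- M + U
  colnames(D) <- samples
  D
}

#' Filter sites by sequencing depth
#'
#' In `all_samples` mode (the default, matching the study-wide ">= 10x in
#' every stage" rule) a site is kept only when its depth reaches
#' `min_depth` in every sample.  In `per_sample` mode individual sample
#' cells below the threshold are masked to `NA` instead, leaving the site
#' in place for the samples that do qualify.
#'
#' @param x a `site_table`.
#' @param min_depth minimum total reads (methylated + unmethylated).
#' @param mode `"all_samples"` or `"per_sample"`.
#' @return a filtered/masked `site_table`.
#' @export
filter_by_coverage <- function(x, min_depth = 10,
                               mode = c("all_samples", "per_sample")) {
  mode <- match.arg(mode)
  samples <- st_samples(x)
  if (min_depth <= 0) return(x)
  D <- site_depths(x)
  if (mode == "all_samples") {
    keep <- rowSums(D >= min_depth, na.rm = FALSE) == length(samples)
    keep[is.na(keep)] <- FALSE
    out <- x[keep]
  } else {
    out <- data.table::copy(x)
    for (s in samples) {
      low <- D[, s] < min_depth
      data.table::set(out, which(low), m_cols(s), NA_integer_)
      data.table::set(out, which(low), u_cols(s), NA_integer_)
    }
  }
  site_table(out, samples, validate = FALSE)
}

#' Read / write the tab-delimited site table format
#'
#' Plain TSV with header `chrom pos strand context <S>_M <S>_U ...`;
#' positions 1-based.  `read_site_table(write_site_table(x))` round-trips
#' byte-identically.
#'
#' @param x a `site_table`.
#' @param path file path.
#' @return `read_site_table` returns a `site_table`.
#' @export
write_site_table <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  samples <- sub("_M$", "", grep("_M$", names(dt), value = TRUE))
  cnt <- as.matrix(dt[, c(m_cols(samples), u_cols(samples)), with = FALSE])
  neg <- which(rowSums(cnt < 0, na.rm = TRUE) > 0)
  if (length(neg))
    stop("negative count at line ", neg[1] + 1L, " of ", path)
  site_table(dt, samples)
}
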