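# Standard-format readers/writers and run configuration.
#
# Conventions: tab tables (site, SNP) are 1-based inclusive; BED and
# bedGraph are 0-based half-open.  All writers are byte-deterministic.

#' Read and write FASTA genomes
#' @param genome a `DNAStringSet`.
#' @param path file path.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  Biostrings::readDNAStringSet(path)
}

#' Read and write BED intervals
#'
#' BED is 0-based half-open: record `chr1 999 1200` covers 1-based
#' bases 1000..1200.
#'
#' @param gr a `GRanges` (1-based internally).
#' @param path file path.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  rtracklayer::import.bed(path)
}

# plain deterministic BED writer for data.tables already in 0-based
# half-open columns (chrom, start, end, ...)
write_bed_table <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE,
                     col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write per-sample methylation levels as bedGraph
#'
#' One track per sample; uncovered sites are omitted (never written as
#' 0).
#'
#' @param x a `site_table`.
#' @param sample_id sample to export.
#' @param path output file.
#' @export
write_bedgraph <- function(x, sample_id, path) {
  lv <- site_level(x[[paste0(sample_id, "_M")]],
                   x[[paste0(sample_id, "_U")]])
  keep <- !is.na(lv)
  dt <- data.table::data.table(chrom = x$chrom[keep],
                               start = x$pos[keep] - 1L,
                               end = x$pos[keep],
                               score = round(lv[keep], 6))
  header <- sprintf("track type=bedGraph name=%s", sample_id)
  writeLines(header, path)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE,
                     col.names = FALSE, append = TRUE, eol = "\n")
  invisible(path)
}

#' Default run configuration
#'
#' Every analysis threshold defaults to the study's stated value: site
#' test depth 5x and alpha 0.05; region alpha 0.01, merge gap 300 bp,
#' 10 candidate sites, level difference 0.3; study-wide coverage filter
#' 10x; SNP filters 10 reads / base quality 5 / confidence 20 /
#' genotype quality > 20 / both alleles 10x; RDL 0.6; gamete-specific
#' thresholds 0.75 / 0.25; 100 bp density tiles and 500 kb windows;
#' promoters 2 kb up / 1 kb down of the TSS; CGIs > 200 bp, GC > 0.5,
#' obs/exp > 0.65.
#'
#' @return nested named list of parameter blocks.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    genome = list(n_chromosomes = 3L, chrom_length = 200000L,
                  gc_background = 0.42, cpg_retention = 0.4,
                  cgi_count = 20L,
                  cgi_length_min = 300L, cgi_length_max = 600L,
                  gene_count = 30L, cgi_promoter_fraction = 0.6,
                  repeat_count = 20L),
    reads = list(mean_coverage = 30, dispersion = 8,
                 nonconversion = 0.005, overconversion = 0.005),
    spikein = list(n_sites = 20000L),
    filter = list(min_depth = 10L, mode = "all_samples"),
    calling = list(alpha = 0.01, correction = "BH"),
    dmr = list(min_depth = 5L, site_alpha = 0.05, region_alpha = 0.01,
               max_gap = 300L, min_sites = 10L, min_diff = 0.3,
               method = "fisher"),
    allele = list(min_depth = 10L, min_base_qual = 5L,
                  min_var_conf = 20L, min_geno_qual = 20L,
                  min_allele_depth = 10L, rdl_threshold = 0.6,
                  n_snps = 2000L),
    gamete_sites = list(hyper = 0.75, hypo = 0.25),
    annotation = list(promoter_upstream = 2000L,
                      promoter_downstream = 1000L,
                      cgi_min_length = 200L, cgi_min_gc = 0.5,
                      cgi_min_obs_exp = 0.65),
    tiles = list(tile_size = 100L, window_size = 500000L),
    clustering = list(k = 6L, linkage = "average",
                      metric = "euclidean"))
}

check_config_keys <- function(cfg, ref, path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stop("unknown configuration key", if (length(unknown) > 1) "s",
         ": ", paste0(path, unknown, collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      if (!is.list(cfg[[k]]))
        stop("configuration block expected at ", path, k)
      check_config_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

#' Read a YAML run configuration
#'
#' Values omitted from the file keep their defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return full configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  ref <- default_config()
  check_config_keys(cfg, ref)
  modifyList(ref, cfg)
}
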