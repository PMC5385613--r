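# End-to-end pipeline: simulate a study-shaped dataset and run every
# analysis stage, writing all outputs plus a manifest (parameters, seed,
# file checksums).  Bit-reproducible under a fixed seed.

#' Run the full simulation-and-analysis pipeline
#'
#' Generates the synthetic genome, seven-stage methylome, read counts,
#' lambda spike-in and candidate SNPs, then runs error-rate estimation,
#' binomial calling, stage/chromosome trajectories, window and density
#' summaries, stage and CGI clustering, gamete-specific site tracing,
#' the seven pairwise DMR comparisons with annotation, promoter
#' gain/loss at the 8-cell transition, and parent-of-origin tracking
#' with ADM classification.  All outputs land in `outdir`; a
#' `manifest.json` records parameters, seed, and the MD5 checksum of
#' every file written.
#'
#' @param outdir output directory (created).
#' @param config configuration list (see [default_config()]).
#' @param seed overrides `config$seed` when given.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(outdir, config = default_config(),
                         seed = NULL) {
  cfg <- config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  base_seed <- as.integer(cfg$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(p) { paths <<- c(paths, p); p }

  # --- simulate -------------------------------------------------------
  g <- simulate_genome(genome_spec(
    n_chromosomes = cfg$genome$n_chromosomes,
    chrom_length = cfg$genome$chrom_length,
    gc_background = cfg$genome$gc_background,
    cpg_retention = cfg$genome$cpg_retention,
    cgi_count = cfg$genome$cgi_count,
    cgi_length_range = c(cfg$genome$cgi_length_min,
                         cfg$genome$cgi_length_max),
    gene_count = cfg$genome$gene_count,
    cgi_promoter_fraction = cfg$genome$cgi_promoter_fraction,
    repeat_count = cfg$genome$repeat_count,
    seed = base_seed))
  meth <- simulate_methylomes(g, stage_spec(seed = base_seed + 1L))
  model <- read_count_model(
    mean_coverage = cfg$reads$mean_coverage,
    dispersion = cfg$reads$dispersion,
    nonconversion = cfg$reads$nonconversion,
    overconversion = cfg$reads$overconversion,
    seed = base_seed + 2L)
  counts <- simulate_counts(meth, model)
  spike_model <- model; spike_model$seed <- base_seed + 3L
  spike <- simulate_spikein(cfg$spikein$n_sites, spike_model)
  snp <- simulate_snp_data(snp_spec(n_snps = cfg$allele$n_snps,
                                    seed = base_seed + 4L), g)

  write_fasta(g$genome, emit(file.path(outdir, "genome.fa")))
  write_site_table(counts, emit(file.path(outdir, "sites.tsv")))
  write_site_table(spike, emit(file.path(outdir, "lambda.tsv")))
  write_snp_table(snp$snps, emit(file.path(outdir, "snps.tsv")))
  for (f in write_truth(meth, file.path(outdir, "truth"))) emit(f)
  write_bed(g$annotation$genes, emit(file.path(outdir, "genes.bed")))
  det <- annotate_genome(g$genome, g$annotation$genes, cfg$annotation)
  write_bed(det$cgis, emit(file.path(outdir, "cgis_detected.bed")))
  write_bed(det$promoters, emit(file.path(outdir, "promoters.bed")))

  # --- methylation core ----------------------------------------------
  err <- estimate_error_rate(spike)
  filt <- filter_by_coverage(counts, cfg$filter$min_depth,
                             cfg$filter$mode)
  traj <- stage_trajectory(filt, "CpG")
  trajh <- stage_trajectory(filt, "CpH")
  data.table::fwrite(traj, emit(file.path(outdir, "trajectory_cpg.tsv")),
                     sep = "\t")
  data.table::fwrite(trajh, emit(file.path(outdir, "trajectory_cph.tsv")),
                     sep = "\t")
  tiles <- cpg_density_tiles(g$genome, cfg$tiles$tile_size)
  data.table::fwrite(tiles, emit(file.path(outdir, "cpg_tiles.tsv")),
                     sep = "\t")
  wm <- window_means(filt, g$annotation$seqlengths,
                     cfg$tiles$window_size)
  data.table::fwrite(wm, emit(file.path(outdir, "window_means.tsv")),
                     sep = "\t")
  stages <- meth$stages
  calls <- cbind(filt[, .(chrom, pos)],
                 call_methylated(filt[[paste0(stages[1], "_M")]],
                                 filt[[paste0(stages[1], "_U")]],
                                 err, cfg$calling$alpha,
                                 cfg$calling$correction))
  data.table::fwrite(calls, emit(file.path(outdir, "calls_sperm.tsv")),
                     sep = "\t")

  # --- dynamics -------------------------------------------------------
  hc <- hierarchical_cluster_stages(filt, "CpG",
                                    metric = cfg$clustering$metric,
                                    linkage = cfg$clustering$linkage,
                                    min_depth = cfg$filter$min_depth)
  write_newick(hc, emit(file.path(outdir, "stage_dendrogram.nwk")))
  cm <- cgi_matrix(filt, det$cgis)
  if (nrow(cm) >= cfg$clustering$k) {
    km <- kmeans_cluster(cm, cfg$clustering$k, seed = base_seed + 5L)
    data.table::fwrite(
      data.table::data.table(cgi = names(km$assignment),
                             cluster = unname(km$assignment)),
      emit(file.path(outdir, "cgi_clusters.tsv")), sep = "\t")
  }
  gs <- gamete_specific_sites(filt, stages[1:2],
                              cfg$gamete_sites$hyper,
                              cfg$gamete_sites$hypo,
                              cfg$filter$min_depth)
  for (side in names(gs)) {
    tr <- trace_sites(gs[[side]], filt)
    data.table::fwrite(tr, emit(file.path(
      outdir, paste0("trace_", side, ".tsv"))), sep = "\t")
  }
  ct <- chromosome_trajectory(filt, "chrX")
  data.table::fwrite(ct, emit(file.path(outdir, "chrX_trajectory.tsv")),
                     sep = "\t")

  # --- DMRs -----------------------------------------------------------
  pairs <- default_stage_pairs(stages)
  dmr_counts <- integer()
  for (lab in names(pairs)) {
    dm <- call_dmrs(counts, pairs[[lab]],
                    min_depth = cfg$dmr$min_depth,
                    site_alpha = cfg$dmr$site_alpha,
                    max_gap = cfg$dmr$max_gap,
                    min_sites = cfg$dmr$min_sites,
                    region_alpha = cfg$dmr$region_alpha,
                    min_diff = cfg$dmr$min_diff,
                    method = cfg$dmr$method)
    dm <- annotate_dmrs(dm, g$annotation)
    write_dmr_bed(dm, emit(file.path(
      outdir, sprintf("dmrs_%s_%s-%s.bed", lab, pairs[[lab]][1],
                      pairs[[lab]][2]))))
    dmr_counts[lab] <- nrow(dm)
  }
  pgl <- promoter_gain_loss(filt, g$annotation$promoters,
                            c("twocell", "eightcell"),
                            cfg$dmr$min_diff)
  writeLines(c(paste0("gained\t", paste(pgl$gained, collapse = ",")),
               paste0("lost\t", paste(pgl$lost, collapse = ","))),
             emit(file.path(outdir, "promoter_gain_loss.tsv")))

  # --- allele tracking ------------------------------------------------
  passed <- filter_candidate_snps(
    snp$snps, min_depth = cfg$allele$min_depth,
    min_base_qual = cfg$allele$min_base_qual,
    min_var_conf = cfg$allele$min_var_conf,
    min_geno_qual = cfg$allele$min_geno_qual,
    min_allele_depth = cfg$allele$min_allele_depth)
  asn <- assign_parent_of_origin(passed)
  atraj <- allele_methylation(asn$assigned, stages)
  data.table::fwrite(atraj, emit(file.path(
    outdir, "allele_trajectories.tsv")), sep = "\t")
  rdl <- classify_adm_sites(rdl_records(asn$assigned),
                            cfg$allele$rdl_threshold)
  adm <- rdl[is_adm == TRUE]
  if (nrow(adm))
    write_bed_table(adm[, .(chrom, start = pos - 1L, end = pos,
                            name = parent)],
                    emit(file.path(outdir, "adm_sites.bed")))
  dist <- adm_genomic_distribution(rdl, g$annotation)
  data.table::fwrite(dist, emit(file.path(
    outdir, "adm_distribution.tsv")), sep = "\t")

  manifest <- list(
    seed = base_seed,
    parameters = cfg,
    error_rate = err$rate,
    n_sites = nrow(counts), n_filtered = nrow(filt),
    dmr_counts = as.list(dmr_counts),
    n_snps_passed = nrow(passed),
    files = as.list(tools::md5sum(sort(paths))))
  jsonlite::write_json(manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Hash every pipeline output (determinism check helper)
#'
#' MD5 checksums of all regular files under a pipeline output
#' directory, excluding the manifest itself (which stores the hashes).
#'
#' @param outdir pipeline output directory.
#' @return named character vector of checksums.
#' @export
hash_outputs <- function(outdir) {
  f <- sort(list.files(outdir, recursive = TRUE, full.names = TRUE))
  f <- f[!grepl("manifest\\.json$", f)]
  h <- tools::md5sum(f)
  names(h) <- sub(paste0("^", outdir, "/?"), "", names(h))
  h
}
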