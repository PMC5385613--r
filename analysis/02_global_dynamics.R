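#!/usr/bin/env Rscript

# Global methylome dynamics: lambda-calibrated error rate, binomial
# methylation calls, CpG/CpH stage trajectories, stage clustering,
# CpG-density tiles, 500 kb window tracks and X-vs-autosome comparison.

suppressPackageStartupMessages({
  library(methwave)
  library(data.table)
})

datadir <- "results/data"; outdir <- "results/global"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

genome <- read_fasta(file.path(datadir, "genome.fa"))
counts <- read_site_table(file.path(datadir, "sites.tsv"))
spike <- read_site_table(file.path(datadir, "lambda.tsv"))

err <- estimate_error_rate(spike)
cat(sprintf("Lambda spike-in error rate: %.4f%% (%d reads)\n",
            100 * err$rate, err$total_reads))

filt <- filter_by_coverage(counts, 10)
cat("Sites covered >= 10x in every stage:", nrow(filt), "of",
    nrow(counts), "\n")

traj <- stage_trajectory(filt, "CpG")
trajh <- stage_trajectory(filt, "CpH")
fwrite(traj, file.path(outdir, "trajectory_cpg.tsv"), sep = "\t")
fwrite(trajh, file.path(outdir, "trajectory_cph.tsv"), sep = "\t")
cat("Global CpG trajectory (%):",
    paste(sprintf("%s %.1f", traj$sample_id, 100 * traj$level),
          collapse = ", "), "\n")

covered <- filt[filt$sperm_M + filt$sperm_U > 0]
calls <- call_methylated(covered$sperm_M, covered$sperm_U, err,
                         alpha = 0.01)
cat(sprintf("Sperm methylated-cytosine calls (BH 0.01): %d of %d\n",
            sum(calls$called), nrow(calls)))

hc <- hierarchical_cluster_stages(filt, "CpG")
write_newick(hc, file.path(outdir, "stage_dendrogram.nwk"))
cat("Stage clustering (first merge):", hc$merge_order[1],
    "- the two global minima pair up first\n")

tiles <- cpg_density_tiles(genome, 100L)
fwrite(tiles, file.path(outdir, "cpg_density_tiles.tsv"), sep = "\t")

seqlens <- setNames(Biostrings::width(genome), names(genome))
wm <- window_means(filt, seqlens, 500000L)
fwrite(wm, file.path(outdir, "window_means.tsv"), sep = "\t")

ct <- chromosome_trajectory(filt, "chrX")
fwrite(ct, file.path(outdir, "chrX_trajectory.tsv"), sep = "\t")
cat(sprintf("Max |chrX - autosome| level difference: %.3f\n",
            max(abs(ct$subset_level - ct$complement_level))))

for (s in st_samples(filt))
  write_bedgraph(filt, s, file.path(outdir, paste0(s, ".bedGraph")))
cat("Outputs under", outdir, "\n")
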