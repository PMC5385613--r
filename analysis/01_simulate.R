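#!/usr/bin/env Rscript

# Builds the synthetic study dataset all later analyses consume: a
# three-chromosome genome with planted CpG islands and gene models,
# seven-stage true methylomes (sperm, oocyte, zygote, 2-cell, 8-cell,
# morula, ICM), 30x bisulfite counts, an unmethylated lambda spike-in
# and a candidate-SNP table with planted parental truth.

suppressPackageStartupMessages(library(methwave))

outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260921L

g <- simulate_genome(genome_spec(seed = seed))
meth <- simulate_methylomes(g, stage_spec(seed = seed + 1L))
counts <- simulate_counts(meth, read_count_model(seed = seed + 2L))
spike <- simulate_spikein(20000L, read_count_model(seed = seed + 3L))
snps <- simulate_snp_data(snp_spec(seed = seed + 4L), g)

write_fasta(g$genome, file.path(outdir, "genome.fa"))
write_bed(g$annotation$genes, file.path(outdir, "genes.bed"))
write_bed(g$annotation$cgis, file.path(outdir, "cgis_planted.bed"))
write_site_table(counts, file.path(outdir, "sites.tsv"))
write_site_table(spike, file.path(outdir, "lambda.tsv"))
write_snp_table(snps$snps, file.path(outdir, "snps.tsv"))
write_snp_table(snps$truth, file.path(outdir, "snps_truth.tsv"))
write_truth(meth, file.path(outdir, "truth"))

cat("Simulated", nrow(counts), "cytosine sites (",
    sum(counts$context == "CpG"), "CpG ) across",
    length(g$genome), "chromosomes;",
    length(g$annotation$cgis), "planted CGIs,",
    length(g$annotation$genes), "genes,",
    nrow(snps$snps), "candidate SNPs.\n")
cat("Outputs under", outdir, "\n")
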