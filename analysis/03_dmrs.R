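#!/usr/bin/env Rscript

# Pairwise sliding-window DMR maps for the seven stage transitions
# (a: sperm-oocyte ... g: morula-ICM), feature annotation, and promoter
# methylation gain/loss at the 2-cell to 8-cell transition.

suppressPackageStartupMessages({
  library(methwave)
  library(data.table)
})

datadir <- "results/data"; outdir <- "results/dmrs"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

genome <- read_fasta(file.path(datadir, "genome.fa"))
counts <- read_site_table(file.path(datadir, "sites.tsv"))
genes <- read_bed(file.path(datadir, "genes.bed"))
GenomicRanges::strand(genes) <-
  ifelse(as.character(GenomicRanges::strand(genes)) == "*", "+",
         as.character(GenomicRanges::strand(genes)))
genes$gene_id <- genes$name
det <- annotate_genome(genome, genes)
ann <- list(genes = genes, promoters = det$promoters, cgis = det$cgis)

pairs <- default_stage_pairs()
for (lab in names(pairs)) {
  dm <- call_dmrs(counts, pairs[[lab]])
  dm <- annotate_dmrs(dm, ann)
  write_dmr_bed(dm, file.path(outdir, sprintf(
    "dmrs_%s_%s-%s.bed", lab, pairs[[lab]][1], pairs[[lab]][2])))
  hyper <- sum(dm$direction == "hyper_in_a")
  cat(sprintf(
    "%s (%s vs %s): %d DMRs (%d higher in %s, %d higher in %s)\n",
    lab, pairs[[lab]][1], pairs[[lab]][2], nrow(dm), hyper,
    pairs[[lab]][1], nrow(dm) - hyper, pairs[[lab]][2]))
}

filt <- filter_by_coverage(counts, 10)
pgl <- promoter_gain_loss(filt, det$promoters,
                          c("twocell", "eightcell"))
cat(sprintf(
  "Promoters gaining methylation 2-cell -> 8-cell: %d; losing: %d\n",
  length(pgl$gained), length(pgl$lost)))
fwrite(data.table(gene_id = c(pgl$gained, pgl$lost),
                  change = rep(c("gained", "lost"),
                               c(length(pgl$gained),
                                 length(pgl$lost)))),
       file.path(outdir, "promoter_gain_loss.tsv"), sep = "\t")
cat("Outputs under", outdir, "\n")
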