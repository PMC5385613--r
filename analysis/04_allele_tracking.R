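#!/usr/bin/env Rscript

# Parent-of-origin methylation tracking: SNP filtering, assignment by
# the homozygous sperm genotype, paternal/maternal methylation
# trajectories, and RDL-based classification of actively demethylated
# (ADM) zygotic CpG sites with their genomic distribution.

suppressPackageStartupMessages({
  library(methwave)
  library(data.table)
})

datadir <- "results/data"; outdir <- "results/alleles"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

snps <- read_snp_table(file.path(datadir, "snps.tsv"))
genome <- read_fasta(file.path(datadir, "genome.fa"))
genes <- read_bed(file.path(datadir, "genes.bed"))
GenomicRanges::strand(genes) <-
  ifelse(as.character(GenomicRanges::strand(genes)) == "*", "+",
         as.character(GenomicRanges::strand(genes)))
det <- annotate_genome(genome, genes)

passed <- filter_candidate_snps(snps)
cat("Candidate SNPs:", nrow(snps), "-> after quality/consistency/",
    "allele-depth filters:", nrow(passed), "\n")
print(attr(passed, "filter_summary"))

asn <- assign_parent_of_origin(passed)
cat("Informative SNPs with parental origin:", nrow(asn$assigned),
    "( unassignable:", nrow(asn$unassignable), ")\n")

stages <- snp_spec()$stage_names
am <- allele_methylation(asn$assigned, stages)
fwrite(am, file.path(outdir, "allele_trajectories.tsv"), sep = "\t")
for (par in c("paternal", "maternal")) {
  tr <- am[parent == par & !is.na(level)]
  cat(sprintf("%s trajectory (%%): %s\n", par,
              paste(sprintf("%s %.1f", tr$stage, 100 * tr$level),
                    collapse = ", ")))
}

rdl <- classify_adm_sites(rdl_records(asn$assigned), 0.6)
fwrite(rdl, file.path(outdir, "rdl_records.tsv"), sep = "\t")
adm <- rdl[is_adm == TRUE]
cat(sprintf(
  "ADM sites (RDL >= 0.6): paternal %d / maternal %d of %d each\n",
  nrow(adm[parent == "paternal"]), nrow(adm[parent == "maternal"]),
  nrow(asn$assigned)))

dist <- adm_genomic_distribution(rdl, c(det, list(genes = genes)))
fwrite(dist, file.path(outdir, "adm_distribution.tsv"), sep = "\t")
cat("ADM genomic distribution written; outputs under", outdir, "\n")
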