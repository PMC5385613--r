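# Shared fixtures, built once per test run (lazily) and cached.

fx <- new.env()

fixture_genome <- function() {
  if (is.null(fx$genome))
    fx$genome <- simulate_genome(genome_spec(seed = 42))
  fx$genome
}

fixture_methylome <- function() {
  if (is.null(fx$methylome))
    fx$methylome <- simulate_methylomes(fixture_genome(),
                                        stage_spec(seed = 43))
  fx$methylome
}

# error-free read model so recovered levels can be compared to truth
# with purely binomial error bounds
fixture_counts <- function() {
  if (is.null(fx$counts))
    fx$counts <- simulate_counts(
      fixture_methylome(),
      read_count_model(mean_coverage = 30, seed = 44,
                       nonconversion = 0, overconversion = 0))
  fx$counts
}

fixture_filtered <- function() {
  if (is.null(fx$filtered))
    fx$filtered <- filter_by_coverage(fixture_counts(), 10)
  fx$filtered
}

fixture_snps <- function() {
  if (is.null(fx$snps))
    fx$snps <- simulate_snp_data(snp_spec(seed = 45))
  fx$snps
}

# --- independent oracles ---------------------------------------------

# two-sided Fisher p by direct hypergeometric enumeration with
# choose()-based pmf (independent of the dhyper/cumsum implementation)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  pmf <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(pmf[pmf <= pmf[a - lo + 1] * (1 + 1e-7)])
}

# upper-tail binomial probability by explicit term summation
binom_tail_oracle <- function(x, n, p) {
  if (x <= 0) return(1)
  sum(choose(n, x:n) * p^(x:n) * (1 - p)^(n - (x:n)))
}

# pooled binomial standard error of a read-weighted level estimate
pooled_se <- function(level, total_reads) {
  sqrt(level * (1 - level) / total_reads)
}

# interval Jaccard between a called DMR row and a truth row
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  union <- max(e1, e2) - min(s1, s2)
  if (union <= 0) return(0)
  inter / union
}

# match truth DMRs against calls; returns per-truth best Jaccard
dmr_recovery <- function(calls, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    tt <- truth[i]
    same <- calls[calls$chrom == tt$chrom]
    if (!nrow(same)) return(0)
    max(vapply(seq_len(nrow(same)), function(j)
      interval_jaccard(same$start[j], same$end[j], tt$start - 1L,
                       tt$end), numeric(1)))
  }, numeric(1))
}
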