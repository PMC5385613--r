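---
title: "Models and methods: bidirectional methylome dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: bidirectional methylome dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`methwave` analyses per-cytosine bisulfite count tables across a
staged developmental series — sperm, oocyte, zygote, 2-cell, 8-cell,
morula and inner cell mass (ICM) — and ships a synthetic-data
generator with machine-readable planted truth so that every analysis
step is validated end to end. This vignette explains the underlying
models, the parameters that matter, the numerical choices, and what
the validation does and does not demonstrate.

## Quantification and binomial calling

A site's methylation level is the fraction of reads reporting 'C'
among reads reporting 'C' or 'T' at that cytosine. A *region* level is
deliberately read-pooled — Σ methylated / Σ total over the region's
covered sites — so deep sites carry proportionally more weight; an
unweighted mean-of-site-levels mode exists behind a flag
(`region_level(..., weighted = FALSE)`) for cross-checks. Cells or
regions with zero coverage are reported as `NA`, never as 0: a missing
level and an unmethylated level are different facts.

Bisulfite conversion is imperfect: unmethylated cytosines occasionally
survive conversion and read as 'C'. The combined non-conversion +
sequencing error rate ε is estimated as the pooled methylated fraction
of a fully unmethylated lambda-phage spike-in. A cytosine with m
methylated reads out of n is then called methylated from the
upper-tail binomial probability P(X ≥ m | n, ε), with
Benjamini–Hochberg correction at α = 0.01. The BH threshold is our
choice (the calling procedure we follow does not fix one); "none" and
any `p.adjust` method are accepted. An estimated ε ≥ 0.5 aborts with a
calibration error — at that point the data cannot distinguish
methylation from conversion failure. CpG duplexes are one analysis
unit keyed to the + strand coordinate of the C; CHG/CHH sites share
the same calling machinery with a single collapsed error channel.

## Sliding-window DMR identification

For a sample pair, candidate sites are CpGs with depth ≥ 5× in both
samples whose two-sided Fisher exact test on the 2×2
methylated/unmethylated table gives P < 0.05, each labelled by the
direction of the level difference. Candidates merge left-to-right into
maximal runs while each next candidate is ≤ 300 bp from the previous
one and shares its direction; a direction flip or larger gap seeds a
new run. Runs with ≥ 10 candidates are re-tested by a Fisher test on
their pooled counts and emitted when the region P ≤ 0.01 and the
absolute pooled level difference is ≥ 0.3. Output intervals span the
first to last candidate site (0-based half-open in BED).

Numerical and design choices:

* **Exact test implementation.** The per-site tests dominate runtime,
  so the two-sided Fisher p-value is computed directly from the
  hypergeometric pmf with caching over shared margins (all tables with
  equal row/column totals reuse one sorted cumulative sum). The
  two-sided rule is the conventional "sum of outcome probabilities not
  exceeding the observed one", with the same 1 + 1e-7 relative
  tolerance `stats::fisher.test` uses; the test suite verifies
  agreement with both `stats::fisher.test` and an independent
  `choose()`-based enumeration to 1e-10 over every table with total
  ≤ 60.
* **Fisher by default, chi-square on request.** `chisq_test_2x2`
  (no continuity correction) is available where all expected cells are
  ≥ 5 and silently falls back to the exact test below that; the
  original procedure permitted either without stating a rule, and the
  exact test is the safe default at low coverage.
* **Two-sided tests**, since no sidedness is prescribed.
* **Intervening non-significant CpGs do not break a run** by default:
  the merge rules speak only of candidate sites. The stricter reading
  is available as `break_at_nonsig = TRUE`.
* **No multiple-testing correction at the site or region stage**,
  mirroring the stated raw thresholds (0.05 / 0.01); BH is available
  through the calling module for users who want it.
* **Greedy maximal extension has no ties**: runs are uniquely
  determined by the direction/gap rules, which is what makes the
  caller provably equivalent to the exhaustive quadratic enumeration
  (`enumerate_dmrs_bruteforce`) used as the validation oracle.

## Parent-of-origin tracking and RDL

The module consumes a candidate heterozygous-SNP table carrying the
quality fields an upstream bisulfite-aware genotyper reports; the
genotyping model itself is out of scope — the contribution here is the
filter-and-track procedure. Filters: zygote depth ≥ 10 reads, base
quality ≥ 5, phred-scaled variant confidence ≥ 20, heterozygote
genotype quality strictly > 20, both alleles ≥ 10×, and genotype
consistency across all stages where observed. "Both alleles ≥ 10×" is
applied in the zygote only (the sentence that introduces it is about
the zygote call); `allele_depth_all_stages = TRUE` extends it.
Records whose ref/alt pair is C/T — or G/A, its bottom-strand image
under the + strand duplex convention — are excluded by default because
bisulfite conversion makes those alleles indistinguishable from
methylation state.

A surviving heterozygote whose allele set contains the homozygous
sperm allele assigns that allele as paternal and the other as
maternal; heterozygous sperm, or no matching allele, is unassignable
and logged. Allele-linked CpG counts (carried per allele per stage in
the table) give read-pooled parental trajectories.

The relative demethylation level of a site from gamete to zygote is
RDL = (pre − post)/pre, floored at 0 and undefined for pre = 0. The
threshold RDL ≥ 0.6 defines actively demethylated (ADM) sites — the
zygote precedes any division, so the loss is replication-independent.
The exact formula is our adoption of the convention from the
mouse-study lineage that introduced the threshold; the flooring means
a methylation *gain* counts as zero demethylation rather than a
negative value. Both the formula and the ≥ (inclusive) threshold are
design decisions documented here and fixed in code.

## CpG islands, promoters and annotation

Islands are regions > 200 bp with GC fraction > 0.5 and
observed/expected CpG = N_CpG · L / (N_C · N_G) > 0.65. Since only the
criteria are given (the original analysis used pre-computed
annotations), detection is a deterministic scan: 200 bp windows
stepped by 1 bp, qualifying windows merged when overlapping, each
merged region re-tested as a whole and, if it fails, trimmed one base
at a time from whichever end better restores the criteria (ties go to
the left end). A merged region can extend slightly beyond a planted
island where flanking windows still qualify; every reported island is
re-checkable with `check_cgi_criteria`, and an isolated single window
(exactly 200 bp) is dropped by the strict length rule.

Promoters span 2 kb upstream and 1 kb downstream of the TSS,
strand-aware: a + strand gene with 1-based TSS t gets BED interval
[t−2001, t+999); on the − strand the window is mirrored around the
TSS at the gene end. Positions are labelled by midpoint overlap with
precedence promoter > 5'UTR > exon > intron > 3'UTR > CGI > repeat >
intergenic. Note the 1 kb downstream tail means first exons and
intron starts usually label as "promoter" — by design, the precedence
expresses regulatory salience, not gene structure.

Coordinates are 1-based inclusive in tab tables (matching common
methylation-extractor output) and 0-based half-open in BED/bedGraph.

## The synthetic-data generator

The generator emulates the structure the analyses must resolve; its
defaults are the study conditions, fixed once:

* **Global stage means** default to the published values where printed
  — sperm 78.68 %, 2-cell 44.8 %, 8-cell 52.7 %, morula 42.2 %, ICM
  47.1 %. No oocyte or zygote global mean is printed anywhere;
  defaults of 65 % and 55 % were chosen once to satisfy the stated
  ordering (oocyte below sperm but above every embryo stage, monotone
  decline to the 2-cell minimum) and are explicitly not published
  values.
* **Compartments.** Each CpG belongs to one of: ordinary CGIs (mean
  0.05, all stages — islands stay unmethylated through reprogramming),
  gamete-specific hypermethylated CGIs (15 % of islands per gamete,
  reprogrammed after fertilisation), gamete-specific single sites
  (2 % of non-island CpGs per gamete; drawn > 0.85 in the defining
  gamete and < 0.15 in the other so that recovery at 50× is limited by
  sampling noise, not by boundary sites sitting on the 0.75/0.25
  thresholds), de novo methylation targets (10 % of non-island CpGs:
  high in gametes, low at 2-cell and morula, remethylated at 8-cell
  and ICM), and background. The de novo compartment is what gives the
  2-cell and morula methylomes their shared hypomethylated *pattern*:
  with mean shifts alone, the printed stage means would make 2-cell
  and ICM (44.8 vs 47.1) the closest pair, whereas the observed
  clustering pairs the two minima. Background per-stage means are
  solved exactly so the pooled CpG mean of every stage lands on the
  configured global trajectory given the realised compartment levels.
* **Within-compartment variation** follows a Gaussian-copula beta
  model: a site-specific latent factor shared across stages (latent
  correlation 0.95) plus per-stage noise, mapped through the beta
  quantile function of each stage's target mean. Concentration 2 for
  background reproduces the dispersed, bimodal-leaning site-level
  distribution of real WGBS without modelling chromatin; planted
  compartments use tighter concentrations (10–30).
* **Read counts**: coverage is negative-binomial (mean 30, size 8 —
  over-dispersed like real WGBS; `dispersion = Inf` gives the Poisson
  limit), and methylated reads are binomial with success probability
  m(1−overconversion) + (1−m)·nonconversion, folding non-conversion
  and sequencing error into the two channels the spike-in calibrates
  (defaults 0.005 each, matching the ~0.5 % error a lambda spike-in
  typically reports).
* **ADM planting**: 30 % of gamete-specific sites drop to
  pre × (1 − 0.75) in the zygote (planted RDL 0.75); the rest
  maintain their gamete level. SNP records carry per-allele depths of
  30–60 reads per stage so that a planted RDL of 0.75 sits about two
  standard errors above the 0.6 classification threshold — at much
  lower depth the recovered ADM fraction is biased low by
  classification noise, which is a property of the statistic, not a
  bug.
* **Planted filter violations**: 20 % of SNP records each violate one
  filtering criterion (including the boundary case genotype quality
  = 20, which the strict inequality must reject); heterozygous-sperm
  plants pass the *filter* and fail at *assignment*, exercising the
  two stages separately.
* **Genome**: i.i.d. background sequence at GC 0.42 with 60 % of CG
  dinucleotides mutated C→T (`cpg_retention = 0.4`), emulating
  germline CpG depletion so the background obs/exp (~0.4) stays well
  below the island threshold; CG-enriched islands are written over the
  background, 60 % of them centred on TSSs. The last chromosome is
  named chrX so sex-chromosome summaries run against a chromosome
  simulated identically to the autosomes — matching the observation
  that X methylation follows the global pattern.

What the generator does **not** emulate: read-level data (FASTQ,
alignment, M-bias, duplicates), linkage disequilibrium or read-backed
phasing across SNPs, realistic repeat families, chromatin-state
autocorrelation along the genome (sites are exchangeable within
compartments), and replicate-to-replicate biological variance (the
study pooled replicates). Passing tests therefore demonstrate that the
algorithms recover what they claim from count data under calibrated
noise — not that real libraries are free of the upstream artefacts
this package deliberately treats as out of scope.

## Validation design and problem sizes

The test suite validates every operation against independent oracles:
exact-test p-values against `choose()`-based enumeration (all 2×2
tables with total ≤ 60) and `stats::fisher.test`; the binomial caller
against explicit term summation; the DMR caller against exhaustive
quadratic enumeration on 50 random 200-site chromosomes whose gap and
segment structure is adversarial (gaps straddling 300 bp, direction
flips, interrupted runs); planted-DMR recovery (20 regions of 15 CpGs
at Δ = 0.5, 30×, recovery ≥ 80 % at interval Jaccard ≥ 0.8) against a
matched null — two count resamplings of one shared truth — that must
yield zero calls; trajectory recovery on a ~50 000-CpG genome at 30×
within three conditional binomial standard errors of the
coverage-weighted truth; parent assignment at 100 % concordance
(genotype observation is noise-free by construction; with allele-read
error the bound would be the corresponding binomial one); and
bit-identical full-pipeline reruns under a fixed seed. These sizes
were chosen as the smallest at which the statistical bounds are
informative; all are configurable upward.

Clustering choices: stage-level hierarchical clustering uses Euclidean
distance on common-site level vectors with average linkage
(correlation distance is available; nothing in the source analysis
fixes either), and CGI k-means defaults to k = 6 with an explicit
seed — k and seed are unstated upstream, so they are configuration,
not claims. k-means at k = number of items returns the trivial
partition directly since `stats::kmeans` requires k < n.

## Known limitations

* The brute-force DMR oracle is quadratic and intended for
  chromosomes of a few hundred candidate sites.
* The CGI detector's 1 bp-step scan is exact but O(L·w) in spirit;
  prefix sums keep it linear in practice, yet chromosome-scale mammal
  genomes would want a coarser step.
* `region_level` pools reads, so samples sequenced much deeper
  dominate pooled cross-sample summaries; per-sample levels are never
  mixed, which keeps this a within-sample weighting question only.
* RDL is undefined at pre = 0 and noisy for small pre; classification
  near the 0.6 threshold inherits binomial noise from both the gamete
  and zygote allele depths, so recovered ADM fractions are mildly
  conservative at realistic depth.
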