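# Seven-stage true-methylome generator.
#
# Each CpG site belongs to one compartment:
#   cgi_low / cgi_sperm_high / cgi_oocyte_high -- island archetypes
#   sperm_specific / oocyte_specific -- gamete-specific hypermethylated
#   denovo -- targets of embryonic de novo methylation (remethylated at
#             the 8-cell and ICM stages, low at 2-cell and morula); this
#     compartment gives the 2-cell and morula methylomes their shared
#     hypomethylated pattern and the 8-cell stage its methylation peak.
#   background -- everything else.
# Background per-stage means are solved so that the pooled CpG mean of
# every stage hits the configured global trajectory exactly (given the
# realised levels of the other compartments).  Within a compartment,
# levels follow a Gaussian-copula beta model: a site-specific latent
# factor shared across stages (correlation `site_cor`) plus per-stage
# noise, pushed through the beta quantile function so each stage keeps
# its target mean while sites stay strongly correlated along development.

#' Specification of the seven-stage methylome
#'
#' Stage-mean defaults use the study's printed global CpG levels where
#' printed (sperm 78.68%, 2-cell 44.8%, 8-cell 52.7%, morula 42.2%, ICM
#' 47.1%); the oocyte and zygote means are free parameters constrained
#' to decline monotonically from sperm to the 2-cell minimum.
#'
#' @param stage_names ordered stage labels (used as sample names).
#' @param stage_mean global CpG methylation mean per stage, in \[0,1\].
#' @param cgi_mean methylation mean of ordinary (always-low) CGIs.
#' @param cgi_sperm_high_fraction,cgi_oocyte_high_fraction fraction of
#'   islands hypermethylated specifically in one gamete.
#' @param gamete_specific_fraction fraction of non-island CpGs
#'   hypermethylated (> 0.75) in exactly one gamete and hypomethylated
#'   (< 0.25) in the other, per gamete.
#' @param adm_fraction fraction of gamete-specific sites actively
#'   demethylated in the zygote (before any division).
#' @param adm_rdl planted relative demethylation level at ADM sites.
#' @param denovo_fraction fraction of non-island CpGs in the de novo
#'   target compartment (remethylated at the 8-cell and ICM stages).
#' @param denovo_levels per-stage mean of the de novo compartment.
#' @param sperm_specific_traj,oocyte_specific_traj post-zygotic mean
#'   trajectory of gamete-specific sites (stages 4..7); gametes and the
#'   zygote are governed by the threshold/ADM rules instead.
#' @param cph_mean per-stage CpH methylation mean (kept low).
#' @param n_cph number of CpH sites to simulate.
#' @param overdispersion beta concentration of the background
#'   compartment (small = more bimodal site levels).
#' @param site_cor latent cross-stage correlation of site levels.
#' @param planted_dmrs optional list of planted differential regions,
#'   each `list(chrom, start, end, pair = c(stage_a, stage_b),
#'   direction = "hyper"|"hypo", delta)`; `hyper` means stage_b gains
#'   `delta` over stage_a inside the interval.
#' @param seed RNG seed.
#' @return a `stage_spec` list.
#' @export
stage_spec <- function(
    stage_names = c("sperm", "oocyte", "zygote", "twocell", "eightcell",
                    "morula", "icm"),
    stage_mean = c(0.7868, 0.65, 0.55, 0.448, 0.527, 0.422, 0.471),
    cgi_mean = 0.05,
    cgi_sperm_high_fraction = 0.15, cgi_oocyte_high_fraction = 0.15,
    gamete_specific_fraction = 0.02,
    adm_fraction = 0.3, adm_rdl = 0.75,
    denovo_fraction = 0.10,
    denovo_levels = c(0.80, 0.60, 0.25, 0.10, 0.80, 0.15, 0.80),
    sperm_specific_traj = c(NA, NA, NA, 0.30, 0.40, 0.28, 0.33),
    oocyte_specific_traj = c(NA, NA, NA, 0.48, 0.48, 0.46, 0.47),
    cph_mean = c(0.050, 0.045, 0.030, 0.020, 0.027, 0.020, 0.030),
    n_cph = 4000L,
    overdispersion = 2, site_cor = 0.95,
    planted_dmrs = NULL, seed = 1L) {
  spec <- as.list(environment())   # capture arguments before temporaries
  stopifnot(length(stage_mean) == length(stage_names),
            all(stage_mean >= 0 & stage_mean <= 1),
            all(cph_mean >= 0 & cph_mean <= 0.2),
            adm_fraction >= 0, adm_fraction <= 1,
            adm_rdl > 0, adm_rdl <= 1,
            overdispersion > 0, site_cor >= 0, site_cor < 1)
  if (length(stage_mean) >= 4 &&
      !(all(diff(stage_mean[1:4]) <= 0)))
    stop("stage means must decline monotonically from sperm to the ",
         "2-cell minimum")
  if (!is.null(planted_dmrs)) {
    for (d in planted_dmrs) {
      stopifnot(d$direction %in% c("hyper", "hypo"),
                length(d$pair) == 2, d$start <= d$end, d$delta > 0)
    }
    key <- vapply(planted_dmrs, function(d)
      paste(sort(d$pair), collapse = "-"), character(1))
    for (k in unique(key)) {
      dd <- planted_dmrs[key == k]
      if (length(dd) > 1) {
        ir <- IRanges::IRanges(vapply(dd, `[[`, numeric(1), "start"),
                               vapply(dd, `[[`, numeric(1), "end"))
        ch <- vapply(dd, `[[`, character(1), "chrom")
        gr <- GenomicRanges::GRanges(ch, ir)
        if (sum(IRanges::width(GenomicRanges::reduce(gr))) <
            sum(IRanges::width(gr)))
          stop("planted DMR intervals overlap within a stage pair")
      }
    }
  }
  structure(spec, class = "stage_spec")
}

# copula beta draw: z shared across stages, e idiosyncratic
draw_copula <- function(z, means, conc, rho) {
  n <- length(z); nt <- length(means)
  out <- matrix(NA_real_, n, nt)
  for (t in seq_len(nt)) {
    u <- pnorm(rho * z + sqrt(1 - rho^2) * rnorm(n))
    out[, t] <- qbeta(u, conc * means[t], conc * (1 - means[t]))
  }
  out
}

#' Generate per-site true methylation levels for every stage
#'
#' @param genome_obj a `synthetic_genome` from [simulate_genome()].
#' @param spec a [stage_spec()].
#' @return a `stage_methylome`: list with `sites` (data.table of
#'   `chrom`, `pos`, `strand`, `context`, `compartment`, `is_adm`, and
#'   one true-level column per stage), `stages`, `spec`, and
#'   `planted_dmrs`.
#' @export
simulate_methylomes <- function(genome_obj, spec = stage_spec()) {
  stopifnot(inherits(genome_obj, "synthetic_genome"),
            inherits(spec, "stage_spec"))
  set.seed(spec$seed)
  stages <- spec$stage_names
  nt <- length(stages)
  ann <- genome_obj$annotation
  sites <- cpg_sites(genome_obj$genome)
  ncpg <- nrow(sites)

  # compartment assignment -------------------------------------------
  comp <- rep("background", ncpg)
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, sites$pos))
  cgis <- ann$cgis
  if (length(cgis)) {
    arch <- rep("cgi_low", length(cgis))
    n_sp <- round(spec$cgi_sperm_high_fraction * length(cgis))
    n_oo <- round(spec$cgi_oocyte_high_fraction * length(cgis))
    pick <- sample(length(cgis), min(length(cgis), n_sp + n_oo))
    arch[pick[seq_len(min(n_sp, length(pick)))]] <- "cgi_sperm_high"
    if (length(pick) > n_sp)
      arch[pick[(n_sp + 1):length(pick)]] <- "cgi_oocyte_high"
    ov <- GenomicRanges::findOverlaps(gr, cgis)
    comp[S4Vectors::queryHits(ov)] <-
      arch[S4Vectors::subjectHits(ov)]
  }
  free <- which(comp == "background")
  n_gs <- round(spec$gamete_specific_fraction * length(free))
  n_dn <- round(spec$denovo_fraction * length(free))
  pick <- sample(free, min(length(free), 2L * n_gs + n_dn))
  if (n_gs) {
    comp[pick[seq_len(n_gs)]] <- "sperm_specific"
    comp[pick[n_gs + seq_len(n_gs)]] <- "oocyte_specific"
  }
  if (n_dn) comp[pick[2L * n_gs + seq_len(n_dn)]] <- "denovo"

  L <- matrix(NA_real_, ncpg, nt, dimnames = list(NULL, stages))
  is_adm <- rep(FALSE, ncpg)

  # island archetypes --------------------------------------------------
  idx <- which(comp == "cgi_low")
  if (length(idx))
    L[idx, ] <- draw_copula(rnorm(length(idx)),
                            rep(spec$cgi_mean, nt), 30, spec$site_cor)
  cgi_sp_traj <- c(0.82, 0.05, 0.45, 0.30, 0.35, 0.25, 0.30)
  cgi_oo_traj <- c(0.05, 0.82, 0.50, 0.48, 0.47, 0.45, 0.46)
  idx <- which(comp == "cgi_sperm_high")
  if (length(idx))
    L[idx, ] <- draw_copula(rnorm(length(idx)), cgi_sp_traj, 20,
                            spec$site_cor)
  idx <- which(comp == "cgi_oocyte_high")
  if (length(idx))
    L[idx, ] <- draw_copula(rnorm(length(idx)), cgi_oo_traj, 20,
                            spec$site_cor)

  # gamete-specific sites: hard threshold draws in the gametes, the ADM
  # rule in the zygote, configured trajectories afterwards
  for (side in c("sperm_specific", "oocyte_specific")) {
    idx <- which(comp == side)
    if (!length(idx)) next
    high <- runif(length(idx), 0.85, 0.98)
    low <- runif(length(idx), 0.02, 0.15)
    adm <- runif(length(idx)) < spec$adm_fraction
    is_adm[idx] <- adm
    pre <- high
    zy <- ifelse(adm, pre * (1 - spec$adm_rdl), pre)
    traj <- if (side == "sperm_specific") spec$sperm_specific_traj
            else spec$oocyte_specific_traj
    post <- draw_copula(rnorm(length(idx)), traj[4:nt], 20,
                        spec$site_cor)
    if (side == "sperm_specific") {
      L[idx, 1] <- high; L[idx, 2] <- low
    } else {
      L[idx, 1] <- low; L[idx, 2] <- high
    }
    L[idx, 3] <- zy
    L[idx, 4:nt] <- post
  }

  # de novo targets ----------------------------------------------------
  idx <- which(comp == "denovo")
  if (length(idx))
    L[idx, ] <- draw_copula(rnorm(length(idx)), spec$denovo_levels, 10,
                            spec$site_cor)

  # background: solve per-stage means so pooled CpG means hit the target
  idx <- which(comp == "background")
  if (!length(idx))
    stop("no background CpG sites: compartment fractions too large")
  other_sum <- colSums(L[-idx, , drop = FALSE], na.rm = TRUE)
  mu_bg <- (ncpg * spec$stage_mean - other_sum) / length(idx)
  if (any(mu_bg < 0.02 | mu_bg > 0.98))
    stop("background mean outside (0.02, 0.98); compartment fractions ",
         "and stage means are inconsistent")
  L[idx, ] <- draw_copula(rnorm(length(idx)), mu_bg,
                          spec$overdispersion, spec$site_cor)

  sites[, compartment := comp]
  sites[, is_adm := is_adm]

  # CpH sites ----------------------------------------------------------
  cph <- cph_sites(genome_obj$genome, n = spec$n_cph)
  if (nrow(cph)) {
    cph[, compartment := "cph"]
    cph[, is_adm := FALSE]
    Lc <- draw_copula(rnorm(nrow(cph)), spec$cph_mean, 30, spec$site_cor)
    colnames(Lc) <- stages
    cph <- cbind(cph, data.table::as.data.table(Lc))
  }
  colnames(L) <- stages
  sites <- cbind(sites, data.table::as.data.table(L))
  sites <- data.table::rbindlist(list(sites, cph), use.names = TRUE)
  data.table::setkeyv(sites, c("chrom", "pos"))

  # planted DMRs override ---------------------------------------------
  if (!is.null(spec$planted_dmrs)) {
    for (d in spec$planted_dmrs) {
      rows <- sites[, which(chrom == d$chrom & pos >= d$start &
                              pos <= d$end & context == "CpG")]
      if (!length(rows)) next
      base <- rbeta(length(rows), 50 * 0.2, 50 * 0.8)
      lo <- base
      hi <- base + d$delta
      if (any(hi > 1)) {
        warning("planted DMR level clamped to [0,1] in ",
                d$chrom, ":", d$start, "-", d$end)
        hi <- clamp01(hi)
      }
      if (d$direction == "hyper") {  # stage b gains
        data.table::set(sites, rows, d$pair[1], lo)
        data.table::set(sites, rows, d$pair[2], hi)
      } else {
        data.table::set(sites, rows, d$pair[1], hi)
        data.table::set(sites, rows, d$pair[2], lo)
      }
    }
  }

  structure(list(sites = sites, stages = stages, spec = spec,
                 planted_dmrs = spec$planted_dmrs),
            class = "stage_methylome")
}

#' True-level matrix of a stage methylome
#' @param m a `stage_methylome`.
#' @param context restrict to a context (`NULL` = all sites).
#' @return numeric matrix sites x stages.
#' @export
true_levels <- function(m, context = NULL) {
  s <- m$sites
  if (!is.null(context)) {
    keep <- if (context == "CpH") s$context %in% c("CHG", "CHH")
            else s$context == context
    s <- s[keep]
  }
  as.matrix(s[, m$stages, with = FALSE])
}

#' Read-count model for bisulfite count simulation
#'
#' Coverage is negative-binomial (over-dispersed; `dispersion = Inf`
#' degenerates to Poisson).  The methylated-read probability at true
#' level m is `m (1 - overconversion) + (1 - m) nonconversion`,
#' folding non-conversion and sequencing error into the two channels the
#' lambda spike-in calibrates.
#'
#' @param mean_coverage mean reads per site.
#' @param dispersion negative-binomial size parameter (`Inf` = Poisson).
#' @param nonconversion probability an unmethylated C reads as 'C'.
#' @param overconversion probability a methylated C reads as 'T'.
#' @param seed RNG seed.
#' @return a `read_model` list.
#' @export
read_count_model <- function(mean_coverage = 30, dispersion = 8,
                             nonconversion = 0.005,
                             overconversion = 0.005, seed = 1L) {
  stopifnot(mean_coverage >= 0,
            nonconversion >= 0, nonconversion <= 0.1,
            overconversion >= 0, overconversion <= 0.1,
            dispersion > 0)
  structure(list(mean_coverage = mean_coverage, dispersion = dispersion,
                 nonconversion = nonconversion,
                 overconversion = overconversion, seed = seed),
            class = "read_model")
}

draw_coverage <- function(n, model) {
  if (is.infinite(model$dispersion))
    rpois(n, model$mean_coverage)
  else
    rnbinom(n, mu = model$mean_coverage, size = model$dispersion)
}

#' Sample bisulfite read counts from true methylation levels
#'
#' @param truth a `stage_methylome`, or a data.table with `chrom`,
#'   `pos`, `strand`, `context` and one true-level column per sample.
#' @param model a [read_count_model()].
#' @param samples columns of `truth` to sample (defaults to all stages).
#' @return a `site_table` with `<sample>_M` / `<sample>_U` counts.
#' @export
simulate_counts <- function(truth, model = read_count_model(),
                            samples = NULL) {
  if (inherits(truth, "stage_methylome")) {
    samples <- samples %||% truth$stages
    dt <- truth$sites
  } else {
    dt <- data.table::as.data.table(truth)
    if (is.null(samples))
      samples <- setdiff(names(dt), c("chrom", "pos", "strand",
                                      "context", "compartment",
                                      "is_adm"))
  }
  set.seed(model$seed)
  out <- dt[, .(chrom, pos, strand, context)]
  n <- nrow(dt)
  for (s in samples) {
    m <- dt[[s]]
    cov <- draw_coverage(n, model)
    p <- m * (1 - model$overconversion) + (1 - m) * model$nonconversion
    M <- rbinom(n, cov, p)
    data.table::set(out, j = paste0(s, "_M"), value = M)
    data.table::set(out, j = paste0(s, "_U"), value = cov - M)
  }
  site_table(out, samples, validate = FALSE)
}

#' Simulate an unmethylated lambda spike-in
#'
#' All sites have true level 0, so the pooled observed level estimates
#' the model's non-conversion rate.
#'
#' @param n_sites number of spike-in cytosines (must be positive).
#' @param model a [read_count_model()].
#' @param sample_id sample column name.
#' @return a `site_table` on the synthetic `lambda` contig.
#' @export
simulate_spikein <- function(n_sites, model = read_count_model(),
                             sample_id = "spikein") {
  if (n_sites <= 0) stop("no spike-in sites requested")
  truth <- data.table::data.table(
    chrom = "lambda", pos = seq_len(n_sites) * 10L, strand = "+",
    context = "CpG", lv = 0)
  data.table::setnames(truth, "lv", sample_id)
  simulate_counts(truth, model, samples = sample_id)
}

#' Planted-DMR benchmark pair
#'
#' Two samples share one background truth (so their comparison is null
#' by construction) except in `n_dmrs` planted intervals of
#' `sites_per_dmr` consecutive CpGs where sample B differs from sample A
#' by `delta` (alternating hyper/hypo).  Counts are then sampled
#' independently for the two samples.
#'
#' @param n_dmrs planted regions.
#' @param sites_per_dmr CpGs per region.
#' @param delta true level difference inside regions.
#' @param n_background background CpGs.
#' @param spacing distance between consecutive CpGs (bases; keep at or
#'   below the 300 bp merge gap).
#' @param model a [read_count_model()].
#' @param seed RNG seed (controls truth and counts).
#' @return list with `table` (samples `A`, `B`), `truth_dmrs`
#'   (data.table with interval, direction and site count).
#' @export
simulate_dmr_benchmark <- function(n_dmrs = 20L, sites_per_dmr = 15L,
                                   delta = 0.5, n_background = 20000L,
                                   spacing = 25L,
                                   model = read_count_model(),
                                   seed = 1L) {
  set.seed(seed)
  n_total <- n_background + n_dmrs * sites_per_dmr
  # gap of 40 spacings between blocks keeps planted regions > 300 bp
  # away from any background run
  block_at <- if (n_dmrs)
    round(seq(0.05, 0.95, length.out = n_dmrs) * n_background)
  else integer()
  pos <- integer(0); grp <- integer(0)
  cur <- 1000L; bg_left <- n_background; bi <- 1L
  i <- 0L
  while (bg_left > 0 || bi <= n_dmrs) {
    if (bi <= n_dmrs && (n_background - bg_left) >= block_at[bi]) {
      pos <- c(pos, cur + 400L + seq_len(sites_per_dmr) * spacing)
      grp <- c(grp, rep(bi, sites_per_dmr))
      cur <- cur + 800L + sites_per_dmr * spacing
      bi <- bi + 1L
    } else if (bg_left > 0) {
      pos <- c(pos, cur + spacing)
      grp <- c(grp, 0L)
      cur <- cur + spacing
      bg_left <- bg_left - 1L
    } else break
  }
  n <- length(pos)
  base <- rbeta(n, 2 * 0.5, 2 * 0.5)
  a <- base; b <- base
  dirs <- rep(c("hyper", "hypo"), length.out = n_dmrs)
  truth <- list()
  for (j in seq_len(n_dmrs)) {
    rows <- which(grp == j)
    lo <- rbeta(length(rows), 50 * 0.2, 50 * 0.8)
    hi <- clamp01(lo + delta)
    if (dirs[j] == "hyper") { a[rows] <- lo; b[rows] <- hi }
    else { a[rows] <- hi; b[rows] <- lo }
    truth[[j]] <- data.table::data.table(
      chrom = "chrS", start = min(pos[rows]), end = max(pos[rows]),
      direction = ifelse(dirs[j] == "hyper", "hypo_in_a", "hyper_in_a"),
      n_sites = length(rows))
  }
  tr <- data.table::data.table(chrom = "chrS", pos = pos, strand = "+",
                               context = "CpG", A = a, B = b)
  model$seed <- seed + 1L
  tab <- simulate_counts(tr, model, samples = c("A", "B"))
  list(table = tab,
       truth_dmrs = if (n_dmrs) data.table::rbindlist(truth)
                    else data.table::data.table())
}

#' Random segmented two-sample chromosome (oracle stress fixture)
#'
#' A single-chromosome two-sample table with adversarial structure for
#' caller-vs-enumeration equivalence checks: CpG gaps mix values below
#' and above the 300 bp merge threshold, and true levels are piecewise
#' constant in random segments that are either shared or strongly
#' different between the samples (random sign), so candidate runs of
#' many lengths, directions and interruptions arise.
#'
#' @param n_sites CpGs on the chromosome.
#' @param model a [read_count_model()].
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @return a `site_table` with samples `A`, `B`.
#' @export
simulate_random_pair <- function(n_sites = 200L,
                                 model = read_count_model(),
                                 seed = 1L, chrom = "chrR") {
  set.seed(seed)
  gaps <- sample(c(10:60, 250:350), n_sites, replace = TRUE,
                 prob = c(rep(0.9 / 51, 51), rep(0.1 / 101, 101)))
  pos <- cumsum(gaps) + 500L
  seg <- cumsum(runif(n_sites) < 0.08)   # segment switches
  n_seg <- max(seg) + 1L
  kind <- sample(c("same", "a_high", "b_high"), n_seg, replace = TRUE,
                 prob = c(0.5, 0.25, 0.25))
  base <- runif(n_seg, 0.15, 0.85)
  la <- base[seg + 1L]; lb <- la
  hi <- pmin(0.95, base + 0.55); lo <- pmax(0.05, base - 0.55)
  ka <- kind[seg + 1L]
  la[ka == "a_high"] <- hi[seg + 1L][ka == "a_high"]
  lb[ka == "a_high"] <- lo[seg + 1L][ka == "a_high"]
  la[ka == "b_high"] <- lo[seg + 1L][ka == "b_high"]
  lb[ka == "b_high"] <- hi[seg + 1L][ka == "b_high"]
  tr <- data.table::data.table(chrom = chrom, pos = pos, strand = "+",
                               context = "CpG", A = la, B = lb)
  model$seed <- seed + 1L
  simulate_counts(tr, model, samples = c("A", "B"))
}

#' Write machine-readable truth files for a stage methylome
#'
#' Emits `truth_sites.tsv` (per-site compartment, ADM flag and true
#' levels), `truth_adm.bed`, `truth_gamete_specific.bed` and, when DMRs
#' were planted, `truth_dmrs.bed`.
#'
#' @param m a `stage_methylome`.
#' @param dir output directory (created).
#' @return invisibly the vector of files written.
#' @export
write_truth <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, "truth_sites.tsv")
  data.table::fwrite(m$sites, files[1], sep = "\t")
  adm <- m$sites[is_adm == TRUE]
  if (nrow(adm)) {
    f <- file.path(dir, "truth_adm.bed")
    write_bed_table(adm[, .(chrom, start = pos - 1L, end = pos,
                            name = compartment)], f)
    files <- c(files, f)
  }
  gs <- m$sites[compartment %in% c("sperm_specific", "oocyte_specific")]
  if (nrow(gs)) {
    f <- file.path(dir, "truth_gamete_specific.bed")
    write_bed_table(gs[, .(chrom, start = pos - 1L, end = pos,
                           name = compartment)], f)
    files <- c(files, f)
  }
  if (!is.null(m$planted_dmrs)) {
    f <- file.path(dir, "truth_dmrs.bed")
    dmr <- data.table::rbindlist(lapply(m$planted_dmrs, function(d)
      data.table::data.table(chrom = d$chrom, start = d$start - 1L,
                             end = d$end,
                             name = paste0(d$pair[1], "-", d$pair[2],
                                           ":", d$direction))))
    write_bed_table(dmr, f)
    files <- c(files, f)
  }
  invisible(files)
}
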