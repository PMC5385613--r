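# Synthetic genome generation and sequence-level annotation: planted
# CpG islands and gene models, CGI detection from first principles, and
# promoter derivation.  The genome is a stand-in at desk scale: a few
# short chromosomes (the last one named chrX so sex-chromosome summaries
# are exercised), i.i.d. background sequence at a configurable GC
# fraction, CG-enriched islands, and simple five-part gene models
# (5'UTR, exon, intron, exon, 3'UTR).

#' Specification of a synthetic genome
#'
#' @param n_chromosomes number of chromosomes; the last is named `chrX`.
#' @param chrom_length chromosome length in bases (must be at least ten
#'   times the longest CGI).
#' @param gc_background background GC fraction in (0, 1).
#' @param cpg_retention fraction of background CG dinucleotides kept;
#'   the rest have their C mutated to T, emulating the germline CpG
#'   depletion of methylated genomes (background obs/exp CpG ~=
#'   `cpg_retention`, well below the 0.65 island threshold).
#' @param cgi_count number of planted CpG islands.
#' @param cgi_length_range min/max island length (bases).
#' @param gene_count number of planted gene models.
#' @param cgi_promoter_fraction fraction of islands centred on a TSS
#'   (CGI promoters); the rest are placed away from genes.
#' @param repeat_count number of annotated repeat intervals (annotation
#'   only; no special sequence).
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return a `genome_spec` list.
#' @export
genome_spec <- function(n_chromosomes = 3L, chrom_length = 200000L,
                        gc_background = 0.42, cpg_retention = 0.4,
                        cgi_count = 20L,
                        cgi_length_range = c(300L, 600L),
                        gene_count = 30L, cgi_promoter_fraction = 0.6,
                        repeat_count = 20L, seed = 1L) {
  stopifnot(n_chromosomes >= 1, gc_background > 0, gc_background < 1,
            cpg_retention > 0, cpg_retention <= 1,
            cgi_count >= 0, gene_count >= 0, repeat_count >= 0,
            length(cgi_length_range) == 2,
            cgi_length_range[1] <= cgi_length_range[2])
  if (chrom_length < 10 * max(cgi_length_range))
    stop("chrom_length must be >= 10x the longest CGI")
  structure(as.list(environment()), class = "genome_spec")
}

rand_seq <- function(n, gc) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# CG-enriched island sequence: a token stream mixing "CG" dinucleotides
# with GC-biased single bases, which comfortably satisfies the island
# criteria (GC > 0.5, obs/exp CpG > 0.65).
cgi_seq <- function(len, p_cg = 0.17, gc = 0.65) {
  n_tok <- len
  tok <- ifelse(runif(n_tok) < p_cg, "CG",
                rand_seq(n_tok, gc))
  s <- paste(tok, collapse = "")
  substring(s, 1, len)
}

#' Generate a synthetic genome with planted CGIs and gene models
#'
#' Gene models are 3 kb: 200 bp 5'UTR, 500 bp exon, 1 kb intron, 1 kb
#' exon, 300 bp 3'UTR, random strand, spaced so promoters (2 kb up /
#' 1 kb down of the TSS) never overlap a neighbouring gene.
#'
#' @param spec a [genome_spec()].
#' @return a `synthetic_genome` list with `genome` (a `DNAStringSet`),
#'   `annotation` (a `genome_annotation` list of `GRanges`: genes,
#'   promoters, utr5, exon, intron, utr3, cgis, repeats) and the spec.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  n_chr <- spec$n_chromosomes
  chroms <- if (n_chr == 1) "chr1" else
    c(paste0("chr", seq_len(n_chr - 1)), "chrX")
  L <- spec$chrom_length

  # gene slots: gene body 3000 bp + 2500 bp margin either side
  gene_len <- 3000L; margin <- 2500L; slot <- gene_len + 2L * margin
  slots_per_chr <- max(0L, (L - 2000L) %/% slot)
  if (spec$gene_count > slots_per_chr * n_chr)
    stop("gene_count exceeds genome capacity")
  slot_tab <- data.table::CJ(chrom = chroms, slot = seq_len(slots_per_chr))
  gene_rows <- slot_tab[sort(sample(nrow(slot_tab), spec$gene_count))]
  gene_start <- 1000L + (gene_rows$slot - 1L) * slot + margin +
    sample(-500L:500L, nrow(gene_rows), replace = TRUE)
  gene_strand <- sample(c("+", "-"), nrow(gene_rows), replace = TRUE)

  genes <- GenomicRanges::GRanges(
    gene_rows$chrom,
    IRanges::IRanges(gene_start, gene_start + gene_len - 1L),
    strand = gene_strand)
  if (length(genes))
    genes$gene_id <- sprintf("gene%03d", seq_along(genes))

  # five-part gene structure, 5' to 3'
  part_w <- c(utr5 = 200L, exon = 500L, intron = 1000L, exon2 = 1000L,
              utr3 = 300L)
  feat <- list(utr5 = NULL, exon = NULL, intron = NULL, utr3 = NULL)
  if (length(genes)) {
    offs <- cumsum(c(0L, part_w[-length(part_w)]))
    for (i in seq_along(genes)) {
      st <- GenomicRanges::start(genes)[i]
      en <- GenomicRanges::end(genes)[i]
      fwd <- as.character(GenomicRanges::strand(genes))[i] == "+"
      starts <- if (fwd) st + offs else en - offs - part_w + 1L
      ends <- starts + part_w - 1L
      gr <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(genes)[i],
        IRanges::IRanges(starts, ends),
        strand = GenomicRanges::strand(genes)[i])
      names(gr) <- names(part_w)
      feat$utr5 <- c(feat$utr5, list(gr["utr5"]))
      feat$exon <- c(feat$exon, list(gr[c("exon", "exon2")]))
      feat$intron <- c(feat$intron, list(gr["intron"]))
      feat$utr3 <- c(feat$utr3, list(gr["utr3"]))
    }
    feat <- lapply(feat, function(l) unname(do.call(c, l)))
  } else {
    feat <- lapply(feat, function(l) GenomicRanges::GRanges())
  }

  # CGI placement: promoter islands centred on TSSs, the rest intergenic
  n_cgi <- spec$cgi_count
  cgi_len <- if (n_cgi)
    as.integer(round(runif(n_cgi, spec$cgi_length_range[1],
                           spec$cgi_length_range[2]))) else integer()
  n_prom_cgi <- min(round(spec$cgi_promoter_fraction * n_cgi),
                    length(genes))
  cgis <- GenomicRanges::GRanges()
  if (n_cgi) {
    picked <- if (n_prom_cgi) sample(seq_along(genes), n_prom_cgi)
              else integer()
    tss <- ifelse(as.character(GenomicRanges::strand(genes)) == "-",
                  GenomicRanges::end(genes), GenomicRanges::start(genes))
    placed <- list()
    for (j in seq_len(n_prom_cgi)) {
      ctr <- tss[picked[j]]
      placed[[j]] <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(genes))[picked[j]],
        IRanges::IRanges(max(1L, ctr - cgi_len[j] %/% 2L),
                         width = cgi_len[j]))
    }
    n_inter <- n_cgi - n_prom_cgi
    avoid <- suppressWarnings(GenomicRanges::reduce(GenomicRanges::trim(c(
      GenomicRanges::granges(genes) + 3500L,
      if (length(placed)) do.call(c, placed) + 500L
      else GenomicRanges::GRanges()))))
    tries <- 0L
    while (n_inter > 0 && tries < 10000L) {
      tries <- tries + 1L
      j <- n_prom_cgi + n_inter
      ch <- sample(chroms, 1)
      st <- sample.int(L - cgi_len[j] - 100L, 1) + 50L
      cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, width = cgi_len[j]))
      clear <- suppressWarnings(
        !length(GenomicRanges::findOverlaps(cand, avoid)) &&
          !any(vapply(placed, function(g)
            length(GenomicRanges::findOverlaps(cand, g)) > 0,
            logical(1))))
      if (clear) {
        placed[[length(placed) + 1L]] <- cand
        n_inter <- n_inter - 1L
      }
    }
    if (n_inter > 0) stop("could not place all CGIs: genome too small")
    cgis <- sort(suppressWarnings(unname(do.call(c, placed))))
  }

  # assemble sequence: depleted background, then overwrite islands
  seqs <- lapply(chroms, function(ch) {
    s <- rand_seq(L, spec$gc_background)
    cg <- which(s[-L] == "C" & s[-1] == "G")
    mut <- cg[runif(length(cg)) > spec$cpg_retention]
    if (length(mut)) s[mut] <- "T"
    s
  })
  names(seqs) <- chroms
  if (length(cgis)) {
    for (i in seq_along(cgis)) {
      ch <- as.character(GenomicRanges::seqnames(cgis))[i]
      st <- GenomicRanges::start(cgis)[i]
      en <- GenomicRanges::end(cgis)[i]
      island <- strsplit(cgi_seq(en - st + 1L), "")[[1]]
      seqs[[ch]][st:en] <- island
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                            collapse = ""))
  names(genome) <- chroms

  repeats <- GenomicRanges::GRanges()
  if (spec$repeat_count) {
    rep_len <- sample(500:2000, spec$repeat_count, replace = TRUE)
    repeats <- GenomicRanges::GRanges(
      sample(chroms, spec$repeat_count, replace = TRUE),
      IRanges::IRanges(sample.int(L - 2100L, spec$repeat_count) + 50L,
                       width = rep_len))
    repeats <- sort(repeats)
  }

  if (length(genes))
    GenomeInfoDb::seqlengths(genes) <-
      setNames(rep(L, n_chr), chroms)[GenomeInfoDb::seqlevels(genes)]
  ann <- structure(list(
    genes = genes,
    promoters = promoters_from_genes(genes),
    utr5 = feat$utr5, exon = feat$exon, intron = feat$intron,
    utr3 = feat$utr3,
    cgis = cgis, repeats = repeats,
    seqlengths = setNames(rep(L, n_chr), chroms)),
    class = "genome_annotation")

  structure(list(genome = genome, annotation = ann, spec = spec),
            class = "synthetic_genome")
}

#' Promoters from gene models
#'
#' A promoter spans 2 kb upstream and 1 kb downstream of the TSS,
#' strand-aware: for a + strand gene with 1-based TSS t it covers
#' \[t - 2000, t + 999\] (BED \[t-2001, t+999)); on the - strand the
#' window is mirrored around the TSS at the gene end.  Genes without a
#' strand are rejected.
#'
#' @param genes `GRanges` of gene models (strand required).
#' @param upstream,downstream promoter extent in bases.
#' @return `GRanges` of promoters carrying `gene_id`, trimmed to
#'   chromosome bounds when seqlengths are set.
#' @export
promoters_from_genes <- function(genes, upstream = 2000L,
                                 downstream = 1000L) {
  if (!length(genes)) return(GenomicRanges::GRanges())
  if (any(as.character(GenomicRanges::strand(genes)) == "*"))
    stop("gene without strand: cannot orient its promoter")
  pr <- GenomicRanges::promoters(genes, upstream = upstream,
                                 downstream = downstream)
  pr <- GenomicRanges::trim(pr)
  GenomicRanges::start(pr) <- pmax(1L, GenomicRanges::start(pr))
  pr
}

#' All CpG sites of a genome (+ strand duplex convention)
#'
#' A CpG duplex is one analysis unit keyed to the + strand coordinate of
#' its C.
#'
#' @param genome a `DNAStringSet`.
#' @return data.table `chrom`, `pos` (1-based), `strand`, `context`.
#' @export
cpg_sites <- function(genome) {
  hits <- Biostrings::vmatchPattern("CG", genome)
  data.table::rbindlist(lapply(names(genome), function(ch) {
    st <- IRanges::start(hits[[ch]])
    if (!length(st)) return(NULL)
    data.table::data.table(chrom = ch, pos = st, strand = "+",
                           context = "CpG")
  }))
}

#' Sample CpH (non-CpG cytosine) sites from a genome
#'
#' + strand cytosines not followed by G; context CHG when the base two
#' positions downstream is G, CHH otherwise.
#'
#' @param genome a `DNAStringSet`.
#' @param n number of sites to sample (all when `NULL`).
#' @return data.table as in [cpg_sites()].
#' @export
cph_sites <- function(genome, n = NULL) {
  all <- data.table::rbindlist(lapply(names(genome), function(ch) {
    s <- strsplit(as.character(genome[[ch]]), "")[[1]]
    len <- length(s)
    isC <- s == "C"
    nxt <- c(s[-1], "N"); nxt2 <- c(s[-(1:2)], "N", "N")
    cph <- isC & nxt != "G"
    cph[len] <- FALSE   # need a defined next base
    p <- which(cph)
    if (!length(p)) return(NULL)
    data.table::data.table(chrom = ch, pos = p, strand = "+",
                           context = ifelse(nxt2[p] == "G", "CHG", "CHH"))
  }))
  if (!is.null(n) && nrow(all) > n)
    all <- all[sort(sample(nrow(all), n))]
  data.table::setkeyv(all, c("chrom", "pos"))
  all[]
}

#' CpG counts in consecutive fixed-width tiles
#'
#' Non-overlapping tiles from the chromosome start; each CpG duplex is
#' counted once, in the tile containing its + strand C.
#'
#' @param genome a `DNAStringSet`.
#' @param tile_size tile width in bases.
#' @return data.table `chrom`, `tile_start` (0-based), `n_cpg`, covering
#'   every tile including empty ones.
#' @export
cpg_density_tiles <- function(genome, tile_size = 100L) {
  sites <- cpg_sites(genome)
  data.table::rbindlist(lapply(names(genome), function(ch) {
    len <- length(genome[[ch]])
    starts <- seq(0L, len - 1L, by = tile_size)
    cnt <- integer(length(starts))
    p <- sites[chrom == ch, pos]
    if (length(p)) {
      t <- (p - 1L) %/% tile_size + 1L
      tt <- tabulate(t, nbins = length(starts))
      cnt <- tt
    }
    data.table::data.table(chrom = ch, tile_start = starts, n_cpg = cnt)
  }))
}

# window CGI statistics from prefix sums ------------------------------

cgi_stats <- function(seq_chars, start, end) {
  # 1-based inclusive; returns length, gc fraction, obs/exp CpG
  s <- seq_chars[start:end]
  L <- length(s)
  nC <- sum(s == "C"); nG <- sum(s == "G")
  nCG <- sum(s[-L] == "C" & s[-1] == "G")
  oe <- if (nC * nG > 0) nCG * L / (nC * nG) else 0
  list(length = L, gc = (nC + nG) / L, obs_exp = oe, n_cpg = nCG)
}

#' Detect CpG islands by exhaustive sliding-window scan
#'
#' Fixed-width windows stepped by 1 bp are tested against the island
#' criteria (GC fraction > `min_gc`, observed/expected CpG
#' `= N_CpG * L / (N_C * N_G)` > `min_obs_exp`); qualifying overlapping
#' windows are merged, each merged region is re-tested as a whole and,
#' if it fails, trimmed from whichever end restores the criteria.
#' Reported islands are strictly longer than `min_length`.
#'
#' @param genome a `DNAStringSet`.
#' @param min_length islands must exceed this length (strict).
#' @param min_gc GC-fraction threshold (strict).
#' @param min_obs_exp observed/expected CpG threshold (strict).
#' @param window scan window width.
#' @return `GRanges` of islands with `gc`, `obs_exp`, `n_cpg` metadata.
#' @export
detect_cgi <- function(genome, min_length = 200L, min_gc = 0.5,
                       min_obs_exp = 0.65, window = 200L) {
  out <- list()
  for (ch in names(genome)) {
    s <- strsplit(as.character(genome[[ch]]), "")[[1]]
    len <- length(s)
    if (len < window) next
    cC <- cumsum(s == "C"); cG <- cumsum(s == "G")
    iscg <- c(s[-len] == "C" & s[-1] == "G", FALSE)
    cCG <- cumsum(iscg)
    starts <- 1:(len - window + 1L)
    ends <- starts + window - 1L
    nC <- cC[ends] - c(0, cC)[starts]
    nG <- cG[ends] - c(0, cG)[starts]
    # CG dinucleotides fully inside the window start at starts..ends-1
    nCG <- cCG[ends - 1L] - c(0, cCG)[starts]
    gc <- (nC + nG) / window
    oe <- ifelse(nC * nG > 0, nCG * window / (nC * nG), 0)
    ok <- gc > min_gc & oe > min_obs_exp
    if (!any(ok)) next
    qual <- IRanges::reduce(IRanges::IRanges(starts[ok], ends[ok]))
    kept <- list()
    for (i in seq_along(qual)) {
      st <- IRanges::start(qual)[i]; en <- IRanges::end(qual)[i]
      repeat {
        if (en - st + 1L <= min_length) { st <- NA; break }
        stt <- cgi_stats(s, st, en)
        if (stt$gc > min_gc && stt$obs_exp > min_obs_exp) break
        # trim the end whose removal better restores the criteria
        left <- cgi_stats(s, st + 1L, en)
        right <- cgi_stats(s, st, en - 1L)
        if (left$obs_exp + left$gc >= right$obs_exp + right$gc)
          st <- st + 1L else en <- en - 1L
      }
      if (!is.na(st)) kept[[length(kept) + 1L]] <- c(st, en)
    }
    for (reg in kept) {
      stt <- cgi_stats(s, reg[1], reg[2])
      out[[length(out) + 1L]] <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(reg[1], reg[2]),
        gc = stt$gc, obs_exp = stt$obs_exp, n_cpg = stt$n_cpg)
    }
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  sort(suppressWarnings(unname(do.call(c, out))))
}

#' Brute-force re-check of the CGI criteria
#'
#' Independent validator: recomputes length, GC fraction and obs/exp CpG
#' for each reported island directly from the sequence.
#'
#' @param cgis `GRanges` of islands.
#' @param genome a `DNAStringSet`.
#' @inheritParams detect_cgi
#' @return logical vector, `TRUE` where all three criteria hold.
#' @export
check_cgi_criteria <- function(cgis, genome, min_length = 200L,
                               min_gc = 0.5, min_obs_exp = 0.65) {
  vapply(seq_along(cgis), function(i) {
    ch <- as.character(GenomicRanges::seqnames(cgis))[i]
    s <- strsplit(as.character(genome[[ch]]), "")[[1]]
    stt <- cgi_stats(s, GenomicRanges::start(cgis)[i],
                     GenomicRanges::end(cgis)[i])
    stt$length > min_length && stt$gc > min_gc && stt$obs_exp > min_obs_exp
  }, logical(1))
}

#' Detect CGIs and derive promoters for a genome
#'
#' @param genome a `DNAStringSet`.
#' @param genes `GRanges` of gene models.
#' @param config annotation parameter block (see [default_config()]).
#' @return list with `cgis` (detected) and `promoters`.
#' @export
annotate_genome <- function(genome, genes,
                            config = default_config()$annotation) {
  list(cgis = detect_cgi(genome,
                         min_length = config$cgi_min_length,
                         min_gc = config$cgi_min_gc,
                         min_obs_exp = config$cgi_min_obs_exp),
       promoters = promoters_from_genes(
         genes, upstream = config$promoter_upstream,
         downstream = config$promoter_downstream))
}

#' Label genomic positions by feature precedence
#'
#' Precedence: promoter > 5'UTR > exon > intron > 3'UTR > CGI > repeat >
#' intergenic.
#'
#' @param chrom,pos vectors of 1-based positions.
#' @param annotation a `genome_annotation` (or list with the feature
#'   `GRanges` named as above).
#' @return character vector of labels.
#' @export
label_position <- function(chrom, pos, annotation) {
  pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  lab <- rep("intergenic", length(pts))
  order_feats <- c("repeats", "cgis", "utr3", "intron", "exon", "utr5",
                   "promoters")
  nice <- c(repeats = "repeat", cgis = "CGI", utr3 = "3'UTR",
            intron = "intron", exon = "exon", utr5 = "5'UTR",
            promoters = "promoter")
  for (f in order_feats) {   # low precedence first, overwritten by higher
    gr <- annotation[[f]]
    if (is.null(gr) || !length(gr)) next
    hit <- S4Vectors::queryHits(
      suppressWarnings(GenomicRanges::findOverlaps(pts, gr)))
    lab[unique(hit)] <- nice[[f]]
  }
  lab
}
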