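# Deterministic synthetic-data generators.
#
# The generators emit a small "stated world" with the statistical structure
# the analysis assumes: random genomes with controllable base composition,
# non-overlapping gene models, coverage time courses with a promoter pause
# peak and a two-level elongation wave whose front advances with decaying
# velocity, stalling spikes at template-strand TT loci upstream of the front,
# repair-read pileups mirroring the stalled loci, bimodal log2 RPKM
# expression, and mutation catalogs with expression-dependent rates and
# TS < NTS asymmetry. Every generator reseeds deterministically from
# `cfg$seed` plus a fixed per-generator salt, so a fixed seed gives
# byte-identical outputs regardless of call order.

#' Simulation configuration
#'
#' Defaults describe the desk-scale world used throughout the test-suite:
#' a pause peak of 8 rpm over -60..+100 bp, a 1 rpm gene-body baseline, a
#' 4 rpm post-UV elongation plateau, fronts at 5/15/25 kb for 30/60/120 min
#' of recovery (decaying velocity 0.33 then 0.17 kb/min), 90% of genes
#' escaping after UV with the rest mildly depleted, TT-locus stalling spikes
#' of +3 rpm on half the upstream loci, a symmetric two-component log2
#' expression mixture at -4 and +4, and mutation rates of 100 (NE) vs 20 (E)
#' per Mb per sample with a TS/NTS asymmetry of 0.5 across 20 samples.
#'
#' @param seed Integer master seed.
#' @param n_chromosomes,chrom_length Genome shape (bp).
#' @param n_genes Number of genes to place.
#' @param gene_length_range Length-2 range of gene lengths (bp).
#' @param intergenic_gap Gap between consecutive genes (bp, >= 1 kb keeps
#'   promoters non-overlapping by construction).
#' @param bin_size Coverage-track bin width (bp).
#' @param pause_height,body_baseline,wave_height Track levels (rpm).
#' @param front_positions_by_time Named numeric vector: timepoint (min) ->
#'   front position (kb); must be non-decreasing in time.
#' @param uv_escape_fraction Fraction of genes released into elongation after
#'   UV (these gain the wave plateau); the remainder get a gene-body
#'   depletion by `uv_depletion_factor` (escape decrease).
#' @param uv_depletion_factor Multiplier (< 1) on the body of non-escaping
#'   genes after UV.
#' @param stall_amplitude,stall_core Stalling spike height (rpm) and
#'   half-width (bp) at stalled TT loci. The default core (+-160 bp) fully
#'   covers the central-20% summit of a +-400 bp, 50 bp-binned locus window,
#'   while staying clear of its outer-25% flanks.
#' @param repair_amplitude,repair_core Same for the excision-read track,
#'   scaled to the +-60 bp repair windows.
#' @param repair_bin_size Bin width of the repair track (bp); finer than the
#'   ChIP tracks because the repair windows are narrow.
#' @param stall_fraction Fraction of upstream TT loci that stall.
#' @param noise_sd Gaussian noise SD added to tracks (rpm; truncated at 0).
#' @param expression_mixture list(means, sds, weight): two log2-normal
#'   components, `weight` = probability of the first (low) component.
#' @param mutation_rate_NE,mutation_rate_E Mutations per Mb per sample.
#' @param ts_nts_asymmetry TS rate / NTS rate in expressed genes, in (0, 1].
#' @param n_samples Samples in the mutation catalog.
#' @param base_probs Base composition of the genome (named A/C/G/T).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 2e6,
                       n_genes = 30L,
                       gene_length_range = c(6e4, 9e4),
                       intergenic_gap = 2000,
                       bin_size = 50,
                       pause_height = 8,
                       body_baseline = 1,
                       wave_height = 4,
                       front_positions_by_time = c("30" = 5, "60" = 15, "120" = 25),
                       uv_escape_fraction = 0.9,
                       uv_depletion_factor = 0.7,
                       stall_amplitude = 3,
                       stall_core = 160,
                       repair_amplitude = 3,
                       repair_core = 20,
                       repair_bin_size = 10,
                       stall_fraction = 0.5,
                       noise_sd = 0.5,
                       expression_mixture = list(means = c(-4, 4),
                                                 sds = c(1.5, 1.5),
                                                 weight = 0.5),
                       mutation_rate_NE = 100,
                       mutation_rate_E = 20,
                       ts_nts_asymmetry = 0.5,
                       n_samples = 20L,
                       base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  cfg <- as.list(environment())
  if (!.is_count(abs(seed))) .stopf("'seed' must be an integer")
  if (chrom_length <= 0 || n_chromosomes < 1) .stopf("non-positive genome dimensions")
  if (any(gene_length_range <= 0) || diff(gene_length_range) < 0) {
    .stopf("invalid 'gene_length_range'")
  }
  tp <- as.numeric(names(front_positions_by_time))
  if (anyNA(tp)) .stopf("'front_positions_by_time' must be named by timepoint (min)")
  o <- order(tp)
  if (any(diff(front_positions_by_time[o]) < 0)) {
    .stopf("front positions must be non-decreasing in time")
  }
  rates <- c(mutation_rate_NE, mutation_rate_E, stall_fraction, noise_sd,
             uv_escape_fraction)
  if (any(rates < 0)) .stopf("rates and fractions must be >= 0")
  if (ts_nts_asymmetry <= 0 || ts_nts_asymmetry > 1) {
    .stopf("'ts_nts_asymmetry' must be in (0, 1]")
  }
  if (abs(sum(base_probs) - 1) > 1e-8 ||
      !identical(sort(names(base_probs)), c("A", "C", "G", "T"))) {
    .stopf("'base_probs' must be named A/C/G/T and sum to 1")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a genome
#'
#' I.i.d. bases drawn from `cfg$base_probs`; TT-motif density is controlled
#' through the base composition.
#'
#' @param cfg A [sim_config()].
#' @return A `DNAStringSet`, chromosomes named chr1, chr2, ...
#' @export
sim_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.derive_seed(cfg$seed, 11L))
  seqs <- vapply(seq_len(cfg$n_chromosomes), function(i) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE,
                 prob = cfg$base_probs[c("A", "C", "G", "T")]),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(cfg$n_chromosomes))
  Biostrings::DNAStringSet(seqs)
}

#' Simulate a gene annotation
#'
#' Genes are laid sequentially along chromosomes with at least
#' `cfg$intergenic_gap` bp between them (inter-TSS distances >= 1 kb by
#' construction), random strands, 3-8 exons each, and biotypes drawn from
#' protein_coding / lncRNA / other.
#'
#' @param cfg A [sim_config()].
#' @return list(genes, exons) in the curated-gene / exon table layouts;
#'   `genes` carries ground-truth attribute `escaper` (logical per gene,
#'   drawn at `uv_escape_fraction`).
#' @export
sim_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.derive_seed(cfg$seed, 23L))
  if (cfg$gene_length_range[2] + 2 * cfg$intergenic_gap > cfg$chrom_length) {
    .stopf("requested genes do not fit on the chromosomes")
  }
  genes <- list()
  exons <- list()
  chrom_i <- 1L
  cursor <- cfg$intergenic_gap
  placed <- 0L
  while (placed < cfg$n_genes) {
    len <- round(stats::runif(1, cfg$gene_length_range[1], cfg$gene_length_range[2]))
    if (cursor + len + cfg$intergenic_gap > cfg$chrom_length) {
      chrom_i <- chrom_i + 1L
      cursor <- cfg$intergenic_gap
      if (chrom_i > cfg$n_chromosomes) {
        .stopf("genome too small for %d genes of %g-%g bp", cfg$n_genes,
               cfg$gene_length_range[1], cfg$gene_length_range[2])
      }
      next
    }
    placed <- placed + 1L
    strand <- sample(c("+", "-"), 1)
    start <- cursor
    end <- cursor + len
    gid <- sprintf("g%04d", placed)
    genes[[placed]] <- data.frame(
      gene_id = gid, chrom = paste0("chr", chrom_i), strand = strand,
      start = start, end = end,
      tss = if (strand == "+") start else end,
      tts = if (strand == "+") end else start,
      biotype = sample(c("protein_coding", "lncRNA", "other"), 1,
                       prob = c(0.7, 0.2, 0.1)),
      stringsAsFactors = FALSE)
    # exons spread along the body: one exon of 150-400 bp per equal slot
    n_ex <- sample(3:8, 1)
    slot <- len / n_ex
    ex <- lapply(seq_len(n_ex) - 1, function(k) {
      elen <- round(stats::runif(1, 150, min(400, slot)))
      s <- round(k * slot + stats::runif(1, 0, slot - elen))
      c(s, s + elen)
    })
    em <- do.call(rbind, ex)
    exons[[placed]] <- data.frame(
      gene_id = gid, chrom = paste0("chr", chrom_i), strand = strand,
      start = if (strand == "+") start + em[, 1] else end - em[, 2],
      end = if (strand == "+") start + em[, 2] else end - em[, 1],
      stringsAsFactors = FALSE)
    cursor <- end + cfg$intergenic_gap
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  rownames(genes) <- rownames(exons) <- NULL
  escaper <- stats::runif(nrow(genes)) < cfg$uv_escape_fraction
  attr(genes, "escaper") <- stats::setNames(escaper, genes$gene_id)
  list(genes = genes, exons = exons)
}

# Build the deterministic (noise-free) signal of one condition/timepoint.
.sim_base_signal <- function(cfg, genes, front_kb, escaper) {
  lens <- stats::setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                          paste0("chr", seq_len(cfg$n_chromosomes)))
  bin <- cfg$bin_size
  sig <- lapply(lens, function(L) numeric(ceiling(L / bin)))
  add_range <- function(sig_v, s, e, value, replace = FALSE) {
    # assign `value` to bins whose centers fall in [s, e)
    b0 <- .clamp(ceiling((s - bin / 2) / bin), 0, length(sig_v) - 1)
    b1 <- .clamp(floor((e - bin / 2) / bin), 0, length(sig_v) - 1)
    if (b1 >= b0) {
      ix <- (b0:b1) + 1
      sig_v[ix] <- if (replace) value else sig_v[ix] + value
    }
    sig_v
  }
  for (i in seq_len(nrow(genes))) {
    cn <- genes$chrom[i]
    tss <- genes$tss[i]
    L <- abs(genes$tts[i] - genes$tss[i])
    plus <- genes$strand[i] == "+"
    body_level <- cfg$body_baseline
    uv_gene <- !is.null(front_kb)
    if (uv_gene && !escaper[[genes$gene_id[i]]]) {
      body_level <- cfg$body_baseline * cfg$uv_depletion_factor
    }
    span_body <- c(100, L)
    g <- function(d0, d1) if (plus) c(tss + d0, tss + d1) else c(tss - d1, tss - d0)
    b <- g(span_body[1], span_body[2])
    sig[[cn]] <- add_range(sig[[cn]], b[1], b[2], body_level, replace = TRUE)
    if (uv_gene && escaper[[genes$gene_id[i]]]) {
      w_end <- min(front_kb * 1000, L)
      if (w_end > 100) {
        w <- g(100, w_end)
        sig[[cn]] <- add_range(sig[[cn]], w[1], w[2], cfg$wave_height,
                               replace = TRUE)
      }
    }
    p <- g(-60, 100)
    sig[[cn]] <- add_range(sig[[cn]], p[1], p[2], cfg$pause_height,
                           replace = TRUE)
  }
  sig
}

.add_noise <- function(sig, sd, seed) {
  if (sd <= 0) return(sig)
  set.seed(seed)
  lapply(sig, function(v) pmax(0, v + stats::rnorm(length(v), 0, sd)))
}

#' Simulate wave coverage time courses
#'
#' The NO-UV track has the pause peak plus a uniform gene-body baseline. Each
#' +UV track at timepoint t has an enriched plateau (`wave_height`) from the
#' end of the pause region out to `front(t)` and the baseline beyond, for the
#' escaping genes; non-escaping genes get a depleted body. Gaussian noise
#' (`noise_sd`, truncated at 0) is added everywhere.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene table from [sim_annotation()] (with the `escaper`
#'   attribute; a missing attribute means all genes escape).
#' @param timepoints Timepoints (min) to simulate; default all of
#'   `cfg$front_positions_by_time`. Requesting a timepoint absent from the
#'   front map is an error.
#' @return Named list of `CoverageTrack`s: "NO_UV" plus "UV_<t>" per
#'   timepoint; attribute `front_positions` echoes the ground truth (kb).
#' @export
sim_wave_tracks <- function(cfg, genes, timepoints = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  fronts <- cfg$front_positions_by_time
  if (is.null(timepoints)) timepoints <- as.numeric(names(fronts))
  miss <- setdiff(as.character(timepoints), names(fronts))
  if (length(miss)) {
    .stopf("timepoint(s) %s missing from 'front_positions_by_time'",
           paste(miss, collapse = ", "))
  }
  escaper <- attr(genes, "escaper")
  if (is.null(escaper)) {
    escaper <- stats::setNames(rep(TRUE, nrow(genes)), genes$gene_id)
  }
  out <- list()
  sig0 <- .sim_base_signal(cfg, genes, front_kb = NULL, escaper = escaper)
  out[["NO_UV"]] <- coverage_track(
    .add_noise(sig0, cfg$noise_sd, .derive_seed(cfg$seed, 31L)),
    cfg$bin_size, sample_id = "NO_UV")
  for (tp in as.character(timepoints)) {
    sig <- .sim_base_signal(cfg, genes, front_kb = fronts[[tp]],
                            escaper = escaper)
    out[[paste0("UV_", tp)]] <- coverage_track(
      .add_noise(sig, cfg$noise_sd,
                 .derive_seed(cfg$seed, 31L + 7L * as.integer(as.numeric(tp)))),
      cfg$bin_size, sample_id = paste0("UV_", tp))
  }
  attr(out, "front_positions") <- fronts[as.character(timepoints)]
  out
}

#' Plant stalling spikes at upstream TT loci and build a repair track
#'
#' A `stall_fraction` of the TT loci upstream of the front at each timepoint
#' receives a summit of `+stall_amplitude` rpm over a +-`stall_core` bp core
#' on the +UV tracks; downstream loci are untouched. The repair track mirrors
#' the stalled loci with independent amplitude/half-width over a low uniform
#' background. The stalled-locus assignment is drawn once so that the same
#' loci stall across timepoints.
#'
#' @param cfg A [sim_config()].
#' @param tracks Track list from [sim_wave_tracks()].
#' @param tt_loci Locus table from [call_tt_loci()].
#' @param front_by_time Named front positions (kb) per timepoint; defaults to
#'   the tracks' ground truth.
#' @return list(tracks, repair, stalled): augmented tracks, a repair-read
#'   `CoverageTrack`, and the logical stalled-locus ground truth.
#' @export
sim_stalling_and_repair <- function(cfg, tracks, tt_loci,
                                    front_by_time = attr(tracks, "front_positions")) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(front_by_time)) .stopf("'front_by_time' is required")
  if (!nrow(tt_loci)) {
    .warnf("empty TT locus set; tracks returned unchanged")
    return(list(tracks = tracks, repair = NULL,
                stalled = logical(0)))
  }
  set.seed(.derive_seed(cfg$seed, 47L))
  stalled <- stats::runif(nrow(tt_loci)) < cfg$stall_fraction
  spike <- function(sig, loci, amplitude, core, bin) {
    for (i in seq_len(nrow(loci))) {
      cn <- loci$chrom[i]
      ctr <- loci$position[i] + 1
      v <- sig[[cn]]
      b0 <- .clamp(ceiling((ctr - core - bin / 2) / bin), 0, length(v) - 1)
      b1 <- .clamp(floor((ctr + core - bin / 2) / bin), 0, length(v) - 1)
      if (b1 >= b0) v[(b0:b1) + 1] <- v[(b0:b1) + 1] + amplitude
      sig[[cn]] <- v
    }
    sig
  }
  for (tp in names(front_by_time)) {
    key <- paste0("UV_", tp)
    if (is.null(tracks[[key]])) next
    up <- tt_loci$distance_to_tss < front_by_time[[tp]] * 1000
    sel <- tt_loci[up & stalled, , drop = FALSE]
    tracks[[key]]$signal <- spike(tracks[[key]]$signal, sel,
                                  cfg$stall_amplitude, cfg$stall_core,
                                  cfg$bin_size)
  }
  # repair track mirrors the loci stalled at the earliest front, on its own
  # finer bin grid
  tp1 <- names(front_by_time)[1]
  up1 <- tt_loci$distance_to_tss < front_by_time[[tp1]] * 1000
  lens <- stats::setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                          paste0("chr", seq_len(cfg$n_chromosomes)))
  rbin <- cfg$repair_bin_size
  rsig <- lapply(lens, function(L) rep(0.2, ceiling(L / rbin)))
  rsig <- spike(rsig, tt_loci[up1 & stalled, , drop = FALSE],
                cfg$repair_amplitude, cfg$repair_core, rbin)
  rsig <- .add_noise(rsig, cfg$noise_sd / 2, .derive_seed(cfg$seed, 53L))
  repair <- coverage_track(rsig, rbin, sample_id = "XR")
  attr(tracks, "front_positions") <- front_by_time
  list(tracks = tracks, repair = repair, stalled = stalled)
}

#' Simulate a bimodal expression table
#'
#' log2 RPKM drawn from a two-component Gaussian mixture; component
#' membership (1 = low/NE component) is recorded as ground truth.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene table.
#' @return data.frame gene_id, rpkm, component.
#' @export
sim_expression <- function(cfg, genes) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.derive_seed(cfg$seed, 61L))
  mx <- cfg$expression_mixture
  comp <- ifelse(stats::runif(nrow(genes)) < mx$weight, 1L, 2L)
  lg <- stats::rnorm(nrow(genes), mx$means[comp], mx$sds[comp])
  data.frame(gene_id = genes$gene_id, rpkm = 2^lg, component = comp,
             stringsAsFactors = FALSE)
}

#' Enumerate signature context sites within gene bodies
#'
#' Positions (0-based, mutated base) of the signature's trinucleotide motifs
#' on the reference strand within each gene's profiled span, with the
#' strand label (TS/NTS) the emitted mutation will carry given the gene
#' strand.
#'
#' @param genome `DNAStringSet`.
#' @param genes Gene table.
#' @param signature "UV" or "smoking".
#' @param span Scan span downstream of the TSS (bp).
#' @return data.frame gene_id, chrom, pos, ref, alt, class, strand_label.
#' @export
find_context_sites <- function(genome, genes, signature = c("UV", "smoking"),
                               span = 60000) {
  signature <- match.arg(signature)
  sig <- .SIGNATURES[[signature]]
  out <- list()
  for (i in seq_len(nrow(genes))) {
    cn <- genes$chrom[i]
    L <- length(genome[[cn]])
    plus <- genes$strand[i] == "+"
    lo <- if (plus) genes$tss[i] else max(genes$tss[i] - min(span, abs(genes$tss[i] - genes$tts[i])), 0)
    hi <- if (plus) min(genes$tss[i] + min(span, abs(genes$tts[i] - genes$tss[i])), L) else genes$tss[i]
    if (hi - lo < 3) next
    sub <- Biostrings::subseq(genome[[cn]], lo + 1, hi)
    for (cls in names(sig$contexts)) {
      motif <- sig$contexts[[cls]]
      m <- IRanges::start(Biostrings::matchPattern(motif, sub))
      if (!length(m)) next
      pos <- lo + m           # 0-based center = lo + (m - 1) + 1
      ref <- substr(cls, 1, 1)
      alt <- substr(cls, 3, 3)
      adduct_on_plus <- cls %in% c("C>T", "G>T")
      lab <- if (plus == adduct_on_plus) "NTS" else "TS"
      out[[length(out) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], chrom = cn, pos = pos, ref = ref,
        alt = alt, class = cls, strand_label = lab, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), chrom = character(), pos = numeric(),
               ref = character(), alt = character(), class = character(),
               strand_label = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Simulate a mutation catalog with expression-dependent, strand-asymmetric rates
#'
#' Per gene and strand, mutation counts are Poisson with rate (per Mb per
#' sample) `mutation_rate_NE` on both strands of non-expressed genes and
#' `mutation_rate_E` (NTS) / `mutation_rate_E * ts_nts_asymmetry` (TS) on
#' expressed genes; positions are drawn from genuine signature context sites
#' so the context filter has true positives by construction. Genes with no
#' eligible context position are skipped with a log entry.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene table.
#' @param expression Table from [sim_expression()] (component 1 = NE).
#' @param genome `DNAStringSet` (ignored when `sites` is given).
#' @param signature "UV" or "smoking".
#' @param span Profiled span (bp).
#' @param sites Optional precomputed [find_context_sites()] table.
#' @return Catalog data.frame in the 7-column layout (1-based positions);
#'   attributes `expressed` (named logical) and `truth` (rates used).
#' @export
sim_mutations <- function(cfg, genes, expression, genome = NULL,
                          signature = c("UV", "smoking"), span = 60000,
                          sites = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  signature <- match.arg(signature)
  if (is.null(sites)) {
    if (is.null(genome)) .stopf("either 'genome' or 'sites' is required")
    sites <- find_context_sites(genome, genes, signature, span)
  }
  set.seed(.derive_seed(cfg$seed, 71L))
  expressed <- stats::setNames(expression$component == 2L, expression$gene_id)
  glen_mb <- stats::setNames(pmin(abs(genes$tts - genes$tss), span) / 1e6,
                             genes$gene_id)
  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    gsites <- sites[sites$gene_id == gid, , drop = FALSE]
    if (!nrow(gsites)) { skipped <- skipped + 1L; next }
    for (lab in c("TS", "NTS")) {
      rate <- if (!expressed[[gid]]) cfg$mutation_rate_NE
              else if (lab == "NTS") cfg$mutation_rate_E
              else cfg$mutation_rate_E * cfg$ts_nts_asymmetry
      n <- stats::rpois(1, rate * glen_mb[[gid]] * cfg$n_samples)
      if (n == 0) next
      pool <- gsites[gsites$strand_label == lab, , drop = FALSE]
      if (!nrow(pool)) next
      pick <- pool[sample.int(nrow(pool), n, replace = TRUE), , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        sample = sample(samples, n, replace = TRUE), type = "subs",
        chrom = pick$chrom, start = pick$pos + 1, end = pick$pos + 1,
        ref = pick$ref, alt = pick$alt, stringsAsFactors = FALSE)
    }
  }
  if (skipped) message("sim_mutations: skipped ", skipped,
                       " gene(s) with no eligible context position")
  cat <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(), type = character(), chrom = character(),
               start = numeric(), end = numeric(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  rownames(cat) <- NULL
  attr(cat, "expressed") <- expressed
  attr(cat, "truth") <- list(rate_NE = cfg$mutation_rate_NE,
                             rate_E_NTS = cfg$mutation_rate_E,
                             rate_E_TS = cfg$mutation_rate_E * cfg$ts_nts_asymmetry,
                             signature = signature)
  cat
}
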