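# Determinism, stated-world structure and round-trips of the generators.

test_that("generators are byte-identical under a fixed seed and differ across seeds", {
  cfg1 <- test_cfg(seed = 1)
  cfg1b <- test_cfg(seed = 1)
  cfg2 <- test_cfg(seed = 2)
  expect_identical(as.character(sim_genome(cfg1)), as.character(sim_genome(cfg1b)))
  expect_false(identical(as.character(sim_genome(cfg1)),
                         as.character(sim_genome(cfg2))))
  a1 <- sim_annotation(cfg1); a1b <- sim_annotation(cfg1b)
  expect_identical(a1, a1b)
  t1 <- sim_wave_tracks(cfg1, a1$genes)
  t1b <- sim_wave_tracks(cfg1b, a1b$genes)
  expect_identical(t1, t1b)
  e1 <- sim_expression(cfg1, a1$genes)
  expect_identical(e1, sim_expression(cfg1b, a1$genes))
  g1 <- sim_genome(cfg1)
  suppressMessages({
    m1 <- sim_mutations(cfg1, a1$genes, e1, g1)
    m1b <- sim_mutations(cfg1b, a1$genes, e1, g1)
  })
  expect_identical(m1, m1b)
})

test_that("sim_config validates its invariants", {
  expect_error(test_cfg(chrom_length = -5), "non-positive")
  expect_error(test_cfg(front_positions_by_time = c("30" = 10, "60" = 5)),
               "non-decreasing")
  expect_error(test_cfg(ts_nts_asymmetry = 1.5), "asymmetry")
  expect_error(test_cfg(mutation_rate_NE = -1), ">= 0")
  expect_error(test_cfg(base_probs = c(A = 1, C = 0, G = 0, X = 0)),
               "base_probs")
})

test_that("base composition controls motif content", {
  cfg <- test_cfg(base_probs = c(A = 1, C = 0, G = 0, T = 0),
                  n_genes = 2, gene_length_range = c(3e4, 4e4))
  g <- sim_genome(cfg)
  expect_equal(as.character(Biostrings::uniqueLetters(g[[1]])), "A")
  ann <- sim_annotation(cfg)
  # no C/G/T anywhere: the XTTX motif cannot occur on either strand
  expect_equal(nrow(call_tt_loci(g, ann$genes)), 0)
})

test_that("annotation respects spacing and capacity constraints", {
  cfg <- test_cfg()
  ann <- sim_annotation(cfg)
  expect_equal(nrow(ann$genes), cfg$n_genes)
  tss <- sort(ann$genes$tss)
  expect_true(all(diff(tss) >= 1000))
  expect_true(all(ann$genes$end <= cfg$chrom_length))
  expect_true(all(table(ann$exons$gene_id) >= 1))
  expect_error(sim_annotation(test_cfg(gene_length_range = c(6e5, 7e5))),
               "do not fit")
  expect_error(sim_wave_tracks(cfg, ann$genes, timepoints = 999),
               "missing from")
})

test_that("wave tracks have the stated two-level anatomy", {
  cfg <- test_cfg(seed = 4, noise_sd = 0, uv_escape_fraction = 1,
                  front_positions_by_time = c("60" = 10))
  ann <- sim_annotation(cfg)
  tr <- sim_wave_tracks(cfg, ann$genes)
  g <- ann$genes[1, ]
  at <- function(track, offset) {
    pos <- if (g$strand == "+") g$tss + offset else g$tss - offset
    mean_density(track, g$chrom, pos - 25, pos + 25)
  }
  # +UV at 60 min: wave height at 5 kb, baseline at 15 kb
  expect_equal(at(tr$UV_60, 5000), cfg$wave_height)
  expect_equal(at(tr$UV_60, 15000), cfg$body_baseline)
  # pause peak present in all conditions over -60..+100
  expect_equal(at(tr$NO_UV, 25), cfg$pause_height)
  expect_equal(at(tr$UV_60, 25), cfg$pause_height)
  # NO-UV body is uniform baseline
  expect_equal(at(tr$NO_UV, 5000), cfg$body_baseline)

  # with noise: NO-UV body mean within 3 SE of the configured baseline
  cfgn <- test_cfg(seed = 8, noise_sd = 0.5)
  annn <- sim_annotation(cfgn)
  trn <- sim_wave_tracks(cfgn, annn$genes)
  gg <- annn$genes[1, ]
  body <- genebody_region(gg)
  n_bins <- (body$end - body$start) / cfgn$bin_size
  se <- cfgn$noise_sd / sqrt(n_bins)
  expect_lt(abs(mean_density(trn$NO_UV, gg$chrom, body$start, body$end) -
                  cfgn$body_baseline), 3 * se + 0.05)
})

test_that("stalling spikes land only on upstream loci; fraction 0 is null", {
  cfg <- test_cfg(seed = 12, noise_sd = 0, stall_fraction = 1,
                  front_positions_by_time = c("120" = 25))
  genome <- sim_genome(cfg)
  ann <- sim_annotation(cfg)
  tr <- sim_wave_tracks(cfg, ann$genes)
  loci <- exclude_ppp_proximal(call_tt_loci(genome, ann$genes))
  sr <- sim_stalling_and_repair(cfg, tr, loci)
  expect_true(all(sr$stalled))
  m <- locus_window_matrix(sr$tracks$UV_120, loci)
  sc <- sf_scores(m)
  lo_sorted <- loci[order(loci$distance_to_tss), ]
  d <- lo_sorted$distance_to_tss
  gene_len <- abs(ann$genes$tts - ann$genes$tss)[
    match(lo_sorted$gene_id, ann$genes$gene_id)]
  up <- d < 25000
  # keep loci whose window cannot straddle the front, the gene end, or
  # another locus's spike core
  iso <- c(diff(d) > 800, TRUE) & c(TRUE, diff(d) > 800)
  clean_up <- up & d < 25000 - 500 & iso
  clean_down <- !up & d < gene_len - 500 & iso
  expect_gt(sum(clean_up), 0)
  expect_equal(unname(sc$score[clean_up]),
               rep(cfg$stall_amplitude, sum(clean_up)))
  expect_equal(mean(sc$score[clean_down]), 0, tolerance = 1e-9)

  # stall_fraction 0: upstream and downstream indistinguishable
  cfg0 <- test_cfg(seed = 13, noise_sd = 0.5, stall_fraction = 0,
                   front_positions_by_time = c("120" = 25))
  tr0 <- sim_wave_tracks(cfg0, ann$genes)
  sr0 <- sim_stalling_and_repair(cfg0, tr0, loci)
  m0 <- locus_window_matrix(sr0$tracks$UV_120, loci)
  sc0 <- sf_scores(m0)
  p <- stats::wilcox.test(sc0$score[up], sc0$score[!up])$p.value
  expect_gt(p, 0.05)

  # empty locus set: warning, tracks unchanged
  expect_warning(sr_empty <- sim_stalling_and_repair(cfg, tr, loci[0, ]),
                 "empty")
  expect_identical(sr_empty$tracks, tr)
})

test_that("expression mixture is bimodal with recoverable membership", {
  cfg <- sim_config(seed = 3, n_chromosomes = 4, chrom_length = 2e6,
                    n_genes = 120, gene_length_range = c(1e4, 3e4))
  ann <- sim_annotation(cfg)
  expr <- sim_expression(cfg, ann$genes)
  thr <- expression_threshold(expr$rpkm)
  expect_gt(thr$threshold, -2)
  expect_lt(thr$threshold, 2)
  called_ne <- log2(expr$rpkm + 0.01) < thr$threshold
  expect_gte(mean(called_ne == (expr$component == 1)), 0.95)
})

test_that("null mutation world gives a TS/NTS ratio near 1", {
  cfg <- sim_config(seed = 21, n_chromosomes = 4, chrom_length = 1e6,
                    n_genes = 60, gene_length_range = c(1e4, 3e4),
                    ts_nts_asymmetry = 1, mutation_rate_E = 50,
                    mutation_rate_NE = 50, n_samples = 10)
  genome <- sim_genome(cfg)
  ann <- sim_annotation(cfg)
  expr <- sim_expression(cfg, ann$genes)
  suppressMessages({
    cat_tab <- sim_mutations(cfg, ann$genes, expr, genome)
    rec <- assign_strand(filter_context(select_signature(
      parse_catalog(cat_tab), "UV"), genome, "UV"), ann$genes)
  })
  ratio <- sum(rec$strand_label == "TS") / sum(rec$strand_label == "NTS")
  expect_equal(ratio, 1, tolerance = 0.1)
})

test_that("generated files round-trip through the package readers", {
  cfg <- test_cfg(seed = 6, n_genes = 3, chrom_length = 2e5,
                  gene_length_range = c(3e4, 5e4))
  genome <- sim_genome(cfg)
  ann <- sim_annotation(cfg)
  td <- withr::local_tempdir()

  f_fa <- file.path(td, "genome.fa")
  write_genome_fasta(genome, f_fa)
  expect_identical(as.character(read_genome_fasta(f_fa)), as.character(genome))

  tr <- sim_wave_tracks(cfg, ann$genes)
  f_bg <- file.path(td, "track.bedGraph")
  write_bedgraph(tr$NO_UV, f_bg)
  back <- read_bedgraph(f_bg)
  expect_equal(back$signal, tr$NO_UV$signal, tolerance = 1e-12)
  expect_equal(back$bin_size, tr$NO_UV$bin_size)

  f_bed <- file.path(td, "genes.bed")
  write_bed6(data.frame(chrom = ann$genes$chrom, start = ann$genes$start,
                        end = ann$genes$end, name = ann$genes$gene_id,
                        score = 0, strand = ann$genes$strand), f_bed)
  bed <- read_bed6(f_bed)
  expect_equal(bed$start, ann$genes$start)
  expect_equal(bed$name, ann$genes$gene_id)
  expect_equal(bed$strand, ann$genes$strand)

  expr <- sim_expression(cfg, ann$genes)
  f_rpkm <- file.path(td, "rpkm.tsv")
  write_rpkm_table(expr[, c("gene_id", "rpkm")], f_rpkm)
  expect_equal(read_rpkm_table(f_rpkm)$rpkm, expr$rpkm, tolerance = 1e-12)
})

test_that("peak reader applies the significance filters", {
  td <- withr::local_tempdir()
  f <- file.path(td, "peaks.narrowPeak")
  # 10-column rows: one passing, one weak fold change, one weak q-value
  rows <- data.frame(chrom = "chr1", start = c(100, 500, 900),
                     end = c(200, 600, 1000), name = paste0("p", 1:3),
                     score = 100, strand = ".",
                     fc = c(3, 0.8, 3), p = 9, q = c(9, 9, 0.5), summit = 50)
  utils::write.table(rows, f, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  expect_message(pk <- read_peaks(f), "filtered out 2")
  expect_equal(pk$start, 100)
})
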