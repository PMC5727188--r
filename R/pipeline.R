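# End-to-end orchestration on a synthetic bundle: deterministic, resumable,
# with a JSON run manifest echoing every parameter.

.PIPELINE_KEYS <- c("seed", "outdir", "sim", "timepoints", "metagene_bin",
                    "locus_flank", "locus_bin", "min_run", "smooth_bins",
                    "ppp_exclusion", "fc_threshold", "signature", "span",
                    "window")

#' Default pipeline configuration
#'
#' @param seed Master seed (propagated to the simulation config).
#' @param outdir Output directory for stage TSVs and the manifest.
#' @param ... Overrides for [sim_config()] fields, passed under `sim`.
#' @return Named list accepted by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("wavescape_run_"),
                            ...) {
  list(seed = seed, outdir = outdir, sim = list(...),
       timepoints = NULL, metagene_bin = 200, locus_flank = 400,
       locus_bin = 50, min_run = 3, smooth_bins = 3, ppp_exclusion = 2000,
       fc_threshold = 2, signature = "UV", span = 60000, window = 2000)
}

#' Run the full synthetic analysis pipeline
#'
#' Stages, in dependency order: simulate (genome, annotation, tracks,
#' expression, mutations) -> escape indexes and shift test -> composite wave
#' fronts and elongation rates -> TT loci -> stalling scores and cluster
#' statistics -> mutation prevalence and comparisons. Each stage writes a
#' TSV under `config$outdir`; a stage whose output file already exists is
#' skipped unless `force = TRUE` (resume semantics). A JSON manifest records
#' package version, every configuration value and the md5 of every output.
#'
#' Unknown configuration keys are rejected by name.
#'
#' @param config List from [pipeline_config()] (or a path to a JSON file with
#'   the same keys).
#' @param force Recompute stages whose outputs exist.
#' @return Invisible list of in-memory stage results plus `manifest` path.
#' @export
run_pipeline <- function(config = pipeline_config(), force = FALSE) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  unknown <- setdiff(names(config), .PIPELINE_KEYS)
  if (length(unknown)) {
    .stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  defaults <- pipeline_config(seed = config$seed %||% 1L)
  for (k in setdiff(.PIPELINE_KEYS, names(config))) config[[k]] <- defaults[[k]]
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(config$outdir, name)
  done <- function(name) file.exists(outfile(name)) && !force
  results <- list()

  cfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  genome <- sim_genome(cfg)
  ann <- sim_annotation(cfg)
  genes <- ann$genes
  if (!done("genes.tsv")) write_gene_table(genes, outfile("genes.tsv"))
  tracks <- sim_wave_tracks(cfg, genes, config$timepoints)
  fronts_truth <- attr(tracks, "front_positions")

  # escape indexes and the UV escape-shift test
  if (!done("escape.tsv")) {
    ei_ref <- escape_index(tracks$NO_UV, genes)
    tp1 <- names(fronts_truth)[1]
    ei_uv <- escape_index(tracks[[paste0("UV_", tp1)]], genes)
    dei <- delta_ei(ei_uv, ei_ref)
    shift <- escape_shift_test(dei)
    write_gene_table(dei, outfile("escape.tsv"))
    results$escape_shift <- shift
  }

  # composite wave fronts and elongation rates
  if (!done("waves.tsv")) {
    big <- genes[abs(genes$tts - genes$tss) >= config$span, , drop = FALSE]
    anchors <- data.frame(id = big$gene_id, chrom = big$chrom, pos = big$tss,
                          strand = big$strand)
    fronts <- vapply(names(fronts_truth), function(tp) {
      m <- density_matrix(tracks[[paste0("UV_", tp)]], anchors, flank = 0,
                          bin_size = config$metagene_bin, flank_up = 0,
                          flank_down = config$span)
      prof <- average_profile(m, config$smooth_bins)
      thr <- wave_threshold(prof,
                            plateau_window = c(1000, 4000),
                            baseline_window = c(config$span - 10000, config$span))
      wave_front(prof, thr$threshold, config$min_run)
    }, numeric(1))
    pos <- data.frame(time = as.numeric(names(fronts_truth)),
                      position_kb = as.numeric(fronts))
    rates <- elongation_rate(pos)
    wave_tab <- data.frame(pos, truth_kb = as.numeric(fronts_truth))
    write_gene_table(wave_tab, outfile("waves.tsv"))
    write_gene_table(rates, outfile("rates.tsv"))
    results$fronts <- pos
    results$rates <- rates
  }

  # TT loci + stalling
  loci <- call_tt_loci(genome, genes)
  loci <- exclude_ppp_proximal(loci, config$ppp_exclusion)
  if (!done("tt_loci.bed")) {
    write_bed6(data.frame(chrom = loci$chrom, start = loci$position,
                          end = loci$position + 2, name = loci$gene_id,
                          score = loci$distance_to_tss, strand = loci$strand),
               outfile("tt_loci.bed"))
  }
  if (!done("stalling.tsv") && nrow(loci)) {
    sim_sr <- sim_stalling_and_repair(cfg, tracks, loci)
    tp_last <- names(fronts_truth)[length(fronts_truth)]
    m_uv <- locus_window_matrix(sim_sr$tracks[[paste0("UV_", tp_last)]], loci,
                                flank = config$locus_flank,
                                bin_size = config$locus_bin)
    m_ref <- locus_window_matrix(sim_sr$tracks$NO_UV, loci,
                                 flank = config$locus_flank,
                                 bin_size = config$locus_bin)
    clus <- cluster_loci_by_front(
      loci[order(loci$distance_to_tss), , drop = FALSE],
      fronts_truth[tp_last])
    scores <- sf_scores(m_uv)
    fc <- region_fc(m_uv, m_ref)
    tab <- data.frame(scores, log2_fc = fc$log2_fc, side = clus$side,
                      cluster = clus$cluster)
    write_gene_table(tab, outfile("stalling.tsv"))
    sides <- split(tab$score, tab$side)
    if (length(sides) >= 2) {
      results$stalling_tests <- compare_sf_groups(sides)
    }
  }

  # mutations
  if (!done("prevalence.tsv")) {
    expr <- sim_expression(cfg, genes)
    catalog <- sim_mutations(cfg, genes, expr, genome,
                             signature = config$signature, span = config$span)
    rec <- parse_catalog(catalog)
    rec <- select_signature(rec, config$signature)
    rec <- filter_context(rec, genome, config$signature)
    rec <- assign_strand(rec, genes)
    thr <- expression_threshold(expr$rpkm, min_genes = min(50, nrow(genes)))
    classes <- stratify_expression(expr[, c("gene_id", "rpkm")], thr$threshold)
    prof <- prevalence_profile(rec, genes, classes, cfg$n_samples,
                               window = config$window, span = config$span)
    write_gene_table(prof, outfile("prevalence.tsv"))
    results$prevalence <- prof
  }

  manifest <- list(
    package = "wavescape",
    version = as.character(utils::packageVersion("wavescape")),
    config = config[order(names(config))],
    outputs = local({
      fs <- list.files(config$outdir, full.names = TRUE)
      fs <- fs[!grepl("manifest[.]json$", fs)]
      stats::setNames(as.list(unname(tools::md5sum(fs))), basename(fs))
    }))
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  results$manifest <- outfile("manifest.json")
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
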