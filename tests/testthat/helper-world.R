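# Small fixture builders used across test files.

# A track with a single chromosome and an explicit bin vector.
one_chrom_track <- function(values, bin_size = 50, chrom = "chr1") {
  coverage_track(stats::setNames(list(values), chrom), bin_size)
}

# A uniform track of the given rpm level.
uniform_track <- function(level, n_bins = 400, bin_size = 50, chrom = "chr1") {
  one_chrom_track(rep(level, n_bins), bin_size, chrom)
}

# A step average-profile: `hi` rpm for offsets < step_bp, `lo` beyond.
step_profile <- function(step_bp, hi = 5, lo = 1, bin = 200, span = 40000,
                         noise_sd = 0) {
  offs <- seq(0, span - bin, by = bin)
  v <- ifelse(offs + bin <= step_bp, hi, lo)   # bins fully before the step
  partial <- offs < step_bp & offs + bin > step_bp
  v[partial] <- (hi * (step_bp - offs[partial]) +
                 lo * (offs[partial] + bin - step_bp)) / bin
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  data.frame(offset = offs, value = v)
}

# A minimal curated-style gene table.
gene_row <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                     start = 1000, end = 21000) {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             start = start, end = end,
             tss = if (strand == "+") start else end,
             tts = if (strand == "+") end else start,
             biotype = "protein_coding", stringsAsFactors = FALSE)
}

# Deterministic small simulation config for unit tests; `...` overrides any
# default, including the small-world values set here.
test_cfg <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chromosomes = 1L, chrom_length = 5e5,
         n_genes = 6L, gene_length_range = c(5e4, 7e4)),
    list(...))
  do.call(sim_config, args)
}
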