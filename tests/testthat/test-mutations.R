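# Catalog parsing, signature/context selection, strand assignment,
# prevalence profiles, exome correction, stratification, comparisons.

catalog_row <- function(sample = "S1", chrom = "chr1", pos1 = 100,
                        ref = "C", alt = "T", type = "subs") {
  data.frame(sample, type, chrom, pos1, pos1, ref, alt)
}

test_that("parse_catalog keeps substitutions, classifies them, round-trips", {
  tab <- rbind(catalog_row(ref = "C", alt = "T"),
               catalog_row(pos1 = 200, ref = "G", alt = "T"),
               catalog_row(pos1 = 300, ref = "A", alt = "G"),
               catalog_row(pos1 = 400, ref = "TA", alt = "T", type = "indel"))
  expect_message(rec <- parse_catalog(tab), "skipped 1")
  expect_equal(rec$class, c("C>T", "G>T", "other"))
  expect_equal(rec$pos, c(99, 199, 299))
  # round-trip through the on-disk layout
  f <- tempfile(fileext = ".txt")
  write_catalog(rec, f)
  rec2 <- parse_catalog(f)
  expect_equal(rec2[, c("sample", "chrom", "pos", "ref", "alt", "class")],
               rec[, c("sample", "chrom", "pos", "ref", "alt", "class")])
  expect_error(parse_catalog(data.frame(a = 1, b = 2)), "7 columns")
})

test_that("select_signature keeps the canonical substitution pairs", {
  rec <- data.frame(class = c("C>T", "G>T", "G>A", "C>A", "other"))
  expect_equal(select_signature(rec, "UV")$class, c("C>T", "G>A"))
  expect_equal(select_signature(rec, "smoking")$class, c("G>T", "C>A"))
  expect_equal(nrow(select_signature(rec[0, , drop = FALSE], "UV")), 0)
})

test_that("filter_context keeps only the signature trinucleotide motifs", {
  #          0123456789
  g <- Biostrings::DNAStringSet(c(chr1 = "ATCCAGGAAA"))
  # C>T at pos 2 sits in context TCC (bases 1..3) -> kept
  rec <- data.frame(sample = "S1", chrom = "chr1", pos = c(2, 3, 6),
                    ref = c("C", "C", "G"), alt = c("T", "T", "A"),
                    class = c("C>T", "C>T", "G>A"))
  out <- filter_context(rec, g, "UV")
  expect_equal(out$pos, c(2, 6))            # CCA context at pos 3 dropped
  expect_equal(out$context, c("TCC", "GGA"))
  # ref mismatching the genome is dropped with a warning
  bad <- data.frame(sample = "S1", chrom = "chr1", pos = 2, ref = "G",
                    alt = "A", class = "G>A")
  expect_warning(out_bad <- filter_context(bad, g, "UV"), "mismatches")
  expect_equal(nrow(out_bad), 0)
  # context off the chromosome end is dropped with a log entry
  edge <- data.frame(sample = "S1", chrom = "chr1", pos = 0, ref = "A",
                     alt = "T", class = "other")
  expect_message(mutation_context(edge, g), "off a chromosome end")
})

test_that("assign_strand maps adduct strand to TS/NTS by gene orientation", {
  genes <- rbind(gene_row("gp", start = 0, end = 1000),
                 gene_row("gm", strand = "-", start = 2000, end = 3000))
  rec <- data.frame(sample = "S1", chrom = "chr1",
                    pos = c(100, 200, 2100, 2200, 5000),
                    ref = c("G", "C", "G", "C", "C"),
                    alt = c("A", "T", "A", "T", "T"),
                    class = c("G>A", "C>T", "G>A", "C>T", "C>T"))
  out <- assign_strand(rec, genes)
  expect_equal(out$strand_label,
               c("TS", "NTS", "NTS", "TS", "intergenic"))
  # opposite-strand overlapping genes are ambiguous and dropped
  genes2 <- rbind(gene_row("a", start = 0, end = 1000),
                  gene_row("b", strand = "-", start = 500, end = 1500))
  amb <- data.frame(sample = "S1", chrom = "chr1", pos = 600, ref = "G",
                    alt = "A", class = "G>A")
  expect_message(out2 <- assign_strand(amb, genes2), "opposite-strand")
  expect_equal(nrow(out2), 0)
  # same-strand overlap resolves to the nearest TSS
  genes3 <- rbind(gene_row("near", start = 500, end = 2000),
                  gene_row("far", start = 0, end = 2000))
  out3 <- assign_strand(amb, genes3)
  expect_equal(out3$gene_id, "near")
})

test_that("TS/NTS labelling is invariant under genome mirror + strand flip", {
  cfg <- test_cfg(seed = 19, n_genes = 4, chrom_length = 3e5,
                  gene_length_range = c(2e4, 4e4))
  genome <- sim_genome(cfg)
  ann <- sim_annotation(cfg)
  expr <- sim_expression(cfg, ann$genes)
  suppressMessages({
    cat_tab <- sim_mutations(cfg, ann$genes, expr, genome)
    rec <- filter_context(select_signature(parse_catalog(cat_tab), "UV"),
                          genome, "UV")
    out <- assign_strand(rec, ann$genes)
  })
  # mirror the world
  N <- cfg$chrom_length
  rc <- Biostrings::reverseComplement(genome[[1]])
  genome_m <- Biostrings::DNAStringSet(stats::setNames(as.character(rc), "chr1"))
  genes_m <- ann$genes
  genes_m$strand <- ifelse(ann$genes$strand == "+", "-", "+")
  genes_m$start <- N - ann$genes$end
  genes_m$end <- N - ann$genes$start
  genes_m$tss <- ifelse(genes_m$strand == "+", genes_m$start, genes_m$end)
  genes_m$tts <- ifelse(genes_m$strand == "+", genes_m$end, genes_m$start)
  rec_m <- rec
  rec_m$pos <- N - 1 - rec$pos
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rec_m$ref <- unname(comp[rec$ref])
  rec_m$alt <- unname(comp[rec$alt])
  rec_m$class <- paste0(rec_m$ref, ">", rec_m$alt)
  rec_m$context <- NULL
  suppressMessages({
    rec_m <- filter_context(select_signature(rec_m, "UV"), genome_m, "UV")
    out_m <- assign_strand(rec_m, genes_m)
  })
  key <- function(d) d[order(d$pos), "strand_label"]
  expect_equal(nrow(out_m), nrow(out))
  expect_equal(key(transform(out_m, pos = N - 1 - pos)), key(out))
})

test_that("prevalence_profile normalizes counts per Mb per sample", {
  # 30 mutations in one 10 kb window over 6 samples -> 500 /Mb/sample
  g <- gene_row("g1", start = 0, end = 10000)
  rec <- data.frame(sample = rep("S1", 30), chrom = "chr1",
                    pos = sample(1000:9000, 30), ref = "C", alt = "T",
                    class = "C>T", gene_id = "g1", strand_label = "NTS")
  classes <- data.frame(gene_id = "g1", class = "Hi")
  prof <- prevalence_profile(rec, g, classes, n_samples = 6,
                             window = 10000, span = 10000)
  got <- prof[prof$strand == "NTS" & prof$class == "Hi", ]
  expect_equal(got$count, 30)
  expect_equal(got$prevalence, 30 / 6 / (10000 / 1e6))
  expect_equal(prof$count[prof$strand == "TS"], 0)
  # count conservation: sum(count) = records inside the span
  expect_equal(sum(prof$count), 30)
})

test_that("exon_density_correction divides by exon fraction with masking", {
  g <- gene_row("g1", start = 0, end = 50000)
  # exons covering 4% of the first window
  exons <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 0, end = 400, ord = 1, exon_id = "e1")
  classes <- data.frame(gene_id = "g1", class = "Hi")
  rec <- data.frame(sample = "S1", chrom = "chr1", pos = c(100, 300),
                    ref = "C", alt = "T", class = "C>T", gene_id = "g1",
                    strand_label = "NTS")
  prof <- prevalence_profile(rec, g, classes, n_samples = 1,
                             window = 10000, span = 50000)
  out <- exon_density_correction(prof, exons, g, classes,
                                 window = 10000, span = 50000)
  w1 <- out[out$window_start == 0 & out$strand == "NTS", ]
  expect_equal(w1$exon_fraction, 0.04)
  expect_equal(w1$corrected, w1$prevalence / 0.04)
  # zero exon coverage is masked, never divided
  w2 <- out[out$window_start == 10000 & out$strand == "NTS", ]
  expect_true(is.na(w2$corrected))
  # exon fraction 1 leaves prevalence unchanged
  ex_full <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                        start = 0, end = 50000, ord = 1, exon_id = "e1")
  out2 <- exon_density_correction(prof, ex_full, g, classes,
                                  window = 10000, span = 50000)
  expect_equal(out2$corrected, out2$prevalence)
})

test_that("stratify_expression cuts expressed genes into balanced terciles", {
  rpkm <- data.frame(gene_id = sprintf("g%03d", 1:351),
                     rpkm = c(rep(0.001, 50), seq(2, 100, length.out = 301)))
  out <- stratify_expression(rpkm, threshold = 0)
  expect_equal(unname(table(out$class)["NE"]), 50)
  expect_equal(as.numeric(sort(table(out$class)[c("Hi", "Med", "Lo")],
                               decreasing = TRUE)), c(101, 100, 100))
  # all genes below threshold -> all NE
  out2 <- stratify_expression(data.frame(gene_id = "a", rpkm = 0.001), 0)
  expect_equal(as.character(out2$class), "NE")
})

test_that("moving averages and binned comparisons follow their contracts", {
  expect_equal(moving_average_by_rank(c(1, 2, 3, 4, 5), 1:5, 1)$value,
               c(1, 2, 3, 4, 5))
  expect_equal(moving_average_by_rank(c(1, 2, 3, 4, 5), 1:5, 3)$value,
               c(1.5, 2, 3, 4, 4.5))
  expect_equal(moving_average_by_rank(rep(7, 10), 10:1, 4)$value, rep(7, 10))

  # 45 genes -> 3 bins of 15
  pg <- data.frame(gene_id = sprintf("g%02d", 1:45), class = "Hi",
                   rank = 1:45, count = rpois(45, 3), covered_mb = 0.05)
  bc <- binned_comparison(pg, n_samples = 10)
  expect_equal(nrow(bc$bins), 3)
  expect_equal(bc$bins$n_genes, rep(15, 3))
  expect_equal(sum(bc$bins$count), sum(pg$count))
})
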