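# Transcript curation, exon merging, promoter/gene-body regions, controls.

tx <- function(id, start, end, strand = "+", chrom = "chr1",
               biotype = "protein_coding") {
  data.frame(id = id, chrom = chrom, strand = strand, start = start,
             end = end, biotype = biotype, stringsAsFactors = FALSE)
}

test_that("curate_transcripts applies the collapse and exclusion rules", {
  # two isoforms 100 bp apart: keep the 8 kb one
  raw <- rbind(tx("short", 10000, 15000), tx("long", 10100, 18100))
  out <- curate_transcripts(raw)
  expect_equal(out$gene_id, "long")

  # two distinct genes with inter-TSS distance 800 bp: both excluded
  raw2 <- rbind(tx("a", 10000, 15000), tx("b", 10800, 20800))
  expect_equal(nrow(curate_transcripts(raw2)), 0)

  # non-coding biotypes are dropped before distance rules
  raw3 <- rbind(tx("a", 10000, 15000), tx("rna", 10800, 20800, biotype = "other"))
  expect_equal(curate_transcripts(raw3)$gene_id, "a")

  # malformed coordinates are a hard error naming the row
  raw4 <- tx("bad", 5000, 5000)
  expect_error(curate_transcripts(raw4), "malformed")

  # missing biotype dropped with a warning
  raw5 <- rbind(tx("a", 10000, 15000), tx("nob", 50000, 60000, biotype = NA))
  expect_warning(out5 <- curate_transcripts(raw5), "missing biotype")
  expect_equal(out5$gene_id, "a")
})

test_that("curate_transcripts equals the brute-force oracle and is idempotent", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30
    raw <- tx(sprintf("t%02d", 1:n),
              start = sample.int(60000, n),
              end = 0, strand = sample(c("+", "-"), n, replace = TRUE),
              biotype = sample(c("protein_coding", "lncRNA", "other"), n,
                               replace = TRUE))
    raw$end <- raw$start + sample(500:8000, n, replace = TRUE)
    out <- curate_transcripts(raw)
    expect_equal(out$gene_id, oracle_curate(raw)$id)
    # idempotence: re-curating the curated set changes nothing
    again <- curate_transcripts(data.frame(id = out$gene_id, chrom = out$chrom,
                                           strand = out$strand,
                                           start = out$start, end = out$end,
                                           biotype = out$biotype))
    expect_equal(again$gene_id, out$gene_id)
  }
})

test_that("merge_exons merges with 1 bp gap tolerance and drops strand clashes", {
  g <- rbind(gene_row("g1", start = 0, end = 1000),
             gene_row("g2", start = 2000, end = 3000))
  ex <- data.frame(gene_id = c("g1", "g1", "g2", "g2"),
                   chrom = "chr1", strand = "+",
                   start = c(100, 150, 2100, 2200),
                   end = c(200, 300, 2200, 2300))
  out <- merge_exons(g, ex)
  g1 <- out[out$gene_id == "g1", ]
  expect_equal(c(g1$start, g1$end), c(100, 300))        # overlap merged
  g2 <- out[out$gene_id == "g2", ]
  expect_equal(c(g2$start, g2$end), c(2100, 2300))      # book-ended merged

  # opposite-strand exon overlap removes both parent genes
  g3 <- rbind(gene_row("p", start = 0, end = 1000),
              gene_row("m", start = 0, end = 1000, strand = "-"))
  ex3 <- data.frame(gene_id = c("p", "m"), chrom = "chr1",
                    strand = c("+", "-"),
                    start = c(100, 150), end = c(200, 250))
  expect_message(out3 <- merge_exons(g3, ex3), "opposite-strand")
  expect_equal(nrow(out3), 0)
  expect_setequal(attr(out3, "dropped_genes"), c("p", "m"))
})

test_that("merged exon sets have no same-strand overlaps and 5'->3' ordinals", {
  set.seed(21)
  g <- gene_row("gm", strand = "-", start = 0, end = 50000)
  starts <- sort(sample.int(49000, 30))
  ex <- data.frame(gene_id = "gm", chrom = "chr1", strand = "-",
                   start = starts, end = starts + sample(50:2000, 30, TRUE))
  out <- merge_exons(g, ex)
  o <- out[order(out$start), ]
  expect_true(all(diff(o$start) > 0))
  expect_true(all(o$start[-1] > o$end[-nrow(o)] + 1))   # sweep: gaps > 1 bp
  # minus-strand ordinals decrease with genomic coordinate
  expect_equal(out$ord[order(-out$end)], seq_len(nrow(out)))
})

test_that("promoter and gene-body regions follow strand-aware offsets", {
  gp <- gene_row("gp", start = 10000, end = 30000)
  gm <- gene_row("gm", strand = "-", start = 2000, end = 10000)
  pp <- promoter_region(gp)
  pm <- promoter_region(gm)
  expect_equal(c(pp$start, pp$end), c(9750, 10100))
  expect_equal(c(pm$start, pm$end), c(9900, 10250))

  bp <- genebody_region(gp)
  expect_equal(c(bp$start, bp$end), c(10101, 12000))
  # short + gene truncates at the TTS
  gs <- gene_row("gs", start = 0, end = 1500)
  bs <- genebody_region(gs)
  expect_equal(c(bs$start, bs$end), c(101, 1500))
  # sub-102 bp gene: body undefined, flagged
  expect_message(bu <- genebody_region(gene_row("tiny", start = 0, end = 80)),
                 "no defined gene body")
  expect_false(bu$defined)

  # promoter and body never overlap for the same gene
  set.seed(2)
  for (k in 1:20) {
    st <- sample(3000:50000, 1)
    gr <- gene_row("gx", strand = sample(c("+", "-"), 1), start = st,
                   end = st + sample(200:30000, 1))
    p <- promoter_region(gr); b <- genebody_region(gr)
    if (b$defined) expect_true(p$end <= b$start || b$end <= p$start)
  }
})

test_that("exon-start controls follow substring vs ordinal semantics", {
  # one gene with 25 exons e1..e25
  starts <- seq(0, by = 400, length.out = 25)
  g <- gene_row("g25", start = 0, end = 11000)
  ex <- data.frame(gene_id = "g25", chrom = "chr1", strand = "+",
                   start = starts, end = starts + 200)
  me <- merge_exons(g, ex)
  sub <- select_exon_start_controls(me, "substring_e2")
  expect_equal(sort(sub$exon_id),
               sort(c("e2", paste0("e2", 0:5))))          # 7 loci
  ord <- select_exon_start_controls(me, "ordinal_second")
  expect_equal(ord$exon_id, "e2")
  expect_equal(ord$pos, 400)                               # 5' boundary
  # single-exon gene contributes nothing
  me1 <- merge_exons(gene_row("g1", start = 0, end = 1000),
                     data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                                start = 10, end = 100))
  expect_equal(nrow(select_exon_start_controls(me1)), 0)
})
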