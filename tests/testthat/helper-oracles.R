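# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and its interval/string libraries): plain loops and base R.

# Base-level mean of a binned signal over [start, end), one base at a time.
oracle_region_mean <- function(signal, bin_size, start, end) {
  bases <- seq.int(start, end - 1)
  vals <- vapply(bases, function(b) {
    i <- b %/% bin_size + 1
    if (i <= length(signal)) signal[i] else 0
  }, numeric(1))
  mean(vals)
}

# Per-bin full-overlap read counts.
oracle_bin_counts <- function(reads, bin_size, n_bins) {
  counts <- numeric(n_bins)
  for (r in seq_len(nrow(reads))) {
    for (b in seq_len(n_bins)) {
      bs <- (b - 1) * bin_size
      if (reads$start[r] < bs + bin_size && reads$end[r] > bs) {
        counts[b] <- counts[b] + 1
      }
    }
  }
  counts
}

# Exhaustive application of the transcript curation rules.
oracle_curate <- function(raw, collapse_dist = 500, exclude_dist = 1000) {
  raw <- raw[raw$biotype %in% c("protein_coding", "lncRNA"), , drop = FALSE]
  raw$tss <- ifelse(raw$strand == "+", raw$start, raw$end)
  raw$len <- raw$end - raw$start
  # collapse: connected components of the pairwise same-chrom/strand
  # |dTSS| < dist relation; keep the longest member (ties: smallest id)
  n <- nrow(raw)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (raw$chrom[i] == raw$chrom[j] && raw$strand[i] == raw$strand[j] &&
            abs(raw$tss[i] - raw$tss[j]) < collapse_dist &&
            comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  winners <- vapply(unique(comp), function(cc) {
    ix <- which(comp == cc)
    ix[order(-raw$len[ix], raw$id[ix])][1]
  }, integer(1))
  raw <- raw[sort(winners), , drop = FALSE]
  # exclude any gene with a neighbouring TSS < exclude_dist on the same chrom
  drop <- logical(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    for (j in seq_len(nrow(raw))) {
      if (i != j && raw$chrom[i] == raw$chrom[j] &&
          abs(raw$tss[i] - raw$tss[j]) < exclude_dist) {
        drop[i] <- TRUE
      }
    }
  }
  raw <- raw[!drop, , drop = FALSE]
  raw[order(raw$chrom, raw$tss, raw$id), , drop = FALSE]
}

# Character-level XTTX scan of one gene's template strand, with the
# isolation filter applied by brute force over all raw matches. Works on a
# plain character vector of bases, independent of any sequence library.
oracle_tt_scan <- function(seq_char, tss, tts, strand, max_span = 1e6,
                           min_separation = 70) {
  L <- nchar(seq_char)
  ch <- strsplit(seq_char, "")[[1]]
  if (strand == "+") {
    s <- tss; e <- min(tts, tss + max_span, L)
    p <- if (e - s >= 4) seq.int(s, e - 4) else integer(0)
    # template (-) strand motif X T T X <=> reference-strand B A A B
    hit <- ch[p + 2] == "A" & ch[p + 3] == "A" &
      ch[p + 1] %in% c("C", "G", "T") & ch[p + 4] %in% c("C", "G", "T")
  } else {
    e <- tss; s <- max(tts, tss - max_span, 0)
    p <- if (e - s >= 4) seq.int(s, e - 4) else integer(0)
    hit <- ch[p + 2] == "T" & ch[p + 3] == "T" &
      ch[p + 1] %in% c("A", "C", "G") & ch[p + 4] %in% c("A", "C", "G")
  }
  hits <- p[hit] + 1                    # TT 0-based start
  if (!length(hits)) return(numeric(0))
  keep <- vapply(seq_along(hits), function(i) {
    others <- hits[-i]
    !length(others) || min(abs(others - hits[i])) > min_separation
  }, logical(1))
  hits[keep]
}

# Benjamini-Hochberg step-up by the textbook formula.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# 2x2 chi-square by the closed-form contingency formula.
oracle_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
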