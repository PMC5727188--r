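# Plain-text readers/writers: FASTA, BED6, bedGraph, RPKM tables, peak files.
# All on-disk interval formats are 0-based half-open (BED convention); the
# package's internal convention is identical, so round-trips are lossless.

#' Read / write genome FASTA
#' @param path File path.
#' @return `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_genome_fasta
#' @param genome `DNAStringSet` to write.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' @param df data.frame with chrom, start, end and optionally name, score,
#'   strand columns (missing ones filled with ".", 0, ".").
#' @param path Output path.
#' @export
write_bed6 <- function(df, path) {
  .check_cols(df, c("chrom", "start", "end"), "df")
  name <- if (!is.null(df$name)) df$name else "."
  score <- if (!is.null(df$score)) df$score else 0
  strand <- if (!is.null(df$strand)) df$strand else "."
  out <- data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE),
                    name, score, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 (or BED3+) file
#' @param path File path.
#' @return data.frame chrom, start, end, name, score, strand.
#' @export
read_bed6 <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#")
  if (ncol(tab) < 3) .stopf("BED file needs at least 3 columns")
  out <- data.frame(chrom = tab[[1]], start = as.numeric(tab[[2]]),
                    end = as.numeric(tab[[3]]), stringsAsFactors = FALSE)
  out$name <- if (ncol(tab) >= 4) tab[[4]] else "."
  out$score <- if (ncol(tab) >= 5) suppressWarnings(as.numeric(tab[[5]])) else 0
  out$strand <- if (ncol(tab) >= 6) tab[[6]] else "."
  out
}

#' Write / read a coverage track as bedGraph
#'
#' One line per bin (consecutive equal-value bins are not collapsed, so the
#' bin grid round-trips exactly).
#'
#' @param track A `CoverageTrack`.
#' @param path File path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "CoverageTrack"))
  con <- file(path, "w")
  on.exit(close(con))
  for (cn in names(track$signal)) {
    v <- track$signal[[cn]]
    s <- (seq_along(v) - 1) * track$bin_size
    utils::write.table(
      data.frame(cn, format(s, scientific = FALSE, trim = TRUE),
                 format(s + track$bin_size, scientific = FALSE, trim = TRUE),
                 v),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @param sample_id Sample label for the reconstructed track.
#' @return `read_bedgraph`: a `CoverageTrack` on the file's bin grid.
#' @export
read_bedgraph <- function(path, sample_id = "sample") {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "value"),
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric"))
  bin <- unique(tab$end - tab$start)
  if (length(bin) != 1) .stopf("bedGraph is not on a uniform bin grid")
  sig <- lapply(split(tab, tab$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    v <- numeric(max(d$end) / bin)
    v[d$start / bin + 1] <- d$value
    v
  })
  coverage_track(sig, bin, sample_id = sample_id)
}

#' Write / read gene tables as TSV
#' @param genes Gene table.
#' @param path File path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}

#' Read a peak-caller table, applying significance filters
#'
#' Accepts narrowPeak-style 10-column files (chrom, start, end, name, score,
#' strand, signalValue, pValue, qValue, summit) or plain BED. Peaks are
#' filtered on read: fold change (signalValue) > `fc_min` and FDR
#' (10^-qValue) < `fdr_max`, when those columns exist.
#'
#' @param path File path.
#' @param fdr_max FDR cutoff.
#' @param fc_min Fold-change cutoff (strict >).
#' @return data.frame chrom, start, end (filtered).
#' @export
read_peaks <- function(path, fdr_max = 0.05, fc_min = 1) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#")
  out <- data.frame(chrom = tab[[1]], start = as.numeric(tab[[2]]),
                    end = as.numeric(tab[[3]]), stringsAsFactors = FALSE)
  if (ncol(tab) >= 9) {
    fc <- as.numeric(tab[[7]])
    q <- as.numeric(tab[[9]])
    keep <- fc > fc_min & 10^(-q) < fdr_max
    n_drop <- sum(!keep)
    if (n_drop) message("read_peaks: filtered out ", n_drop,
                        " peak(s) (fc <= ", fc_min, " or fdr >= ", fdr_max, ")")
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write an RPKM table / read it back
#' @param rpkm data.frame gene_id, rpkm.
#' @param path File path.
#' @export
write_rpkm_table <- function(rpkm, path) {
  utils::write.table(rpkm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rpkm_table
#' @export
read_rpkm_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}
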