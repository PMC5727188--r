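# Genome-wide calling of dipyrimidine (XTTX) loci on the template strand of
# active genes, with isolation and promoter-proximal filters, and the
# locus-window density matrices used for stalling / repair scoring.
#
# "Template strand" is the strand RNAPII reads, where a TT photodimer blocks
# elongation: the reference minus strand for '+' genes (so the scan looks for
# the reverse complement of XTTX, i.e. [CGT]AA[CGT] = "BAAB" on the reference)
# and the reference plus strand for '-' genes ("VTTV", V = [ACG]). The X != T
# flanks reject overlapping matches inside TTT runs by construction.

#' Call XTTX dipyrimidine loci in active genes
#'
#' Scans the template strand of each gene from the TSS to
#' `min(TTS, TSS + max_span)` (set `bound_at_tts = FALSE` to use the raw
#' `max_span` window) and reports XTTX motif matches (X in A/C/G). Matches
#' are then isolation-filtered per chromosome: a locus is retained only when
#' no other raw match lies within `min_separation` bp (motif-midpoint
#' distance).
#'
#' @param genome A `DNAStringSet` (or named list of DNAString) of chromosome
#'   sequences.
#' @param genes Gene table (typically the active subset) with gene_id, chrom,
#'   strand, tss, tts.
#' @param max_span Maximum scan distance downstream of the TSS in bp.
#' @param bound_at_tts Stop the scan at the TTS (default) or run the full
#'   `max_span` window.
#' @param min_separation Isolation distance in bp (strict >).
#' @param template_strand Set FALSE to scan the coding strand instead
#'   (interpretation flip for sensitivity checks).
#' @return data.frame chrom, position (0-based start of the TT dinucleotide on
#'   the reference), gene_id, strand (gene strand), distance_to_tss (bp, to
#'   the TT midpoint in transcription orientation).
#' @export
call_tt_loci <- function(genome, genes, max_span = 1e6, bound_at_tts = TRUE,
                         min_separation = 70, template_strand = TRUE) {
  .check_cols(genes, c("gene_id", "chrom", "strand", "tss", "tts"), "genes")
  .check_strand(genes$strand)
  out <- list()
  for (i in seq_len(nrow(genes))) {
    cn <- genes$chrom[i]
    if (!cn %in% names(genome)) .stopf("chromosome '%s' not in genome", cn)
    L <- length(genome[[cn]])
    tss <- genes$tss[i]; tts <- genes$tts[i]
    if (genes$strand[i] == "+") {
      s <- tss
      e <- min(if (bound_at_tts) tts else Inf, tss + max_span, L)
      if (e > L) { .warnf("gene %s scan truncated at chromosome end", genes$gene_id[i]); e <- L }
    } else {
      e <- tss
      s <- max(if (bound_at_tts) tts else -Inf, tss - max_span, 0)
    }
    if (e - s < 4) next
    sub <- Biostrings::subseq(genome[[cn]], s + 1, e)
    scan_minus <- (genes$strand[i] == "+") == template_strand
    pat <- if (scan_minus) "BAAB" else "VTTV"
    m <- IRanges::start(Biostrings::matchPattern(pat, sub, fixed = FALSE))
    if (!length(m)) next
    motif0 <- s + m - 1                 # 0-based motif start on the reference
    tt0 <- motif0 + 1                   # 0-based TT (ref AA for '+') start
    mid <- tt0 + 1                      # motif midpoint
    dist <- if (genes$strand[i] == "+") mid - tss else tss - mid
    out[[length(out) + 1L]] <- data.frame(
      chrom = cn, position = tt0, gene_id = genes$gene_id[i],
      strand = genes$strand[i], distance_to_tss = dist,
      stringsAsFactors = FALSE)
  }
  loci <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), position = numeric(), gene_id = character(),
               strand = character(), distance_to_tss = numeric(),
               stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  if (!nrow(loci)) return(loci)
  # isolation filter: per chromosome, against all raw matches
  keep <- logical(nrow(loci))
  for (cn in unique(loci$chrom)) {
    ix <- which(loci$chrom == cn)
    o <- ix[order(loci$position[ix])]
    p <- loci$position[o]
    gap_prev <- c(Inf, diff(p))
    gap_next <- c(diff(p), Inf)
    keep[o] <- gap_prev > min_separation & gap_next > min_separation
  }
  loci <- loci[keep, , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

#' Drop loci near the promoter-proximal pause signal
#'
#' Loci closer to the TSS than `exclusion_bp` carry promoter-proximal-pause
#' RNAPII signal unrelated to wave stalling and are excluded.
#'
#' @param loci Locus table from [call_tt_loci()].
#' @param exclusion_bp Minimum distance to TSS (strict: loci with
#'   `distance_to_tss < exclusion_bp` are dropped).
#' @return Filtered locus table.
#' @export
exclude_ppp_proximal <- function(loci, exclusion_bp = 2000) {
  .check_cols(loci, "distance_to_tss", "loci")
  out <- loci[loci$distance_to_tss >= exclusion_bp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locus-centred density matrix, sorted by distance to TSS
#'
#' Delegates to [density_matrix()] with the locus midpoint as anchor and the
#' gene strand as orientation; when a second track is supplied (e.g. the
#' opposite-strand excision reads) both strands are summed before extraction.
#' Rows are sorted by increasing distance to TSS, the display/cluster order of
#' locus heatmaps. Default flanks: 400 bp for ChIP windows, 60 bp for
#' excision-read windows.
#'
#' @param track A `CoverageTrack` (e.g. elongating RNAPII or repair reads).
#' @param loci Locus table from [call_tt_loci()] (or exon-start controls with
#'   a `pos` column and `distance_to_tss`).
#' @param flank Half-window in bp.
#' @param bin_size Matrix bin width in bp.
#' @param track2 Optional second `CoverageTrack` summed onto `track`.
#' @return Density matrix (rows = loci sorted by distance to TSS).
#' @export
locus_window_matrix <- function(track, loci, flank = 400, bin_size = 50,
                                track2 = NULL) {
  .check_cols(loci, c("chrom", "position", "gene_id", "strand",
                      "distance_to_tss"), "loci")
  if (!is.null(track2)) track <- track_sum(track, track2)
  loci <- loci[order(loci$distance_to_tss), , drop = FALSE]
  anchors <- data.frame(
    id = paste0(loci$gene_id, ":", loci$chrom, ":", loci$position),
    chrom = loci$chrom, pos = loci$position + 1, strand = loci$strand,
    stringsAsFactors = FALSE)
  density_matrix(track, anchors, flank = flank, bin_size = bin_size)
}
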