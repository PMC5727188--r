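# Transcript curation, exon merging, and anchor region definitions.
#
# Gene tables use 0-based half-open [start, end) reference coordinates with a
# transcription-oriented convention: tss is the transcription start boundary
# (tss == start for '+' genes, tss == end for '-' genes) and tts the opposite
# boundary. All offsets "downstream of TSS" run in transcription direction.

.BIOTYPES_KEPT <- c("protein_coding", "lncRNA")

#' Curate a raw transcript table into gene models
#'
#' Applies, in order: a biotype pre-filter (protein-coding and lncRNA only),
#' collapsing of isoforms whose TSSs lie within `collapse_dist` of each other
#' (the longest isoform of each collapsed group is kept; ties broken by
#' lexicographic id), and exclusion of remaining genes whose TSS lies within
#' `exclude_dist` of a neighbouring gene's TSS (both members of such a pair
#' are removed, to avoid promoter-proximal read cross-talk).
#'
#' The biotype filter runs first so that non-coding clutter cannot trigger
#' distance exclusions of retained genes; a message is emitted when that
#' ordering changes the outcome relative to filtering last.
#'
#' @param raw data.frame with columns id, chrom, strand, start, end, biotype
#'   (0-based half-open coordinates).
#' @param collapse_dist TSS-collapse distance in bp (same chrom and strand).
#' @param exclude_dist Inter-TSS exclusion distance in bp (same chrom, any
#'   strand).
#' @return data.frame of gene models sorted by (chrom, tss) with columns
#'   gene_id, chrom, strand, start, end, tss, tts, biotype.
#' @export
curate_transcripts <- function(raw, collapse_dist = 500, exclude_dist = 1000) {
  .check_cols(raw, c("id", "chrom", "strand", "start", "end", "biotype"), "raw")
  bad <- which(!is.finite(raw$start) | !is.finite(raw$end) | raw$end <= raw$start |
                 !raw$strand %in% c("+", "-"))
  if (length(bad)) {
    .stopf("malformed coordinates/strand in transcript row(s): %s",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  no_bio <- is.na(raw$biotype) | raw$biotype == ""
  if (any(no_bio)) {
    .warnf("dropping %d transcript(s) with missing biotype", sum(no_bio))
    raw <- raw[!no_bio, , drop = FALSE]
  }
  kept <- raw[raw$biotype %in% .BIOTYPES_KEPT, , drop = FALSE]
  out <- .curate_distance_rules(kept, collapse_dist, exclude_dist)
  # diagnostic: does rule order matter for this input?
  alt <- .curate_distance_rules(raw, collapse_dist, exclude_dist)
  alt <- alt[alt$biotype %in% .BIOTYPES_KEPT, , drop = FALSE]
  if (!identical(sort(out$gene_id), sort(alt$gene_id))) {
    message("note: biotype-first filtering changed the curated set relative to ",
            "biotype-last (", nrow(out), " vs ", nrow(alt), " genes)")
  }
  out
}

.curate_distance_rules <- function(tx, collapse_dist, exclude_dist) {
  if (!nrow(tx)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = numeric(), end = numeric(),
                      tss = numeric(), tts = numeric(), biotype = character(),
                      stringsAsFactors = FALSE))
  }
  tx$tss <- ifelse(tx$strand == "+", tx$start, tx$end)
  tx$len <- tx$end - tx$start
  # (i) collapse nearby TSSs per (chrom, strand); chain clustering, keep longest
  keep <- unlist(lapply(split(seq_len(nrow(tx)), paste(tx$chrom, tx$strand)),
                        function(ix) {
    o <- ix[order(tx$tss[ix], tx$id[ix])]
    grp <- cumsum(c(1, diff(tx$tss[o]) >= collapse_dist))
    unlist(lapply(split(o, grp), function(g) {
      g[order(-tx$len[g], tx$id[g])][1]
    }))
  }), use.names = FALSE)
  tx <- tx[sort(keep), , drop = FALSE]
  # (ii) exclude genes with a neighbouring TSS < exclude_dist (any strand)
  drop <- logical(nrow(tx))
  for (ix in split(seq_len(nrow(tx)), tx$chrom)) {
    o <- ix[order(tx$tss[ix])]
    d <- diff(tx$tss[o])
    close_pair <- d < exclude_dist
    drop[o[c(close_pair, FALSE)]] <- TRUE
    drop[o[c(FALSE, close_pair)]] <- TRUE
  }
  tx <- tx[!drop, , drop = FALSE]
  tx <- tx[order(tx$chrom, tx$tss, tx$id), , drop = FALSE]
  data.frame(gene_id = tx$id, chrom = tx$chrom, strand = tx$strand,
             start = tx$start, end = tx$end, tss = tx$tss,
             tts = ifelse(tx$strand == "+", tx$end, tx$start),
             biotype = tx$biotype, row.names = NULL, stringsAsFactors = FALSE)
}

#' Merge exons per strand and assign transcription-order ordinals
#'
#' Genes owning an exon that overlaps an opposite-strand exon are removed
#' before merging (to avoid ambiguous strand references); the remaining exons
#' are merged per strand with a 1 bp gap tolerance (book-ended or 1-bp-apart
#' intervals fuse). Each merged exon carries an ordinal id e1, e2, ... within
#' its gene, numbered 5'->3' in transcription orientation.
#'
#' @param genes Curated gene table (see [curate_transcripts()]).
#' @param exons data.frame with columns gene_id, chrom, strand, start, end.
#' @return data.frame gene_id, chrom, strand, start, end, ord, exon_id;
#'   attribute `dropped_genes` lists genes removed for opposite-strand overlap.
#' @export
merge_exons <- function(genes, exons) {
  .check_cols(exons, c("gene_id", "chrom", "strand", "start", "end"), "exons")
  .check_strand(exons$strand)
  if (any(exons$end <= exons$start)) .stopf("exons must have end > start")
  dropped <- character(0)
  for (cn in unique(exons$chrom)) {
    p <- exons[exons$chrom == cn & exons$strand == "+", , drop = FALSE]
    m <- exons[exons$chrom == cn & exons$strand == "-", , drop = FALSE]
    if (nrow(p) && nrow(m)) {
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(p$start + 1, p$end),
        IRanges::IRanges(m$start + 1, m$end))
      if (length(ov)) {
        dropped <- c(dropped,
                     p$gene_id[S4Vectors::queryHits(ov)],
                     m$gene_id[S4Vectors::subjectHits(ov)])
      }
    }
  }
  dropped <- sort(unique(dropped))
  exons <- exons[!exons$gene_id %in% dropped, , drop = FALSE]
  out <- list()
  for (key in unique(paste(exons$chrom, exons$strand))) {
    sel <- paste(exons$chrom, exons$strand) == key
    e <- exons[sel, , drop = FALSE]
    red <- IRanges::reduce(IRanges::IRanges(e$start + 1, e$end), min.gapwidth = 2)
    mstart <- IRanges::start(red) - 1
    mend <- IRanges::end(red)
    # assign merged intervals back to each gene owning an overlapping exon
    hits <- IRanges::findOverlaps(IRanges::IRanges(e$start + 1, e$end), red)
    gene_of <- split(S4Vectors::subjectHits(hits), e$gene_id[S4Vectors::queryHits(hits)])
    for (g in names(gene_of)) {
      ix <- sort(unique(gene_of[[g]]))
      df <- data.frame(gene_id = g, chrom = e$chrom[1], strand = e$strand[1],
                       start = mstart[ix], end = mend[ix],
                       stringsAsFactors = FALSE)
      df <- if (e$strand[1] == "+") df[order(df$start), , drop = FALSE]
            else df[order(-df$end), , drop = FALSE]
      df$ord <- seq_len(nrow(df))
      df$exon_id <- paste0("e", df$ord)
      out[[length(out) + 1L]] <- df
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), chrom = character(), strand = character(),
               start = numeric(), end = numeric(), ord = integer(),
               exon_id = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  if (length(dropped)) {
    message("merge_exons: removed ", length(dropped),
            " gene(s) with opposite-strand exon overlap")
  }
  attr(res, "dropped_genes") <- dropped
  res
}

#' Promoter-proximal region of each gene
#'
#' The promoter-proximal window runs from `upstream` bp before to `downstream`
#' bp after the TSS in transcription orientation (default -250..+100, the Dp
#' region).
#'
#' @param genes Curated gene table.
#' @param upstream,downstream Window bounds in bp.
#' @return data.frame gene_id, chrom, start, end, strand, role = "promoter".
#' @export
promoter_region <- function(genes, upstream = 250, downstream = 100) {
  .check_cols(genes, c("gene_id", "chrom", "strand", "tss"), "genes")
  plus <- genes$strand == "+"
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = ifelse(plus, genes$tss - upstream, genes$tss - downstream),
             end = ifelse(plus, genes$tss + downstream, genes$tss + upstream),
             strand = genes$strand, role = "promoter", stringsAsFactors = FALSE)
}

#' Gene-body region of each gene
#'
#' The Db region runs from `body_start` bp downstream of the TSS to
#' `min(body_end, gene length)` downstream (default 101 bp to 2 kb, truncated
#' at the TTS for genes shorter than 2 kb). Genes shorter than
#' `body_start + 1` bp have no defined gene body and are flagged.
#'
#' @param genes Curated gene table.
#' @param body_start,body_end Transcription-offset bounds in bp.
#' @return data.frame gene_id, chrom, start, end, strand, role = "gene_body",
#'   defined (logical; undefined rows carry NA coordinates).
#' @export
genebody_region <- function(genes, body_start = 101, body_end = 2000) {
  .check_cols(genes, c("gene_id", "chrom", "strand", "tss", "tts"), "genes")
  len <- abs(genes$tts - genes$tss)
  hi <- pmin(body_end, len)
  defined <- len >= body_start + 1
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss + body_start, genes$tss - hi)
  end <- ifelse(plus, genes$tss + hi, genes$tss - body_start)
  start[!defined] <- NA_real_
  end[!defined] <- NA_real_
  if (any(!defined)) {
    message("genebody_region: ", sum(!defined),
            " gene(s) shorter than ", body_start + 1,
            " bp have no defined gene body (excluded from EI)")
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom, start = start,
             end = end, strand = genes$strand, role = "gene_body",
             defined = defined, stringsAsFactors = FALSE)
}

#' Exon-start control loci
#'
#' Returns the transcription-orientation 5' boundary of a subset of merged
#' exons, used as intragenic control regions that are not dipyrimidine
#' enriched. `substring_e2` selects every exon whose id begins with "e2"
#' (e2, e20, e21, ..., reproducing a substring-match selection); ties to
#' `ordinal_second` which selects exactly the second exon of each gene.
#'
#' @param exons Merged exon table from [merge_exons()].
#' @param mode "substring_e2" (default) or "ordinal_second".
#' @return data.frame gene_id, chrom, pos (0-based exon 5' boundary), strand,
#'   exon_id.
#' @export
select_exon_start_controls <- function(exons,
                                       mode = c("substring_e2", "ordinal_second")) {
  mode <- match.arg(mode)
  .check_cols(exons, c("gene_id", "chrom", "strand", "start", "end", "ord",
                       "exon_id"), "exons")
  sel <- if (mode == "substring_e2") grepl("^e2", exons$exon_id) else exons$ord == 2L
  e <- exons[sel, , drop = FALSE]
  data.frame(gene_id = e$gene_id, chrom = e$chrom,
             pos = ifelse(e$strand == "+", e$start, e$end),
             strand = e$strand, exon_id = e$exon_id,
             row.names = NULL, stringsAsFactors = FALSE)
}
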