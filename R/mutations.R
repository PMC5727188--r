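# Somatic mutation landscape pipeline: catalog parsing, signature and
# trinucleotide-context selection, template/non-template strand assignment,
# prevalence profiles (mutations per Mb per sample) with exome density
# correction, expression stratification and binned comparisons.
#
# Catalogs use the tab-delimited layout
# (sample, type, chrom, start, end, ref, alt; 1-based inclusive positions);
# internally positions become 0-based. Trinucleotide contexts are read 5'->3'
# on the reference strand with the mutated base central; the UV signature
# keeps C>T in TCC context and its reverse complement G>A in GGA, the smoking
# signature G>T in TGG and C>A in CCA. Contexts are matched on the reference
# strand as stated motifs, without reverse-complementing records.

.SIGNATURES <- list(
  UV = list(classes = c("C>T", "G>A"),
            contexts = c("C>T" = "TCC", "G>A" = "GGA")),
  smoking = list(classes = c("G>T", "C>A"),
                 contexts = c("G>T" = "TGG", "C>A" = "CCA")))

#' Parse a substitution catalog (Alexandrov-style layout)
#'
#' Reads a headerless 7-column tab-delimited catalog (sample, type, chrom,
#' start, end, ref, alt; 1-based inclusive) and keeps single-base
#' substitutions; indels and multi-base records are skipped with a logged
#' count.
#'
#' @param path File path, or a data.frame already in the 7-column layout.
#' @return data.frame sample, chrom, pos (0-based), ref, alt, class
#'   (one of C>T, G>A, G>T, C>A, other).
#' @export
parse_catalog <- function(path) {
  if (is.data.frame(path)) {
    tab <- path
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "",
                             comment.char = "")
  }
  if (ncol(tab) != 7) .stopf("catalog must have 7 columns, found %d", ncol(tab))
  names(tab) <- c("sample", "type", "chrom", "start", "end", "ref", "alt")
  start <- suppressWarnings(as.numeric(tab$start))
  end <- suppressWarnings(as.numeric(tab$end))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    if (bad[1] && nrow(tab) > 1) {
      # tolerate a single header line
      tab <- tab[-1, , drop = FALSE]; start <- start[-1]; end <- end[-1]
      bad <- is.na(start) | is.na(end)
    }
    if (any(bad)) {
      .warnf("skipping %d malformed catalog row(s)", sum(bad))
      tab <- tab[!bad, , drop = FALSE]; start <- start[!bad]; end <- end[!bad]
    }
  }
  is_sub <- nchar(tab$ref) == 1 & nchar(tab$alt) == 1 &
    tab$ref %in% c("A", "C", "G", "T") & tab$alt %in% c("A", "C", "G", "T") &
    tab$ref != tab$alt & end == start
  n_skip <- sum(!is_sub)
  if (n_skip) message("parse_catalog: skipped ", n_skip,
                      " non-substitution record(s) (indels/MNVs)")
  tab <- tab[is_sub, , drop = FALSE]
  cls <- paste0(tab$ref, ">", tab$alt)
  cls[!cls %in% c("C>T", "G>A", "G>T", "C>A")] <- "other"
  data.frame(sample = tab$sample, chrom = tab$chrom,
             pos = start[is_sub] - 1, ref = tab$ref, alt = tab$alt,
             class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Write records back to the 7-column catalog layout
#' @param records Record table from [parse_catalog()].
#' @param path Output path.
#' @export
write_catalog <- function(records, path) {
  .check_cols(records, c("sample", "chrom", "pos", "ref", "alt"), "records")
  out <- data.frame(records$sample, "subs", records$chrom,
                    records$pos + 1, records$pos + 1,
                    records$ref, records$alt)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Keep the substitutions of a mutational signature
#'
#' UV keeps C>T and its reverse complement G>A; smoking keeps G>T and C>A.
#'
#' @param records Record table.
#' @param signature "UV" or "smoking".
#' @return Filtered records.
#' @export
select_signature <- function(records, signature = c("UV", "smoking")) {
  signature <- match.arg(signature)
  out <- records[records$class %in% .SIGNATURES[[signature]]$classes, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate records with their reference-strand trinucleotide context
#'
#' @param records Record table.
#' @param genome `DNAStringSet` of chromosome sequences.
#' @return Records with a `context` column; records whose context runs off a
#'   chromosome end, or whose ref base mismatches the genome, are dropped with
#'   a logged count.
#' @export
mutation_context <- function(records, genome) {
  .check_cols(records, c("chrom", "pos", "ref"), "records")
  ctx <- rep(NA_character_, nrow(records))
  for (cn in unique(records$chrom)) {
    if (!cn %in% names(genome)) .stopf("chromosome '%s' not in genome", cn)
    ix <- which(records$chrom == cn)
    L <- length(genome[[cn]])
    p <- records$pos[ix]
    ok <- p >= 1 & p + 1 <= L - 1
    if (any(ok)) {
      ctx[ix[ok]] <- as.character(Biostrings::extractAt(
        genome[[cn]], IRanges::IRanges(start = p[ok], width = 3)))
    }
  }
  off_end <- is.na(ctx)
  if (any(off_end)) message("mutation_context: dropped ", sum(off_end),
                            " record(s) with context off a chromosome end")
  records <- records[!off_end, , drop = FALSE]
  ctx <- ctx[!off_end]
  mismatch <- substr(ctx, 2, 2) != records$ref
  if (any(mismatch)) {
    .warnf("dropped %d record(s) whose ref base mismatches the genome",
           sum(mismatch))
    records <- records[!mismatch, , drop = FALSE]
    ctx <- ctx[!mismatch]
  }
  records$context <- ctx
  rownames(records) <- NULL
  records
}

#' Keep records in the signature's canonical trinucleotide contexts
#'
#' @param records Record table (context added on the fly when absent).
#' @param genome `DNAStringSet` (needed when `records` lack a context column).
#' @param signature "UV" or "smoking".
#' @return Filtered records with a `context` column.
#' @export
filter_context <- function(records, genome = NULL,
                           signature = c("UV", "smoking")) {
  signature <- match.arg(signature)
  if (is.null(records$context)) {
    if (is.null(genome)) .stopf("'genome' required to extract contexts")
    records <- mutation_context(records, genome)
  }
  want <- .SIGNATURES[[signature]]$contexts
  keep <- records$class %in% names(want) &
    records$context == unname(want[records$class])
  out <- records[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign template / non-template strand labels to genic records
#'
#' The damaged base of both signatures sits on the reference strand carrying
#' the pyrimidine C (UV) or the adducted G (smoking). For a '+' strand gene
#' (template = reference minus strand) a reference-strand C>T or G>T record
#' means the adduct sat on the '+' (non-template) strand, hence NTS, while
#' G>A / C>A records mirror to TS; labels flip for '-' strand genes.
#' Intergenic records are labelled "intergenic"; records falling in
#' overlapping opposite-strand genes are ambiguous and dropped (count
#' logged); same-strand overlaps resolve to the gene with the nearest TSS.
#'
#' @param records Record table (signature/context-filtered).
#' @param genes Curated gene table.
#' @return Records with `gene_id` and `strand_label` (TS / NTS / intergenic).
#' @export
assign_strand <- function(records, genes) {
  .check_cols(records, c("chrom", "pos", "class"), "records")
  .check_cols(genes, c("gene_id", "chrom", "strand", "start", "end", "tss"),
              "genes")
  gene_id <- rep(NA_character_, nrow(records))
  gene_strand <- rep(NA_character_, nrow(records))
  ambiguous <- logical(nrow(records))
  for (cn in unique(records$chrom)) {
    rix <- which(records$chrom == cn)
    g <- genes[genes$chrom == cn, , drop = FALSE]
    if (!nrow(g)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(records$pos[rix] + 1, width = 1),
      IRanges::IRanges(g$start + 1, g$end))
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    n_hits <- tabulate(qh, nbins = length(rix))
    # fast path: the overwhelmingly common single-gene hit
    single <- which(n_hits == 1)
    one <- qh %in% single
    gene_id[rix[qh[one]]] <- g$gene_id[sh[one]]
    gene_strand[rix[qh[one]]] <- g$strand[sh[one]]
    # multi-gene hits: nearest TSS on the same strand, ambiguous otherwise
    for (k in which(n_hits > 1)) {
      i <- rix[k]
      gs <- sh[qh == k]
      if (length(unique(g$strand[gs])) > 1) {
        ambiguous[i] <- TRUE
        next
      }
      gs <- gs[which.min(abs(records$pos[i] - g$tss[gs]))]
      gene_id[i] <- g$gene_id[gs]
      gene_strand[i] <- g$strand[gs]
    }
  }
  if (any(ambiguous)) message("assign_strand: dropped ", sum(ambiguous),
                              " record(s) in overlapping opposite-strand genes")
  records <- records[!ambiguous, , drop = FALSE]
  gene_id <- gene_id[!ambiguous]
  gene_strand <- gene_strand[!ambiguous]
  adduct_on_plus <- records$class %in% c("C>T", "G>T")
  label <- ifelse(is.na(gene_id), "intergenic",
           ifelse((gene_strand == "+") == adduct_on_plus, "NTS", "TS"))
  records$gene_id <- gene_id
  records$strand_label <- label
  rownames(records) <- NULL
  records
}

# Transcription-oriented offset of each record within its gene.
.tx_offset <- function(pos, tss, strand) {
  ifelse(strand == "+", pos - tss, tss - pos - 1)
}

#' Mutation prevalence profile along gene bodies
#'
#' Counts genic records in transcription-oriented windows of `window` bp from
#' the TSS out to `span` bp, per strand label and expression class, and
#' normalizes to mutations per Mb per sample using per-window covered length
#' (genes contribute length only to the windows they span).
#'
#' @param records Strand-assigned records (see [assign_strand()]).
#' @param genes Curated gene table.
#' @param classes data.frame gene_id, class (e.g. from
#'   [stratify_expression()]); genes absent from `classes` are dropped.
#' @param n_samples Number of samples in the catalog (denominator).
#' @param window Window width in bp.
#' @param span Profile span from the TSS in bp.
#' @return data.frame window_start (bp), class, strand, count, covered_bp,
#'   prevalence (mutations / Mb / sample); attribute `n_samples`.
#' @export
prevalence_profile <- function(records, genes, classes, n_samples,
                               window = 2000, span = 60000) {
  if (!.is_count(n_samples) || n_samples < 1) .stopf("'n_samples' must be >= 1")
  .check_cols(classes, c("gene_id", "class"), "classes")
  genes <- genes[genes$gene_id %in% classes$gene_id, , drop = FALSE]
  cls_of <- stats::setNames(as.character(classes$class), classes$gene_id)
  glen <- pmin(abs(genes$tts - genes$tss), span)
  nwin <- ceiling(span / window)
  wstarts <- (seq_len(nwin) - 1) * window
  # covered bp per (window, class)
  cov_by <- tapply(seq_len(nrow(genes)), cls_of[genes$gene_id], function(ix) {
    vapply(wstarts, function(w) sum(.clamp(glen[ix] - w, 0, window)), 0)
  })
  class_levels <- sort(unique(as.character(classes$class)))
  rec <- records[!is.na(records$gene_id) &
                   records$gene_id %in% genes$gene_id, , drop = FALSE]
  gi <- match(rec$gene_id, genes$gene_id)
  off <- .tx_offset(rec$pos, genes$tss[gi], genes$strand[gi])
  keep <- off >= 0 & off < glen[gi]
  rec <- rec[keep, , drop = FALSE]
  off <- off[keep]
  win <- off %/% window
  rec_class <- cls_of[rec$gene_id]
  out <- expand.grid(window_start = wstarts, class = class_levels,
                     strand = c("TS", "NTS"), stringsAsFactors = FALSE)
  key <- paste(win * window, rec_class, rec$strand_label)
  counts <- table(key)
  out$count <- as.numeric(counts[paste(out$window_start, out$class, out$strand)])
  out$count[is.na(out$count)] <- 0
  out$covered_bp <- vapply(seq_len(nrow(out)), function(i) {
    cb <- cov_by[[out$class[i]]]
    if (is.null(cb)) 0 else cb[out$window_start[i] / window + 1]
  }, 0)
  out$prevalence <- ifelse(out$covered_bp > 0,
                           out$count / n_samples / (out$covered_bp / 1e6),
                           NA_real_)
  attr(out, "n_samples") <- n_samples
  out
}

#' Exon-density correction of a prevalence profile (WES mode)
#'
#' Exome-sequenced catalogs only observe exonic positions, so raw window
#' prevalence is deflated by the local exon fraction. The correction divides
#' each window's prevalence by its exon fraction (exonic bp / covered bp);
#' windows with exon fraction below `floor` are masked (NA), never divided.
#'
#' @param profile Profile from [prevalence_profile()].
#' @param exons Merged exon table (see [merge_exons()]).
#' @param genes,classes As passed to [prevalence_profile()].
#' @param window,span Must match the profile's grid.
#' @param floor Minimum exon fraction.
#' @return Profile with `exon_fraction` and `corrected` columns.
#' @export
exon_density_correction <- function(profile, exons, genes, classes,
                                    window = 2000, span = 60000,
                                    floor = 0.01) {
  .check_cols(profile, c("window_start", "class", "prevalence", "covered_bp"),
              "profile")
  .check_cols(exons, c("gene_id", "start", "end"), "exons")
  genes <- genes[genes$gene_id %in% classes$gene_id, , drop = FALSE]
  cls_of <- stats::setNames(as.character(classes$class), classes$gene_id)
  glen <- stats::setNames(pmin(abs(genes$tts - genes$tss), span), genes$gene_id)
  nwin <- ceiling(span / window)
  wstarts <- (seq_len(nwin) - 1) * window
  ex <- exons[exons$gene_id %in% genes$gene_id, , drop = FALSE]
  gi <- match(ex$gene_id, genes$gene_id)
  # exon bounds in transcription offsets, clipped to the profiled span
  lo <- ifelse(genes$strand[gi] == "+", ex$start - genes$tss[gi],
               genes$tss[gi] - ex$end)
  hi <- lo + (ex$end - ex$start)
  lo <- .clamp(lo, 0, glen[ex$gene_id])
  hi <- .clamp(hi, 0, glen[ex$gene_id])
  ex_class <- cls_of[ex$gene_id]
  exonic_by <- tapply(seq_len(nrow(ex)), ex_class, function(ix) {
    vapply(wstarts, function(w) {
      sum(pmax(0, pmin(hi[ix], w + window) - pmax(lo[ix], w)))
    }, 0)
  })
  frac <- vapply(seq_len(nrow(profile)), function(i) {
    eb <- exonic_by[[profile$class[i]]]
    e <- if (is.null(eb)) 0 else eb[profile$window_start[i] / window + 1]
    if (profile$covered_bp[i] > 0) e / profile$covered_bp[i] else NA_real_
  }, 0)
  profile$exon_fraction <- frac
  profile$corrected <- ifelse(!is.na(frac) & frac >= floor,
                              profile$prevalence / frac, NA_real_)
  profile
}

#' Restrict records to exonic positions (whole-exome mode)
#'
#' Emulates what an exome-sequenced catalog observes: only records whose
#' position falls inside a merged exon are kept. Pair with
#' [exon_density_correction()] to recover genome-wide prevalence.
#'
#' @param records Record table with chrom, pos.
#' @param exons Merged exon table.
#' @return Filtered records.
#' @export
restrict_to_exome <- function(records, exons) {
  .check_cols(records, c("chrom", "pos"), "records")
  keep <- logical(nrow(records))
  for (cn in unique(records$chrom)) {
    rix <- which(records$chrom == cn)
    e <- exons[exons$chrom == cn, , drop = FALSE]
    if (!nrow(e)) next
    keep[rix] <- IRanges::overlapsAny(
      IRanges::IRanges(records$pos[rix] + 1, width = 1),
      IRanges::IRanges(e$start + 1, e$end))
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratify genes into NE / Lo / Med / Hi expression classes
#'
#' Non-expressed (NE) genes fall below the kernel-density threshold (log2
#' scale, see [expression_threshold()]); remaining expressed genes are ranked
#' and cut into three classes of equal size (+-1; any remainder goes to the
#' highest classes first).
#'
#' @param rpkm data.frame gene_id, rpkm.
#' @param threshold log2-scale cutoff (e.g. `expression_threshold(...)$threshold`).
#' @param eps Pseudocount matching the threshold's construction.
#' @return data.frame gene_id, class (factor NE < Lo < Med < Hi), rpkm.
#' @export
stratify_expression <- function(rpkm, threshold, eps = 0.01) {
  .check_cols(rpkm, c("gene_id", "rpkm"), "rpkm")
  lg <- log2(rpkm$rpkm + eps)
  ne <- lg < threshold
  cls <- rep(NA_character_, nrow(rpkm))
  cls[ne] <- "NE"
  e_ix <- which(!ne)
  if (length(e_ix)) {
    o <- e_ix[order(-rpkm$rpkm[e_ix])]
    nE <- length(o)
    base <- nE %/% 3
    rem <- nE %% 3
    sizes <- base + (seq_len(3) <= rem)   # Hi gets the remainder first
    cls[o] <- rep(c("Hi", "Med", "Lo"), times = sizes)
  }
  data.frame(gene_id = rpkm$gene_id,
             class = factor(cls, levels = c("NE", "Lo", "Med", "Hi")),
             rpkm = rpkm$rpkm, stringsAsFactors = FALSE)
}

#' Per-gene mutation prevalence (mutations / Mb / sample)
#'
#' @param records Strand-assigned, filtered records.
#' @param genes Curated gene table.
#' @param n_samples Number of samples in the catalog.
#' @param span Counting span from the TSS in bp (display convention).
#' @param strand Optional: restrict to "TS" or "NTS" records.
#' @return data.frame gene_id, count, covered_mb, prevalence.
#' @export
per_gene_prevalence <- function(records, genes, n_samples, span = 60000,
                                strand = NULL) {
  glen <- pmin(abs(genes$tts - genes$tss), span)
  rec <- records[!is.na(records$gene_id), , drop = FALSE]
  if (!is.null(strand)) rec <- rec[rec$strand_label %in% strand, , drop = FALSE]
  gi <- match(rec$gene_id, genes$gene_id)
  off <- .tx_offset(rec$pos, genes$tss[gi], genes$strand[gi])
  rec <- rec[!is.na(gi) & off >= 0 & off < glen[gi], , drop = FALSE]
  cnt <- table(factor(rec$gene_id, levels = genes$gene_id))
  data.frame(gene_id = genes$gene_id, count = as.numeric(cnt),
             covered_mb = glen / 1e6,
             prevalence = as.numeric(cnt) / n_samples / (glen / 1e6),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Moving average of per-gene values across expression ranks
#'
#' @param values Numeric vector (e.g. per-gene prevalence).
#' @param ranks Expression ranks (any orderable numeric).
#' @param width Moving-window width in genes (centered, truncated at edges).
#' @return data.frame rank, value (smoothed), in rank order.
#' @export
moving_average_by_rank <- function(values, ranks, width = 200) {
  if (length(values) != length(ranks)) .stopf("lengths differ")
  o <- order(ranks)
  data.frame(rank = ranks[o], value = .moving_average(values[o], width))
}

#' Binned pairwise comparisons of mutation prevalence between classes
#'
#' Mutations are sparse, so genes are pooled in consecutive groups of
#' `bin_size` (default 15) along the expression-rank order within each class;
#' bin prevalence = pooled count / n_samples / pooled Mb. A trailing group
#' keeps its own bin when it holds at least `min_tail` genes and is merged
#' into the previous bin otherwise (logged). Pairwise two-sided Wilcoxon
#' rank-sum tests compare Hi/Med/Lo bins, plus pooled all-E (re-binned) vs
#' NE; BH adjustment runs over the reported family; non-significant (N.S.)
#' means adjusted P > `alpha` (default 0.01).
#'
#' @param per_gene data.frame gene_id, class, rank, count, covered_mb (e.g.
#'   join of [per_gene_prevalence()] and [stratify_expression()]).
#' @param n_samples Number of samples.
#' @param bin_size Genes per bin.
#' @param min_tail Minimum size of a trailing bin.
#' @param alpha Significance cutoff on adjusted p-values.
#' @return list(bins = data.frame(class, bin, n_genes, count, mb, prevalence),
#'   comparisons = data.frame(pair, p, p_adj, significant)).
#' @export
binned_comparison <- function(per_gene, n_samples, bin_size = 15,
                              min_tail = 8, alpha = 0.01) {
  .check_cols(per_gene, c("gene_id", "class", "rank", "count", "covered_mb"),
              "per_gene")
  make_bins <- function(df, label) {
    df <- df[order(df$rank), , drop = FALSE]
    n <- nrow(df)
    if (n < bin_size) return(NULL)
    grp <- (seq_len(n) - 1) %/% bin_size + 1
    tail_n <- sum(grp == max(grp))
    if (tail_n < bin_size && tail_n < min_tail && max(grp) > 1) {
      message("binned_comparison: merging trailing group of ", tail_n,
              " gene(s) into the previous bin (class ", label, ")")
      grp[grp == max(grp)] <- max(grp) - 1
    }
    agg <- do.call(rbind, lapply(split(seq_len(n), grp), function(ix) {
      data.frame(class = label, bin = grp[ix[1]], n_genes = length(ix),
                 count = sum(df$count[ix]), mb = sum(df$covered_mb[ix]))
    }))
    agg$prevalence <- agg$count / n_samples / agg$mb
    agg
  }
  classes <- as.character(per_gene$class)
  e_classes <- intersect(c("Hi", "Med", "Lo"), unique(classes))
  bins <- list()
  for (cl in unique(classes)) {
    bins[[cl]] <- make_bins(per_gene[classes == cl, , drop = FALSE], cl)
  }
  if (length(e_classes) > 1) {
    bins[["E"]] <- make_bins(per_gene[classes %in% e_classes, , drop = FALSE], "E")
  }
  bins_df <- do.call(rbind, bins)
  rownames(bins_df) <- NULL
  pairs <- if (length(e_classes) >= 2) {
    utils::combn(e_classes, 2, simplify = FALSE)
  } else list()
  if (!is.null(bins[["E"]]) && !is.null(bins[["NE"]])) {
    pairs <- c(pairs, list(c("E", "NE")))
  }
  if (!length(pairs)) {
    return(list(bins = bins_df,
                comparisons = data.frame(pair = character(), p = numeric(),
                                         p_adj = numeric(),
                                         significant = logical())))
  }
  comp <- do.call(rbind, lapply(pairs, function(pr) {
    a <- bins[[pr[1]]]; b <- bins[[pr[2]]]
    if (is.null(a) || is.null(b) || nrow(a) < 2 || nrow(b) < 2) {
      return(data.frame(pair = paste(pr, collapse = " vs "), p = NA_real_))
    }
    p <- suppressWarnings(
      stats::wilcox.test(a$prevalence, b$prevalence)$p.value)
    data.frame(pair = paste(pr, collapse = " vs "), p = p)
  }))
  comp$p_adj <- stats::p.adjust(comp$p, method = "BH")
  comp$significant <- !is.na(comp$p_adj) & comp$p_adj <= alpha
  list(bins = bins_df, comparisons = comp)
}
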