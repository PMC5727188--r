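# Promoter escape indexes, UV escape-shift statistics, activity classes,
# and the kernel-density expression threshold.

#' Escape index (EI) of each gene on a track
#'
#' EI is the ratio of mean read density in the gene body (Db, default 101 bp
#' to 2 kb downstream of the TSS, truncated at the TTS) over mean read density
#' in the promoter-proximal region (Dp, default -250..+100 bp around the TSS).
#' Genes with Dp = 0 or with no defined gene body carry `defined = FALSE`
#' rather than NaNs.
#'
#' @param track A `CoverageTrack`.
#' @param genes Curated gene table.
#' @param promoter,genebody Optional precomputed region tables from
#'   [promoter_region()] / [genebody_region()].
#' @return data.frame gene_id, Dp, Db, EI, defined.
#' @export
escape_index <- function(track, genes,
                         promoter = promoter_region(genes),
                         genebody = genebody_region(genes)) {
  stopifnot(inherits(track, "CoverageTrack"))
  n <- nrow(genes)
  Dp <- Db <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Dp[i] <- mean_density(track, promoter$chrom[i], promoter$start[i],
                          promoter$end[i])
    if (genebody$defined[i]) {
      Db[i] <- mean_density(track, genebody$chrom[i], genebody$start[i],
                            genebody$end[i])
    }
  }
  defined <- genebody$defined & !is.na(Dp) & Dp > 0
  EI <- ifelse(defined, Db / Dp, NA_real_)
  data.frame(gene_id = genes$gene_id, Dp = Dp, Db = Db, EI = EI,
             defined = defined, stringsAsFactors = FALSE)
}

#' EI change between conditions (dEI = EI(+UV) / EI(reference))
#'
#' @param ei_uv,ei_ref Tables from [escape_index()] for the two conditions.
#' @return data.frame gene_id, EI_uv, EI_ref, dEI, defined; dEI is undefined
#'   when either input is undefined (such genes are excluded from proportions).
#' @export
delta_ei <- function(ei_uv, ei_ref) {
  .check_cols(ei_uv, c("gene_id", "EI", "defined"), "ei_uv")
  .check_cols(ei_ref, c("gene_id", "EI", "defined"), "ei_ref")
  m <- merge(ei_uv[, c("gene_id", "EI", "defined")],
             ei_ref[, c("gene_id", "EI", "defined")],
             by = "gene_id", suffixes = c("_uv", "_ref"))
  defined <- m$defined_uv & m$defined_ref & m$EI_ref > 0
  data.frame(gene_id = m$gene_id, EI_uv = m$EI_uv, EI_ref = m$EI_ref,
             dEI = ifelse(defined, m$EI_uv / m$EI_ref, NA_real_),
             defined = defined, stringsAsFactors = FALSE)
}

#' Chi-square test for an excess of genes with dEI > 1
#'
#' Tests whether the observed number of genes with increased escape
#' (dEI > 1) differs from the expectation under a symmetric null
#' (`null_prop`, default 0.5). Undefined dEI values are excluded and counted.
#'
#' @param deltas Numeric vector of dEI values, or the table from [delta_ei()].
#' @param null_prop Null proportion of genes with dEI > 1.
#' @return list(percent_above, n, n_excluded, chisq, df, p_value).
#' @export
escape_shift_test <- function(deltas, null_prop = 0.5) {
  if (is.data.frame(deltas)) deltas <- deltas$dEI
  n_excluded <- sum(!is.finite(deltas))
  x <- deltas[is.finite(deltas)]
  if (!length(x)) .stopf("no defined dEI values")
  if (!.is_number(null_prop) || null_prop <= 0 || null_prop >= 1) {
    .stopf("'null_prop' must be in (0, 1)")
  }
  n <- length(x)
  k <- sum(x > 1)
  exp_k <- n * null_prop
  chisq <- (k - exp_k)^2 / exp_k + ((n - k) - (n - exp_k))^2 / (n - exp_k)
  list(percent_above = 100 * k / n, n = n, n_excluded = n_excluded,
       chisq = chisq, df = 1L,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Empirical cumulative distribution function of EI values
#'
#' Validated wrapper used for ECDF comparisons of escape indexes between
#' conditions.
#'
#' @param values Numeric vector (non-empty; NAs dropped).
#' @return A right-continuous step function (see [stats::ecdf()]).
#' @export
escape_ecdf <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) .stopf("no finite values for ECDF")
  stats::ecdf(values)
}

.overlaps_promoter <- function(promoters, peaks) {
  out <- logical(nrow(promoters))
  if (is.null(peaks) || !nrow(peaks)) return(out)
  for (cn in unique(promoters$chrom)) {
    ps <- promoters$chrom == cn
    pk <- peaks[peaks$chrom == cn, , drop = FALSE]
    if (!nrow(pk)) next
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(promoters$start[ps] + 1, promoters$end[ps]),
      IRanges::IRanges(pk$start + 1, pk$end))
    out[ps] <- ov
  }
  out
}

#' Classify gene activity from promoter peak overlaps and promoter Rd
#'
#' A gene is `active` when an elongating-isoform (ser2P) peak overlaps its
#' promoter-proximal region and its promoter read density exceeds
#' `rd_threshold` (default 0.7 rpm); `poised` when an initiating (ser5P) or
#' hypophosphorylated (hypo) peak overlaps the promoter but no ser2P peak
#' does; otherwise `inactive`. Genes with a ser2P peak but promoter Rd at or
#' below the threshold are flagged (`low_rd_ser2p`): they fall to poised if
#' ser5P/hypo evidence exists, else inactive.
#'
#' @param genes Curated gene table.
#' @param promoter_rd Numeric vector of promoter read densities (rpm), one per
#'   gene (the ser2P track by default convention).
#' @param peaks Named list of peak interval data.frames (chrom, start, end)
#'   with any of the names "ser2P", "ser5P", "hypo"; missing elements are
#'   treated as absent evidence (message emitted).
#' @param rd_threshold Promoter Rd threshold in rpm (strict >).
#' @return data.frame gene_id, status, ser2p_peak, ser5p_peak, hypo_peak,
#'   promoter_rd, low_rd_ser2p.
#' @export
classify_activity <- function(genes, promoter_rd, peaks, rd_threshold = 0.7) {
  .check_cols(genes, c("gene_id", "chrom", "strand", "tss"), "genes")
  if (length(promoter_rd) != nrow(genes)) {
    .stopf("'promoter_rd' must have one value per gene")
  }
  prom <- promoter_region(genes)
  get_peaks <- function(name) {
    if (is.null(peaks[[name]])) {
      message("classify_activity: no '", name,
              "' peaks supplied; treating as absent evidence")
      return(logical(nrow(genes)))
    }
    .overlaps_promoter(prom, peaks[[name]])
  }
  ser2 <- get_peaks("ser2P")
  ser5 <- get_peaks("ser5P")
  hypo <- get_peaks("hypo")
  active <- ser2 & promoter_rd > rd_threshold
  poised <- !active & (ser5 | hypo) & !ser2
  status <- ifelse(active, "active", ifelse(poised, "poised", "inactive"))
  data.frame(gene_id = genes$gene_id, status = status,
             ser2p_peak = ser2, ser5p_peak = ser5, hypo_peak = hypo,
             promoter_rd = promoter_rd,
             low_rd_ser2p = ser2 & promoter_rd <= rd_threshold,
             stringsAsFactors = FALSE)
}

#' Expression threshold from the log2 RPKM kernel density
#'
#' Fits a Gaussian kernel density (Silverman's bandwidth) to log2(RPKM + eps)
#' and returns the minimum-density point between the two highest modes; genes
#' below it are non-expressed (NE). If fewer than two modes are found (or the
#' values are degenerate), falls back to the `fallback_quantile` of the
#' values with a warning.
#'
#' @param rpkm Numeric vector of RPKM values (or log2 values when
#'   `values_are_log2 = TRUE`).
#' @param eps Pseudocount added before log2 (RPKM units).
#' @param values_are_log2 Set TRUE when `rpkm` is already on the log2 scale.
#' @param fallback_quantile Quantile used when the density is unimodal.
#' @param min_genes Minimum number of values required.
#' @return list(threshold (log2 scale), unimodal (logical), modes (log2
#'   positions of the two modes used, or NULL), bandwidth).
#' @export
expression_threshold <- function(rpkm, eps = 0.01, values_are_log2 = FALSE,
                                 fallback_quantile = 0.25, min_genes = 50) {
  x <- if (values_are_log2) rpkm else log2(rpkm + eps)
  x <- x[is.finite(x)]
  if (length(x) < min_genes) .stopf("need at least %d genes", min_genes)
  fallback <- function() {
    .warnf("expression density is unimodal/degenerate; falling back to the %.2f quantile",
           fallback_quantile)
    list(threshold = unname(stats::quantile(x, fallback_quantile)),
         unimodal = TRUE, modes = NULL, bandwidth = NA_real_)
  }
  if (stats::sd(x) == 0) return(fallback())
  d <- stats::density(x, bw = "nrd0")
  y <- d$y
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(is_peak)
  if (length(peaks) < 2) return(fallback())
  top2 <- sort(peaks[order(-y[peaks])][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
  list(threshold = d$x[valley], unimodal = FALSE,
       modes = d$x[top2], bandwidth = d$bw)
}
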