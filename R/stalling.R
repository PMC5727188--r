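# Quantification of stalling / repair activity around loci: fold changes,
# summit-minus-flank ('S - F') scores, control-derived thresholds, proportions
# above threshold and the statistical test battery (ANOVA + pairwise t,
# Kruskal-Wallis + pairwise Wilcoxon, BH adjustment, 2x2 chi-square).
# The same machinery applies to ChIP read matrices and excision-read matrices.

#' Per-region fold change between conditions
#'
#' FC per region = (mean row density + pseudocount) / (mean reference row
#' density + pseudocount); reported raw and log2.
#'
#' @param mat_uv,mat_ref Density matrices sharing shape and region order.
#' @param pseudocount Added to both means (rpm).
#' @return data.frame region_id, rd_uv, rd_ref, fc, log2_fc.
#' @export
region_fc <- function(mat_uv, mat_ref, pseudocount = 0.25) {
  if (!identical(dim(mat_uv), dim(mat_ref)) ||
      !identical(rownames(mat_uv), rownames(mat_ref))) {
    .stopf("matrices must share shape and region order")
  }
  a <- rowMeans(mat_uv)
  b <- rowMeans(mat_ref)
  fc <- (a + pseudocount) / (b + pseudocount)
  data.frame(region_id = rownames(mat_uv), rd_uv = a, rd_ref = b, fc = fc,
             log2_fc = log2(fc), row.names = NULL, stringsAsFactors = FALSE)
}

.sf_indices <- function(n, summit_frac, flank_frac) {
  if (n < 5) .stopf("'S - F' score needs at least 5 bins (got %d)", n)
  k <- max(1L, round(n * summit_frac))
  m <- max(1L, round(n * flank_frac))
  if (2 * m + k > n) .stopf("summit and flank windows overlap (n = %d)", n)
  s0 <- floor((n - k) / 2) + 1L
  list(summit = seq.int(s0, length.out = k),
       flank = c(seq_len(m), seq.int(n - m + 1L, n)))
}

#' Summit-minus-flank ('S - F') scores of a density matrix
#'
#' S is the mean density over the central `summit_frac` of bins (the specific
#' accumulation at the locus); F the mean over the outermost `flank_frac` of
#' bins on each side, pooled (the background expected from the wave passing
#' by); the score is S - F. Adding a constant to every bin leaves the score
#' unchanged.
#'
#' @param mat Density matrix (regions x bins), e.g. from
#'   [locus_window_matrix()].
#' @param summit_frac Fraction of bins forming the central summit window.
#' @param flank_frac Fraction of bins per side forming the flank windows.
#' @return data.frame region_id, S, F, score.
#' @export
sf_scores <- function(mat, summit_frac = 0.2, flank_frac = 0.25) {
  if (!is.matrix(mat)) .stopf("'mat' must be a matrix")
  ix <- .sf_indices(ncol(mat), summit_frac, flank_frac)
  S <- rowMeans(mat[, ix$summit, drop = FALSE])
  F <- rowMeans(mat[, ix$flank, drop = FALSE])
  data.frame(region_id = rownames(mat), S = S, F = F, score = S - F,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' 'S - F' score of a single row profile
#' @param row Numeric vector of bin densities.
#' @inheritParams sf_scores
#' @return list(S, F, score).
#' @export
sf_score <- function(row, summit_frac = 0.2, flank_frac = 0.25) {
  ix <- .sf_indices(length(row), summit_frac, flank_frac)
  S <- mean(row[ix$summit])
  F <- mean(row[ix$flank])
  list(S = S, F = F, score = S - F)
}

#' Control-derived 'S - F' threshold (mean + 3 SD of control scores)
#'
#' The threshold separating specific stalling from wave pass-through is
#' estimated from a control locus set (exon starts): mean + 3 x sample SD of
#' the control scores. Under Gaussian control scores the expected
#' false-positive rate is ~0.13%.
#'
#' @param control_scores Numeric vector of control 'S - F' scores.
#' @param min_controls Minimum number of control regions (default 10).
#' @return list(mean, sd, n, threshold).
#' @export
sf_threshold <- function(control_scores, min_controls = 10) {
  control_scores <- control_scores[is.finite(control_scores)]
  if (length(control_scores) < min_controls) {
    .stopf("need at least %d control regions", min_controls)
  }
  m <- mean(control_scores)
  s <- stats::sd(control_scores)
  list(mean = m, sd = s, n = length(control_scores), threshold = m + 3 * s)
}

#' Percent of scores strictly above a threshold
#'
#' @param scores Numeric vector.
#' @param threshold Threshold (strict `>`).
#' @return Percent in 0..100; NA (with a message) for an empty group.
#' @export
proportion_above <- function(scores, threshold) {
  scores <- scores[is.finite(scores)]
  if (!length(scores)) {
    message("proportion_above: empty group; reporting NA")
    return(NA_real_)
  }
  100 * sum(scores > threshold) / length(scores)
}

.check_groups <- function(x) {
  if (!is.list(x) || length(x) < 2 || is.null(names(x))) {
    .stopf("need a named list of at least 2 groups")
  }
  if (any(vapply(x, length, 1L) < 2)) .stopf("each group needs >= 2 values")
  invisible(x)
}

#' One-way ANOVA with BH-adjusted pairwise t-tests on log2 FC groups
#'
#' Parametric battery for fold-change comparisons (normality assumed for
#' log2 FC values): one-way ANOVA across clusters, then all pairwise
#' two-sided Welch t-tests with Benjamini-Hochberg adjustment over the
#' pairwise family.
#'
#' @param fc_by_cluster Named list of numeric vectors (log2 FC per cluster).
#' @return list(anova_p, pairwise_p) where `pairwise_p` is the lower-triangle
#'   matrix of BH-adjusted p-values from [stats::pairwise.t.test()].
#' @export
compare_fc_groups <- function(fc_by_cluster) {
  .check_groups(fc_by_cluster)
  values <- unlist(fc_by_cluster, use.names = FALSE)
  groups <- factor(rep(names(fc_by_cluster), lengths(fc_by_cluster)),
                   levels = names(fc_by_cluster))
  fit <- stats::lm(values ~ groups)
  an <- stats::anova(fit)
  pw <- stats::pairwise.t.test(values, groups, p.adjust.method = "BH",
                               pool.sd = FALSE)
  list(anova_p = an[["Pr(>F)"]][1], pairwise_p = pw$p.value)
}

#' Kruskal-Wallis with BH-adjusted pairwise Wilcoxon rank-sum tests
#'
#' Non-parametric battery for 'S - F' comparisons: Kruskal-Wallis one-way
#' analysis of variance across clusters, then all pairwise two-sided Wilcoxon
#' rank-sum tests with BH adjustment.
#'
#' @param sf_by_cluster Named list of numeric vectors.
#' @return list(kruskal_p, pairwise_p).
#' @export
compare_sf_groups <- function(sf_by_cluster) {
  .check_groups(sf_by_cluster)
  values <- unlist(sf_by_cluster, use.names = FALSE)
  groups <- factor(rep(names(sf_by_cluster), lengths(sf_by_cluster)),
                   levels = names(sf_by_cluster))
  kw <- stats::kruskal.test(values, groups)
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(values, groups, p.adjust.method = "BH"))
  list(kruskal_p = kw$p.value, pairwise_p = pw$p.value)
}

#' 2x2 chi-square enrichment test (above-threshold counts, locus vs control)
#'
#' Tests whether the proportion of regions above threshold differs between a
#' locus set and its control set; df = 1, no continuity correction.
#'
#' @param n_above_tt,n_tt Above-threshold count and total for the locus set.
#' @param n_above_ctrl,n_ctrl Same for the control set.
#' @return list(chisq, df, p_value, table).
#' @export
enrichment_chisq <- function(n_above_tt, n_tt, n_above_ctrl, n_ctrl) {
  if (n_above_tt > n_tt || n_above_ctrl > n_ctrl) {
    .stopf("'above' counts cannot exceed totals")
  }
  tab <- matrix(c(n_above_tt, n_tt - n_above_tt,
                  n_above_ctrl, n_ctrl - n_above_ctrl),
                nrow = 2, dimnames = list(c("above", "not_above"),
                                          c("locus", "control")))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = tab)
}
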