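# Coverage tracks and density matrices.
#
# All genomic coordinates in this package are 0-based, half-open [start, end).
# A CoverageTrack stores one rpm value per fixed-width bin per chromosome; the
# read-density (Rd) of any base-range is the length-weighted mean of the bins
# it overlaps, so downstream region means are exact for partial bins.

#' Construct a coverage track
#'
#' A coverage track holds per-chromosome binned signal in reads per million
#' mapped reads (rpm). It is the substrate for all read-density (Rd)
#' computations: region means, density matrices, average profiles.
#'
#' @param signal Named list of numeric vectors, one per chromosome, one rpm
#'   value per bin.
#' @param bin_size Bin width in bp.
#' @param sample_id Sample label.
#' @param total_mapped_reads Library size used for rpm normalization
#'   (informative only once the signal is already rpm).
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(signal, bin_size, sample_id = "sample",
                           total_mapped_reads = NA_real_) {
  if (!is.list(signal) || is.null(names(signal)) || any(names(signal) == "")) {
    .stopf("'signal' must be a named list of per-chromosome numeric vectors")
  }
  if (!.is_count(bin_size) || bin_size < 1) .stopf("'bin_size' must be a positive integer")
  for (cn in names(signal)) {
    v <- signal[[cn]]
    if (!is.numeric(v)) .stopf("signal for chromosome '%s' is not numeric", cn)
    if (anyNA(v) || any(v < 0)) .stopf("signal for chromosome '%s' has NA or negative rpm", cn)
  }
  structure(
    list(sample_id = sample_id, bin_size = as.integer(bin_size),
         total_mapped_reads = total_mapped_reads,
         signal = lapply(signal, as.numeric)),
    class = "CoverageTrack"
  )
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack '%s': %d chromosome(s), bin %d bp, total rpm %.2f\n",
              x$sample_id, length(x$signal), x$bin_size,
              sum(vapply(x$signal, sum, numeric(1))) ))
  invisible(x)
}

#' Chromosome lengths implied by a track (bin grid extent, bp)
#' @param track A `CoverageTrack`.
#' @return Named numeric vector of lengths in bp.
#' @export
track_chrom_lengths <- function(track) {
  stopifnot(inherits(track, "CoverageTrack"))
  vapply(track$signal, length, numeric(1)) * track$bin_size
}

#' Add two tracks bin-wise (e.g. to pool both-strand repair signal)
#' @param a,b `CoverageTrack`s on the same bin grid.
#' @return A `CoverageTrack` with summed signal.
#' @export
track_sum <- function(a, b) {
  stopifnot(inherits(a, "CoverageTrack"), inherits(b, "CoverageTrack"))
  if (a$bin_size != b$bin_size) .stopf("tracks have different bin sizes")
  if (!identical(sort(names(a$signal)), sort(names(b$signal)))) {
    .stopf("tracks cover different chromosomes")
  }
  sig <- lapply(names(a$signal), function(cn) {
    x <- a$signal[[cn]]; y <- b$signal[[cn]]
    if (length(x) != length(y)) .stopf("tracks disagree on length of '%s'", cn)
    x + y
  })
  names(sig) <- names(a$signal)
  coverage_track(sig, a$bin_size, sample_id = paste(a$sample_id, b$sample_id, sep = "+"))
}

#' Normalize read intervals to an rpm coverage track
#'
#' Each read contributes one count to every bin it overlaps (full-overlap
#' assignment, matching deposited wig/bedGraph coverage semantics); bin counts
#' are scaled by 1e6 / total mapped reads. Midpoint assignment is available
#' for sensitivity checks.
#'
#' @param reads data.frame with columns chrom, start, end (0-based half-open).
#' @param total_mapped Total mapped reads of the library (> 0).
#' @param bin_size Bin width in bp.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param sample_id Sample label.
#' @param assignment "overlap" (default) or "midpoint".
#' @return A `CoverageTrack`.
#' @export
normalize_rpm <- function(reads, total_mapped, bin_size, chrom_lengths,
                          sample_id = "sample",
                          assignment = c("overlap", "midpoint")) {
  assignment <- match.arg(assignment)
  .check_cols(reads, c("chrom", "start", "end"), "reads")
  if (!.is_number(total_mapped) || total_mapped <= 0) {
    .stopf("'total_mapped' must be > 0 (zero-read libraries cannot be rpm-normalized)")
  }
  if (is.null(names(chrom_lengths))) .stopf("'chrom_lengths' must be named")
  unknown <- setdiff(unique(reads$chrom), names(chrom_lengths))
  if (length(unknown)) {
    .warnf("dropping %d read(s) on chromosome(s) absent from 'chrom_lengths': %s",
           sum(reads$chrom %in% unknown), paste(unknown, collapse = ", "))
    reads <- reads[!reads$chrom %in% unknown, , drop = FALSE]
  }
  if (nrow(reads) && any(reads$end <= reads$start)) .stopf("reads must have end > start")
  sig <- lapply(names(chrom_lengths), function(cn) {
    nb <- ceiling(chrom_lengths[[cn]] / bin_size)
    r <- reads[reads$chrom == cn, , drop = FALSE]
    if (!nrow(r)) return(numeric(nb))
    if (assignment == "midpoint") {
      mid <- (r$start + r$end) %/% 2
      idx <- .clamp(mid %/% bin_size, 0, nb - 1)
      counts <- tabulate(idx + 1L, nbins = nb)
    } else {
      b0 <- .clamp(r$start %/% bin_size, 0, nb - 1)
      b1 <- .clamp((r$end - 1) %/% bin_size, 0, nb - 1)
      n <- b1 - b0 + 1
      idx <- rep.int(b0, n) + (sequence(n) - 1)
      counts <- tabulate(idx + 1L, nbins = nb)
    }
    counts * 1e6 / total_mapped
  })
  names(sig) <- names(chrom_lengths)
  coverage_track(sig, bin_size, sample_id = sample_id,
                 total_mapped_reads = total_mapped)
}

# Integral of the piecewise-constant signal: I(x) = rpm-weighted bp up to
# coordinate x. Enables exact length-weighted means over arbitrary ranges.
.track_integral <- function(sig, bin_size) {
  cs <- c(0, cumsum(sig)) * bin_size
  n <- length(sig)
  L <- n * bin_size
  function(x) {
    x <- .clamp(x, 0, L)
    j <- pmin(floor(x / bin_size), n - 1)
    cs[j + 1] + sig[j + 1] * (x - j * bin_size)
  }
}

#' Mean read density (Rd, rpm) over a region
#'
#' Length-weighted mean of the binned rpm signal over `[start, end)`; exact
#' for regions not aligned to the bin grid.
#'
#' @param track A `CoverageTrack`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bounds in bp.
#' @return Mean rpm (numeric scalar).
#' @export
mean_density <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (!chrom %in% names(track$signal)) .stopf("chromosome '%s' not in track", chrom)
  if (!(end > start)) .stopf("'end' must be > 'start'")
  I <- .track_integral(track$signal[[chrom]], track$bin_size)
  (I(end) - I(start)) / (end - start)
}

#' Build a strand-oriented density matrix around anchors
#'
#' One row per anchor, one column per bin of transcription-oriented offset.
#' Rows of minus-strand anchors run 5'->3' in transcription orientation, i.e.
#' the genomic extraction is reversed. Anchors whose window leaves the
#' chromosome are dropped with a warning.
#'
#' @param track A `CoverageTrack`.
#' @param anchors data.frame with columns id, chrom, pos (0-based bp), strand.
#' @param flank Symmetric flank in bp (window `[-flank, +flank)`), used for
#'   both sides unless `flank_up`/`flank_down` are given.
#' @param bin_size Matrix bin width in bp (need not equal the track's).
#' @param flank_up,flank_down Asymmetric window: `flank_up` bp upstream of the
#'   anchor to `flank_down` bp downstream, in transcription orientation.
#' @return Numeric matrix with rownames = anchor ids, colnames = bin start
#'   offsets (bp), attribute `bin_size`.
#' @export
density_matrix <- function(track, anchors, flank, bin_size,
                           flank_up = flank, flank_down = flank) {
  stopifnot(inherits(track, "CoverageTrack"))
  .check_cols(anchors, c("id", "chrom", "pos", "strand"), "anchors")
  .check_strand(anchors$strand)
  if (flank_up + flank_down < bin_size) .stopf("window smaller than one bin")
  offs <- seq(-flank_up, flank_down - bin_size, by = bin_size)
  lens <- track_chrom_lengths(track)
  span_lo <- ifelse(anchors$strand == "+", anchors$pos - flank_up,
                    anchors$pos - flank_down)
  span_hi <- ifelse(anchors$strand == "+", anchors$pos + flank_down,
                    anchors$pos + flank_up)
  ok <- anchors$chrom %in% names(lens) &
    span_lo >= 0 & span_hi <= lens[anchors$chrom]
  if (any(!ok)) {
    .warnf("dropping %d anchor(s) whose window leaves the chromosome", sum(!ok))
    anchors <- anchors[ok, , drop = FALSE]
  }
  mat <- matrix(NA_real_, nrow = nrow(anchors), ncol = length(offs),
                dimnames = list(anchors$id, offs))
  if (!nrow(anchors)) {
    .warnf("no valid anchors; returning empty matrix")
    attr(mat, "bin_size") <- bin_size
    return(mat)
  }
  integrals <- lapply(track$signal, .track_integral, bin_size = track$bin_size)
  bounds <- c(offs, flank_down)  # bin boundaries in transcription offsets
  for (i in seq_len(nrow(anchors))) {
    I <- integrals[[anchors$chrom[i]]]
    if (anchors$strand[i] == "+") {
      g <- anchors$pos[i] + bounds
      mat[i, ] <- diff(I(g)) / bin_size
    } else {
      g <- anchors$pos[i] - bounds
      mat[i, ] <- -diff(I(g)) / bin_size
    }
  }
  attr(mat, "bin_size") <- bin_size
  mat
}

#' Composite average profile of a density matrix
#'
#' Column means, optionally smoothed with a centered moving window (truncated
#' at the edges, as in moving-window smoothing of metagene plots).
#'
#' @param mat Matrix from [density_matrix()].
#' @param smooth_bins Moving-window width in bins; 1 = no smoothing.
#' @return data.frame with columns `offset` (bin start, bp) and `value`
#'   (mean rpm), attribute `bin_size`.
#' @export
average_profile <- function(mat, smooth_bins = 1) {
  if (!is.matrix(mat)) .stopf("'mat' must be a matrix")
  v <- colMeans(mat)
  v <- .moving_average(v, smooth_bins)
  out <- data.frame(offset = as.numeric(colnames(mat)), value = v)
  attr(out, "bin_size") <- attr(mat, "bin_size")
  out
}

#' Log2 fold-change matrix between two conditions
#'
#' Elementwise `log2((uv + pseudocount) / (ref + pseudocount))`, the FC
#' representation used for +UV vs NO-UV heatmaps. The pseudocount keeps empty
#' bins finite and is symmetric (0 vs 0 maps to 0).
#'
#' @param mat_uv,mat_ref Matrices of identical shape and region order.
#' @param pseudocount Added to both numerator and denominator (rpm).
#' @return Matrix of log2 fold changes.
#' @export
log2_fc_profile <- function(mat_uv, mat_ref, pseudocount = 0.25) {
  if (!identical(dim(mat_uv), dim(mat_ref))) .stopf("matrix shapes differ")
  if (!identical(rownames(mat_uv), rownames(mat_ref))) {
    .stopf("matrices have different region order")
  }
  out <- log2((mat_uv + pseudocount) / (mat_ref + pseudocount))
  attr(out, "bin_size") <- attr(mat_uv, "bin_size")
  out
}
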