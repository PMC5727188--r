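# Wave front / backend estimation on composite average profiles, elongation
# rates, and wave-relative clustering of loci.
#
# The front (leading edge) is the largest transcription offset up to which the
# composite profile stays at the post-UV enriched level; it is located as the
# last threshold-respecting run of bins, with sub-bin interpolation under a
# piecewise-constant (partial-bin coverage) model: if the crossing bin's value
# v sits between the plateau (hi) and the baseline (lo), the front covers a
# fraction (v - lo) / (hi - lo) of that bin. For a clean two-level step this
# recovers the step position exactly for any threshold strictly between the
# two levels.

.run_ok_ending <- function(ok, min_run) {
  r <- stats::filter(as.numeric(ok), rep(1, min_run), sides = 1)
  !is.na(r) & r == min_run
}

#' Wave front position from an average profile
#'
#' @param profile data.frame with columns offset (bin start, bp) and value
#'   (rpm), e.g. from [average_profile()].
#' @param threshold Transition threshold in rpm (between baseline and the
#'   enriched plateau).
#' @param min_run Number of consecutive bins that must sit at/above the
#'   threshold for a position to qualify (noise guard).
#' @return Front position in kb from the anchor, or NA (with a message) when
#'   the profile never reaches the threshold. If the profile never falls back
#'   below the threshold the last offset is returned with a warning.
#' @export
wave_front <- function(profile, threshold, min_run = 3) {
  .check_cols(profile, c("offset", "value"), "profile")
  v <- profile$value
  offs <- profile$offset
  if (length(v) < min_run + 1) .stopf("profile too short for min_run = %d", min_run)
  bin <- offs[2] - offs[1]
  ok <- v >= threshold
  qual <- which(.run_ok_ending(ok, min_run))
  if (!length(qual)) {
    message("wave_front: profile never exceeds the threshold; front undefined")
    return(NA_real_)
  }
  i <- max(qual)
  if (i == length(v)) {
    .warnf("profile still above threshold at the last offset; front truncated")
    return((offs[i] + bin) / 1000)
  }
  j <- i + 1L                       # first bin below threshold after the run
  hi <- v[i]
  lo <- if (j < length(v)) min(v[j], v[j + 1]) else v[j]
  f <- if (hi > lo) .clamp((v[j] - lo) / (hi - lo), 0, 1) else 0
  (offs[j] + f * bin) / 1000
}

#' Wave backend position from an average profile
#'
#' Symmetric to [wave_front()]: detects the depleted-to-enriched transition,
#' i.e. the smallest offset at which the profile rises above the threshold
#' with `min_run` persistence (used for drained, pri-elongating profiles).
#'
#' @inheritParams wave_front
#' @return Backend position in kb, or NA when the profile never rises above
#'   the threshold.
#' @export
wave_backend <- function(profile, threshold, min_run = 3) {
  .check_cols(profile, c("offset", "value"), "profile")
  v <- profile$value
  offs <- profile$offset
  if (length(v) < min_run + 1) .stopf("profile too short for min_run = %d", min_run)
  bin <- offs[2] - offs[1]
  ok <- v >= threshold
  ends <- which(.run_ok_ending(ok, min_run))
  if (!length(ends)) {
    message("wave_backend: profile never exceeds the threshold; backend undefined")
    return(NA_real_)
  }
  i <- min(ends) - min_run + 1L     # first bin of the first qualifying run
  if (i == 1L) {
    .warnf("profile already above threshold at the first offset; backend truncated")
    return(offs[1] / 1000)
  }
  j <- i - 1L                       # last bin below threshold before the run
  hi <- v[i]
  lo <- if (j > 1) min(v[j], v[j - 1]) else v[j]
  f <- if (hi > lo) .clamp((v[j] - lo) / (hi - lo), 0, 1) else 0
  (offs[j] + (1 - f) * bin) / 1000
}

#' Midpoint threshold between baseline and plateau levels of a profile
#'
#' Default "arbitrary threshold representing the transition state": the
#' midpoint between the pre-stress baseline and the post-UV enriched plateau,
#' each estimated as a 20%-trimmed mean over a declared calibration window of
#' offsets.
#'
#' @param profile Average profile data.frame (offset, value).
#' @param plateau_window,baseline_window Numeric length-2 offset ranges (bp)
#'   over which to estimate the two levels.
#' @return list(threshold, plateau, baseline).
#' @export
wave_threshold <- function(profile, plateau_window, baseline_window) {
  .check_cols(profile, c("offset", "value"), "profile")
  est <- function(w) {
    sel <- profile$offset >= w[1] & profile$offset < w[2]
    if (!any(sel)) .stopf("calibration window [%g, %g) contains no bins", w[1], w[2])
    mean(profile$value[sel], trim = 0.2)
  }
  plateau <- est(plateau_window)
  baseline <- est(baseline_window)
  if (plateau <= baseline) {
    .warnf("plateau estimate (%.3g) not above baseline (%.3g); threshold degenerate",
           plateau, baseline)
  }
  list(threshold = (plateau + baseline) / 2, plateau = plateau,
       baseline = baseline)
}

#' Average elongation rates between consecutive wave positions
#'
#' @param positions data.frame with columns time (min) and position_kb;
#'   undefined positions (NA) yield NA rates for the adjacent intervals.
#' @return data.frame t0, t1, rate (kb per min) per consecutive interval.
#' @export
elongation_rate <- function(positions) {
  .check_cols(positions, c("time", "position_kb"), "positions")
  if (nrow(positions) < 2) .stopf("need at least two timepoints")
  o <- order(positions$time)
  t <- positions$time[o]
  p <- positions$position_kb[o]
  if (any(diff(t) <= 0)) .stopf("timepoints must be strictly increasing")
  data.frame(t0 = t[-length(t)], t1 = t[-1],
             rate = diff(p) / diff(t))
}

#' Cluster loci relative to wave front positions
#'
#' A locus is Upstream at time t when its distance to the TSS is below the
#' front position; Downstream otherwise. Within each side loci are split into
#' `n_clusters` equal-count sub-clusters ordered by distance (sizes differ by
#' at most 1), labelled with Roman numerals running upstream-first
#' (I..III upstream, IV..VI downstream for the default 3 + 3).
#'
#' @param loci data.frame with a `distance_to_tss` column (bp).
#' @param front_by_time Named numeric vector of front positions in kb (names =
#'   timepoint labels). NA fronts give "unassigned" labels for that timepoint.
#' @param n_clusters Sub-clusters per side.
#' @return data.frame locus row replicated per timepoint with columns
#'   timepoint, side ("Up"/"Down"/"unassigned"), cluster (e.g. "I").
#' @export
cluster_loci_by_front <- function(loci, front_by_time, n_clusters = 3) {
  .check_cols(loci, "distance_to_tss", "loci")
  if (is.null(names(front_by_time))) .stopf("'front_by_time' must be named by timepoint")
  out <- list()
  for (tp in names(front_by_time)) {
    front_bp <- front_by_time[[tp]] * 1000
    lab <- data.frame(loci, timepoint = tp, side = "unassigned",
                      cluster = NA_character_, stringsAsFactors = FALSE)
    if (is.finite(front_bp)) {
      up <- loci$distance_to_tss < front_bp
      lab$side <- ifelse(up, "Up", "Down")
      romans <- as.character(utils::as.roman(seq_len(2 * n_clusters)))
      for (side_idx in 1:2) {
        sel <- which(if (side_idx == 1) up else !up)
        if (!length(sel)) next
        o <- sel[order(loci$distance_to_tss[sel])]
        grp <- ceiling(seq_along(o) / (length(o) / n_clusters))
        grp <- .clamp(grp, 1, n_clusters)
        lab$cluster[o] <- romans[(side_idx - 1) * n_clusters + grp]
      }
    }
    out[[tp]] <- lab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
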