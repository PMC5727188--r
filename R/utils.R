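# Internal helpers shared across modules.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.is_count <- function(x) .is_number(x) && x >= 0 && x == round(x)

.check_cols <- function(df, cols, what) {
  if (!is.data.frame(df)) .stopf("'%s' must be a data.frame", what)
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    .stopf("'%s' is missing required column(s): %s", what,
           paste(miss, collapse = ", "))
  }
  invisible(df)
}

# Seeds derived from a user seed stay below 2^31 and decorrelate the
# generators without hidden global state.
.derive_seed <- function(seed, salt) {
  (abs(as.integer(seed)) * 97L + as.integer(salt)) %% 2147483587L
}

# Centered moving average of odd-or-even width, truncated at the edges:
# width 3 on c(1,2,3,4,5) gives c(1.5, 2, 3, 4, 4.5).
.moving_average <- function(x, width) {
  if (!.is_count(width) || width < 1) .stopf("'width' must be a positive integer")
  n <- length(x)
  if (width == 1 || n == 0L) return(as.numeric(x))
  lo <- floor((width - 1) / 2)
  hi <- ceiling((width - 1) / 2)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - lo):min(n, i + hi)])
  }, numeric(1))
}

# Transcription-oriented strand checks
.check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) .stopf("strand must be '+' or '-'")
  invisible(strand)
}
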