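#' Tandem repeat structure of a sequence
#'
#' Estimates the repeat period of a (possibly imperfect) tandem array and
#' counts the unit copies it spans. The period `p` is chosen to maximize the
#' mean per-base identity between `seq[i]` and `seq[i + p]` over the overlap
#' (self-alignment at lag `p`); among ties the smallest period wins. The
#' maximal repeat span is then located by refining, at that lag, where local
#' identity stays at or above `min_identity` -- cloned probes often carry
#' non-repetitive vector flanks, so the span is reported rather than assumed
#' to cover the whole input. Within the span, consecutive windows of length
#' `p` are compared to the modal (consensus) unit; a window counts as a copy
#' when its identity reaches `min_identity`. A trailing truncated window
#' also counts when at least a third of the unit is present at that
#' identity, so an array cut mid-unit by cloning still reports every unit it
#' touches.
#'
#' If no period reaches `min_identity` anywhere, the sequence is flagged
#' non-repetitive and reported as a single copy of itself.
#'
#' @param seq nucleotide string (or `methylated_seq`).
#' @param min_period,max_period period search range (`max_period` at most
#'   half the sequence length).
#' @param min_identity minimum per-base identity for repeat calls.
#' @return an object of class `tandem_structure`: `period`, `n_copies`,
#'   `mean_copy_identity`, `repeat_span` (0-based half-open `c(start, end)`),
#'   `repetitive`, `consensus`.
#' @examples
#' unit <- "ACGTACGTTTGACGGATCCAGTCAAGGTCC"
#' tandem_structure(strrep(unit, 3), 2, 45)
#' @export
tandem_structure <- function(seq, min_period = 2L, max_period = NULL,
                             min_identity = 0.8) {
  if (inherits(seq, "methylated_seq")) seq <- seq$seq
  s <- check_acgt(seq_to_chars(seq))
  n <- length(s)
  max_period <- max_period %||% (n %/% 2L)
  stop_if_not(is_count(min_period, 2), "min_period must be >= 2")
  stop_if_not(is_count(max_period, min_period) && max_period <= n %/% 2L,
              "max_period must be in [min_period, length/2]")
  stop_if_not(is_number(min_identity, 0) && min_identity <= 1,
              "min_identity must be in [0, 1]")

  identities <- vapply(min_period:max_period, function(p) {
    mean(s[seq_len(n - p)] == s[(p + 1L):n])
  }, numeric(1))
  period <- (min_period:max_period)[which.max(identities)]
  p <- period

  m <- s[seq_len(n - p)] == s[(p + 1L):n]
  w_coarse <- min(p, n - p)
  coarse <- run_mean(m, w_coarse)
  cand <- which(coarse >= min_identity)

  non_repetitive <- structure(list(
    period = p, n_copies = 1L, mean_copy_identity = max(identities),
    repeat_span = c(start = 0L, end = n),
    repetitive = FALSE, consensus = paste(s, collapse = "")),
    class = "tandem_structure")
  if (length(cand) == 0L) return(non_repetitive)

  # refine span edges with a short window at the same lag
  w_edge <- min(30L, p, n - p)
  lo_from <- max(1L, min(cand) - p)
  hi_to <- min(n - p, max(cand) + w_coarse - 1L + p)
  edge_ok_fwd <- function(i) mean(m[i:(i + w_edge - 1L)]) >= min_identity
  edge_ok_rev <- function(i) mean(m[(i - w_edge + 1L):i]) >= min_identity
  start <- NA_integer_
  fwd_last <- n - p - w_edge + 1L
  if (lo_from <= fwd_last) for (i in lo_from:fwd_last) {
    if (edge_ok_fwd(i)) { start <- i; break }
  }
  end_lag <- NA_integer_
  if (hi_to >= w_edge) for (i in hi_to:w_edge) {
    if (edge_ok_rev(i)) { end_lag <- i; break }
  }
  if (is.na(start) || is.na(end_lag) || end_lag < start)
    return(non_repetitive)
  span_start <- start
  span_end <- end_lag + p  # last base participating in the lag-p match

  # windows of length p from the span start; consensus = modal base
  starts <- seq.int(span_start, span_end, by = p)
  starts <- starts[starts <= span_end]
  windows <- lapply(starts, function(a) {
    b <- min(a + p - 1L, span_end)
    s[a:b]
  })
  complete <- vapply(windows, length, integer(1)) == p
  stopifnot(any(complete))
  mat <- do.call(rbind, windows[complete])
  consensus <- apply(mat, 2L, function(col) names(which.max(table(col))))

  copy_identity <- vapply(windows, function(wv) {
    mean(wv == consensus[seq_along(wv)])
  }, numeric(1))
  coverage <- vapply(windows, length, integer(1)) / p
  counted <- copy_identity >= min_identity & (complete | coverage >= 1 / 3)
  if (!any(counted)) return(non_repetitive)
  id_basis <- if (any(counted & complete)) counted & complete else counted

  structure(list(
    period = p,
    n_copies = as.integer(sum(counted)),
    mean_copy_identity = mean(copy_identity[id_basis]),
    repeat_span = c(start = span_start - 1L, end = span_end),
    repetitive = TRUE,
    consensus = paste(consensus, collapse = "")
  ), class = "tandem_structure")
}

#' @export
print.tandem_structure <- function(x, ...) {
  if (x$repetitive)
    cat(sprintf(
      "tandem_structure: period %d nt, %d copies, identity %.3f, span [%d, %d)\n",
      x$period, x$n_copies, x$mean_copy_identity,
      x$repeat_span[["start"]], x$repeat_span[["end"]]))
  else
    cat("tandem_structure: non-repetitive (no period reached min_identity)\n")
  invisible(x)
}
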