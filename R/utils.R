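# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x, min = -Inf) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min
}

#' Otsu threshold of a numeric sample
#'
#' Histogram-based Otsu threshold (maximum between-class variance) computed on
#' an arbitrary set of pixel values, not a whole image, so it can be applied
#' within a single nucleus. Returns `NA` when the values are constant
#' (threshold undefined).
#'
#' @param values numeric vector of intensities.
#' @param nbins number of histogram bins.
#' @return threshold on the intensity scale, or `NA_real_`.
#' @keywords internal
#' @noRd
otsu_threshold <- function(values, nbins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(values) < 2L || rng[1] == rng[2]) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins)
  mids <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[nbins]
  mu <- m[nbins] / n  # grand mean
  w0 <- w[-nbins]
  between <- (mu * w0 - m[-nbins])^2 / (w0 * (n - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  breaks[k + 1L]
}

# Logical disc mask pixel coordinates: rows (y) and cols (x) inside a raster
# of dim x dim, centered at (cx, cy) with radius r. Row-major matrices,
# rows = y, cols = x.
disc_pixels <- function(cx, cy, r, nrow, ncol) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(ncol, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(nrow, ceiling(cy + r))
  xs <- x0:x1; ys <- y0:y1
  grid <- expand.grid(y = ys, x = xs)
  keep <- (grid$x - cx)^2 + (grid$y - cy)^2 <= r^2
  grid[keep, , drop = FALSE]
}

# Running mean of x with integer window w (result length length(x) - w + 1).
run_mean <- function(x, w) {
  cs <- cumsum(c(0, x))
  (cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]) / w
}

# IUPAC nucleotide codes -> allowed bases.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

seq_to_chars <- function(seq) {
  if (inherits(seq, "XString") || inherits(seq, "XStringSet"))
    seq <- as.character(seq)
  stop_if_not(is.character(seq) && length(seq) == 1L,
              "expected a single nucleotide string")
  strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
}

check_acgt <- function(chars, what = "sequence") {
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad) > 0L)
    stop(sprintf("%s contains a non-ACGT character '%s' at position %d",
                 what, chars[bad[1L]], bad[1L]), call. = FALSE)
  invisible(chars)
}

# Relabel a label mask so ids are contiguous 1..K (0 stays background).
relabel_mask <- function(mask) {
  ids <- sort(unique(as.vector(mask)))
  ids <- ids[ids > 0]
  out <- mask
  for (i in seq_along(ids)) out[mask == ids[i]] <- i
  storage.mode(out) <- "integer"
  attr(out, "n_objects") <- length(ids)
  out
}
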