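#' Double-normalize a FRAP trace
#'
#' Applies the standard double normalization: at every frame the
#' background-subtracted FRAP-spot signal is divided by the
#' background-subtracted control-spot signal (cancelling acquisition
#' photobleaching), and the result is scaled by the pre-bleach ratio so the
#' pre-bleach level is 1:
#' \deqn{N(t) = \frac{F(t) - B(t)}{C(t) - B(t)} \times
#'       \frac{\bar C_{pre} - \bar B_{pre}}{\bar F_{pre} - \bar B_{pre}}}
#' where the pre-bleach terms are means over the `n_prebleach` frames
#' (`prebleach = "mean"`, the default) or the last pre-bleach frame alone
#' (`prebleach = "last"`, for sensitivity checks). Time is re-zeroed at T0,
#' the first post-bleach frame; pre-bleach frames are excluded from the
#' returned series but their normalized mean is retained as a check (it is
#' exactly 1 for noise-free traces, for any bleach rate or background
#' level).
#'
#' @param trace a [frap_trace()].
#' @param prebleach `"mean"` or `"last"`.
#' @return an object of class `frap_norm`: list with `time_rel_s` (0 at T0),
#'   `value` (dimensionless), `prebleach_means` (frap, control, background),
#'   `prebleach_value_mean`, `n_prebleach`.
#' @examples
#' tr <- simulate_frap_trace(frap_sim_params(acquisition_bleach_rate = 0.001))
#' nt <- normalize_frap(tr)
#' nt$prebleach_value_mean
#' @export
normalize_frap <- function(trace, prebleach = c("mean", "last")) {
  stop_if_not(inherits(trace, "frap_trace"), "trace must be a frap_trace")
  prebleach <- match.arg(prebleach)
  npre <- attr(trace, "n_prebleach")
  t <- trace$time_s
  if (any(diff(t) <= 0)) stop("time_s must be strictly increasing", call. = FALSE)
  f <- trace$frap_spot; c_ <- trace$control_spot; b <- trace$background

  denom <- c_ - b
  scale <- max(abs(c_), 1e-12)
  bad <- which(abs(denom) < 1e-9 * scale)
  if (length(bad) > 0)
    stop(sprintf("control - background is zero at frame %d", bad[1L]),
         call. = FALSE)

  pre_idx <- if (prebleach == "mean") seq_len(npre) else npre
  f_pre <- mean(f[pre_idx]); c_pre <- mean(c_[pre_idx]); b_pre <- mean(b[pre_idx])
  if (abs(f_pre - b_pre) < 1e-9 * max(abs(f_pre), 1e-12))
    stop("pre-bleach FRAP - background denominator is zero", call. = FALSE)
  if (abs(c_pre - b_pre) < 1e-9 * max(abs(c_pre), 1e-12))
    stop("pre-bleach control - background denominator is zero", call. = FALSE)

  value_all <- (f - b) / denom * (c_pre - b_pre) / (f_pre - b_pre)
  post <- (npre + 1L):length(t)
  structure(list(
    time_rel_s = t[post] - t[npre + 1L],
    value = value_all[post],
    prebleach_means = c(frap = f_pre, control = c_pre, background = b_pre),
    prebleach_value_mean = mean(value_all[seq_len(npre)]),
    n_prebleach = npre
  ), class = "frap_norm")
}

#' @export
print.frap_norm <- function(x, ...) {
  cat(sprintf("frap_norm: %d post-bleach frames over %.4g s, prebleach mean %.6f\n",
              length(x$value), max(x$time_rel_s), x$prebleach_value_mean))
  invisible(x)
}

#' Aggregate normalized FRAP traces into a mean +/- SEM curve
#'
#' @param traces list of `frap_norm` objects sharing the acquisition grid.
#' @param time_tol maximum allowed timestamp deviation between traces;
#'   defaults to half the smallest frame interval.
#' @return a data frame with `time_rel_s`, `mean`, `sem`, `n`. With a single
#'   trace the SEM is `NA` and the attribute `sem_defined` is `FALSE`.
#' @export
aggregate_traces <- function(traces, time_tol = NULL) {
  stop_if_not(is.list(traces) && length(traces) >= 1 &&
                all(vapply(traces, inherits, logical(1), "frap_norm")),
              "traces must be a list of frap_norm objects")
  t0 <- traces[[1L]]$time_rel_s
  time_tol <- time_tol %||% (min(diff(t0)) / 2)
  for (i in seq_along(traces)) {
    ti <- traces[[i]]$time_rel_s
    stop_if_not(length(ti) == length(t0) && all(abs(ti - t0) <= time_tol),
                "trace %d is on a different acquisition grid", i)
  }
  v <- vapply(traces, function(x) x$value, numeric(length(t0)))
  v <- matrix(v, nrow = length(t0))
  n <- length(traces)
  out <- data.frame(time_rel_s = t0,
                    mean = rowMeans(v),
                    sem = if (n > 1) apply(v, 1, sd) / sqrt(n) else NA_real_,
                    n = n)
  attr(out, "sem_defined") <- n > 1
  out
}
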