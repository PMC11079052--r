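#' Parameters for a simulated FRAP acquisition
#'
#' Generates raw photobleaching time series in acquisition units: a bleached
#' spot (FRAP spot), an unbleached control spot, and an extracellular
#' background region, imaged on a regular grid with `n_prebleach` frames
#' recorded before the bleach. After the bleach the FRAP-spot signal follows
#' the two-phase association model
#' \deqn{Y(t) = y_0 + s_f (1 - e^{-k_f t}) + s_s (1 - e^{-k_s t})}
#' on the normalized scale (1 = pre-bleach level). Acquisition photobleaching
#' decays the FRAP and control spots alike as
#' `exp(-acquisition_bleach_rate * t)` (same illumination), leaving the
#' background untouched. Additive Gaussian noise of SD `noise_sd` (a.u.) is
#' applied to all three measured signals.
#'
#' @param y0 normalized signal immediately after the bleach.
#' @param span_fast,span_slow amplitudes of the fast and slow recovery phases
#'   (>= 0, normalized units).
#' @param k_fast,k_slow rate constants (1/s), `k_fast >= k_slow >= 0`.
#' @param duration_s total experiment duration in seconds.
#' @param interval_s frame interval in seconds (at least 10 frames required).
#' @param n_prebleach frames recorded before the bleach (>= 1).
#' @param acquisition_bleach_rate exponential decay rate (1/s) applied to the
#'   FRAP and control spots during acquisition.
#' @param background_level constant background (a.u.).
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param seed integer seed.
#' @param frap_level,control_level pre-bleach plateau levels of the FRAP and
#'   control spots (a.u.).
#' @return an object of class `frap_sim_params`.
#' @seealso [simulate_frap_trace()], [frap_regime_params()]
#' @export
frap_sim_params <- function(y0 = 0.2, span_fast = 0.3, k_fast = 0.1,
                            span_slow = 0.3, k_slow = 0.01,
                            duration_s = 400, interval_s = 1,
                            n_prebleach = 5L,
                            acquisition_bleach_rate = 0,
                            background_level = 50,
                            noise_sd = 0, seed = 1L,
                            frap_level = 1000, control_level = 800) {
  stop_if_not(is_number(span_fast, 0) && is_number(span_slow, 0),
              "spans must be >= 0")
  stop_if_not(is_number(k_fast, 0) && is_number(k_slow, 0) && k_fast >= k_slow,
              "rates must satisfy k_fast >= k_slow >= 0")
  stop_if_not(is_number(duration_s) && duration_s > 0, "duration_s must be positive")
  stop_if_not(is_number(interval_s) && interval_s > 0, "interval_s must be positive")
  stop_if_not(duration_s / interval_s >= 10, "need at least 10 frames")
  stop_if_not(is_count(n_prebleach, 1), "n_prebleach must be >= 1")
  stop_if_not(is_number(acquisition_bleach_rate, 0),
              "acquisition_bleach_rate must be >= 0")
  stop_if_not(is_number(background_level, 0), "background_level must be >= 0")
  stop_if_not(is_number(noise_sd, 0), "noise_sd must be >= 0")
  stop_if_not(is_number(frap_level) && frap_level > 0 &&
                is_number(control_level) && control_level > 0,
              "signal levels must be positive")
  structure(list(y0 = y0, span_fast = span_fast, k_fast = k_fast,
                 span_slow = span_slow, k_slow = k_slow,
                 duration_s = duration_s, interval_s = interval_s,
                 n_prebleach = as.integer(n_prebleach),
                 acquisition_bleach_rate = acquisition_bleach_rate,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 frap_level = frap_level, control_level = control_level),
            class = "frap_sim_params")
}

#' Two-phase association model curve
#'
#' @param t time since the bleach (s).
#' @param y0 intercept; `span_fast`, `k_fast`, `span_slow`, `k_slow` as in
#'   [frap_sim_params()].
#' @param span_fast,span_slow,k_fast,k_slow model parameters.
#' @return numeric vector of model values.
#' @export
two_phase_curve <- function(t, y0, span_fast, k_fast, span_slow, k_slow) {
  y0 + span_fast * (1 - exp(-k_fast * t)) + span_slow * (1 - exp(-k_slow * t))
}

#' Raw FRAP trace container
#'
#' Bundles the four measured series of a FRAP acquisition. Frame
#' `n_prebleach + 1` is the first post-bleach frame (T0).
#'
#' @param time_s strictly increasing acquisition times (s).
#' @param frap_spot,control_spot,background measured intensities (a.u.).
#' @param n_prebleach number of pre-bleach frames (>= 1).
#' @return an object of class `frap_trace` (a data frame with attribute
#'   `n_prebleach`).
#' @export
frap_trace <- function(time_s, frap_spot, control_spot, background,
                       n_prebleach) {
  n <- length(time_s)
  stop_if_not(length(frap_spot) == n && length(control_spot) == n &&
                length(background) == n, "all four series must share length")
  stop_if_not(is_count(n_prebleach, 1), "n_prebleach must be >= 1")
  stop_if_not(n >= n_prebleach + 10,
              "trace must have at least n_prebleach + 10 frames")
  stop_if_not(all(diff(time_s) > 0), "time_s must be strictly increasing")
  out <- data.frame(time_s = time_s, frap_spot = frap_spot,
                    control_spot = control_spot, background = background)
  attr(out, "n_prebleach") <- as.integer(n_prebleach)
  class(out) <- c("frap_trace", "data.frame")
  out
}

#' Simulate a raw FRAP trace
#'
#' @param params a `frap_sim_params` object.
#' @return a [frap_trace()] object. Deterministic for a fixed seed.
#' @examples
#' tr <- simulate_frap_trace(frap_sim_params(noise_sd = 0))
#' head(tr)
#' @export
simulate_frap_trace <- function(params) {
  stop_if_not(inherits(params, "frap_sim_params"),
              "params must be frap_sim_params()")
  p <- params
  withr::with_seed(p$seed, {
    n <- as.integer(round(p$duration_s / p$interval_s))
    time_s <- (seq_len(n) - 1) * p$interval_s
    npre <- p$n_prebleach
    t0 <- time_s[npre + 1L]
    y <- rep(1, n)
    post <- (npre + 1L):n
    y[post] <- two_phase_curve(time_s[post] - t0, p$y0, p$span_fast, p$k_fast,
                               p$span_slow, p$k_slow)
    decay <- exp(-p$acquisition_bleach_rate * time_s)
    frap <- p$background_level + p$frap_level * y * decay
    control <- p$background_level + p$control_level * decay
    background <- rep(p$background_level, n)
    if (p$noise_sd > 0) {
      frap <- frap + rnorm(n, 0, p$noise_sd)
      control <- control + rnorm(n, 0, p$noise_sd)
      background <- background + rnorm(n, 0, p$noise_sd)
    }
    frap_trace(time_s, frap, control, background, npre)
  })
}

#' Preset FRAP regimes with a prescribed plateau and T50
#'
#' Builds [frap_sim_params()] whose noise-free recovery reaches a given
#' mobile fraction (`plateau`, normalized fitted value at the end of the
#' window) and crosses 0.5 at a given `t50_s`. With `y0` and the two rates
#' fixed, the two spans solve a 2x2 linear system; the presets mirror the
#' two regimes seen in methylation-rich versus methylation-free cells: slow
#' (mobile ~75%, T50 ~75 s, a large stably bound pool) and fast (mobile
#' ~97.5%, T50 ~10 s, near-complete rapid exchange).
#'
#' @param regime `"slow"` or `"fast"`, or use `plateau`/`t50_s` directly.
#' @param plateau target normalized recovery at `duration_s` (0.5--1).
#' @param t50_s target time of half recovery (s).
#' @param y0,k_fast,k_slow fixed model parameters.
#' @param ... passed on to [frap_sim_params()] (e.g. `noise_sd`, `seed`).
#' @param duration_s,interval_s,n_prebleach acquisition grid.
#' @return a `frap_sim_params` object whose attribute `"targets"` records the
#'   prescribed plateau and T50.
#' @export
frap_regime_params <- function(regime = c("slow", "fast"),
                               plateau = NULL, t50_s = NULL,
                               y0 = NULL, k_fast = NULL, k_slow = NULL,
                               duration_s = 400, interval_s = 1,
                               n_prebleach = 5L, ...) {
  regime <- match.arg(regime)
  defaults <- switch(regime,
    slow = list(plateau = 0.752, t50_s = 75.5, y0 = 0.20, k_fast = 0.04,
                k_slow = 0.004),
    fast = list(plateau = 0.975, t50_s = 9.9, y0 = 0.30, k_fast = 0.15,
                k_slow = 0.02))
  plateau <- plateau %||% defaults$plateau
  t50_s <- t50_s %||% defaults$t50_s
  y0 <- y0 %||% defaults$y0
  k_fast <- k_fast %||% defaults$k_fast
  k_slow <- k_slow %||% defaults$k_slow
  stop_if_not(plateau > 0.5 && plateau <= 1, "plateau must be in (0.5, 1]")
  stop_if_not(t50_s > 0 && t50_s < duration_s, "t50_s must lie in the window")
  t_end <- duration_s - (n_prebleach + 1) * interval_s
  a <- rbind(c(1 - exp(-k_fast * t_end), 1 - exp(-k_slow * t_end)),
             c(1 - exp(-k_fast * t50_s), 1 - exp(-k_slow * t50_s)))
  b <- c(plateau - y0, 0.5 - y0)
  spans <- solve(a, b)
  stop_if_not(all(spans >= 0),
              "no valid spans for these targets; adjust y0 or the rates")
  out <- frap_sim_params(y0 = y0, span_fast = spans[1], k_fast = k_fast,
                         span_slow = spans[2], k_slow = k_slow,
                         duration_s = duration_s, interval_s = interval_s,
                         n_prebleach = n_prebleach, ...)
  attr(out, "targets") <- c(plateau = plateau, t50_s = t50_s)
  out
}

#' Write / read FRAP traces as CSV
#'
#' The CSV has columns `time_s, frap_spot, control_spot, background` and a
#' leading comment line `# n_prebleach: <k>` so the bleach index survives the
#' round trip.
#'
#' @param trace a `frap_trace`.
#' @param path file path.
#' @param n_prebleach override for files without the comment header.
#' @return `write_frap_trace()` the path invisibly; `read_frap_trace()` a
#'   `frap_trace`.
#' @export
write_frap_trace <- function(trace, path) {
  stop_if_not(inherits(trace, "frap_trace"), "trace must be a frap_trace")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_prebleach: %d", attr(trace, "n_prebleach")), con)
  write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_trace
#' @export
read_frap_trace <- function(path, n_prebleach = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*n_prebleach:", first))
    n_prebleach <- as.integer(sub("^#\\s*n_prebleach:\\s*", "", first))
  stop_if_not(!is.null(n_prebleach),
              "n_prebleach not recorded in '%s'; pass it explicitly", path)
  d <- read.csv(path, comment.char = "#")
  frap_trace(d$time_s, d$frap_spot, d$control_spot, d$background, n_prebleach)
}
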