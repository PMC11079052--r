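#' Fit the two-phase association model to a normalized FRAP curve
#'
#' Nonlinear least squares of
#' \deqn{Y(t) = y_0 + s_f (1 - e^{-k_f t}) + s_s (1 - e^{-k_s t})}
#' to the post-bleach normalized values, with the spans and rates bounded
#' below by zero (Levenberg-Marquardt via \pkg{minpack.lm}). Initialization:
#' `y0` at the first post-bleach value, total span at the mean of the last
#' 10 points minus `y0` split 70/30 between the fast and slow phases, rates
#' at 0.1 and 0.01 per second; a fixed schedule of rate-scaled restarts
#' guards against local minima, and the identifiability convention
#' `k_fast >= k_slow` is enforced by swapping after convergence.
#'
#' @param nt a [normalize_frap()] result (or any list with numeric
#'   `time_rel_s` and `value` of equal length).
#' @param restarts number of additional rate-scaled restarts (0--5).
#' @return an object of class `frap_fit` with components `coefficients`
#'   (`y0`, `span_fast`, `k_fast`, `span_slow`, `k_slow`), `rss`,
#'   `converged`, `data`, `n`. Methods: `print`, `coef`, `predict`,
#'   `fitted`, `residuals`, `summary` (returns the [summarize_fit()] of the
#'   fit), `plot`.
#' @examples
#' nt <- normalize_frap(simulate_frap_trace(frap_sim_params()))
#' fit <- fit_two_phase(nt)
#' coef(fit)
#' summary(fit)
#' @export
fit_two_phase <- function(nt, restarts = 5L) {
  t <- nt$time_rel_s
  v <- nt$value
  stop_if_not(is.numeric(t) && is.numeric(v) && length(t) == length(v),
              "time_rel_s and value must be numeric of equal length")
  stop_if_not(length(t) >= 10, "need at least 10 post-bleach points")

  if (var(v) < 1e-18) {
    # constant series: the flat curve is the exact least-squares solution
    out <- list(coefficients = c(y0 = mean(v), span_fast = 0, k_fast = 0,
                                 span_slow = 0, k_slow = 0),
                rss = sum((v - mean(v))^2), converged = TRUE,
                data = data.frame(t = t, v = v), n = length(t),
                diagnostics = "constant input; exact flat fit")
    class(out) <- "frap_fit"
    return(out)
  }

  y0_init <- v[1L]
  span_total <- max(mean(tail(v, 10L)) - y0_init, 0)
  base_start <- c(y0 = y0_init, sf = 0.7 * span_total, kf = 0.1,
                  ss = 0.3 * span_total, ks = 0.01)
  lower <- c(y0 = -Inf, sf = 0, kf = 0, ss = 0, ks = 0)
  # deterministic restart schedule: rescale both rates
  rate_scales <- c(1, 0.25, 4, 0.05, 20, 100)[seq_len(restarts + 1L)]

  best <- NULL
  d <- data.frame(t = t, v = v)
  for (sc in rate_scales) {
    start <- base_start
    start[["kf"]] <- base_start[["kf"]] * sc
    start[["ks"]] <- base_start[["ks"]] * sc
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ y0 + sf * (1 - exp(-kf * t)) + ss * (1 - exp(-ks * t)),
        data = d, start = as.list(start), lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }

  if (is.null(best)) {
    out <- list(coefficients = c(y0 = NA_real_, span_fast = NA_real_,
                                 k_fast = NA_real_, span_slow = NA_real_,
                                 k_slow = NA_real_),
                rss = NA_real_, converged = FALSE,
                data = d, n = length(t),
                diagnostics = "optimizer failed on all restarts")
    class(out) <- "frap_fit"
    return(out)
  }

  cf <- coef(best$fit)
  if (cf[["kf"]] < cf[["ks"]])
    cf <- c(y0 = cf[["y0"]], kf = cf[["ks"]], sf = cf[["ss"]],
            ks = cf[["kf"]], ss = cf[["sf"]])
  out <- list(
    coefficients = c(y0 = unname(cf[["y0"]]),
                     span_fast = unname(cf[["sf"]]),
                     k_fast = unname(cf[["kf"]]),
                     span_slow = unname(cf[["ss"]]),
                     k_slow = unname(cf[["ks"]])),
    rss = best$rss,
    converged = isTRUE(best$fit$convInfo$isConv),
    data = d, n = length(t),
    diagnostics = best$fit$convInfo$stopMessage %||% ""
  )
  class(out) <- "frap_fit"
  out
}

#' @export
coef.frap_fit <- function(object, ...) object$coefficients

#' @export
predict.frap_fit <- function(object, times = NULL, ...) {
  cf <- object$coefficients
  t <- times %||% object$data$t
  two_phase_curve(t, cf[["y0"]], cf[["span_fast"]], cf[["k_fast"]],
                  cf[["span_slow"]], cf[["k_slow"]])
}

#' @export
fitted.frap_fit <- function(object, ...) predict(object)

#' @export
residuals.frap_fit <- function(object, ...) object$data$v - fitted(object)

#' @export
print.frap_fit <- function(x, ...) {
  cat("Two-phase association FRAP fit\n")
  cat(sprintf("  n = %d points, rss = %.4g, converged: %s\n",
              x$n, x$rss, x$converged))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
summary.frap_fit <- function(object, t_end = NULL, ...) {
  summarize_fit(object, t_end = t_end)
}

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$v, pch = 16, cex = 0.4, col = "grey40",
                 xlab = "time since bleach (s)", ylab = "normalized FRAP", ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 400)
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Mobile / immobile fractions and T50 from a fitted recovery curve
#'
#' The mobile fraction is the fitted curve evaluated at the last observed
#' time point (the plateau convention: fluorescence at the end of the
#' experiment, not the asymptote), expressed in percent; the immobile
#' fraction is its complement to 100 exactly. T50 is the smallest time at
#' which the fitted curve crosses 0.5 -- half of the pre-bleach level, which
#' is 1 by construction of the normalization -- found by bisection to a
#' relative tolerance of 1e-6; it is absent (with `t50_defined = FALSE`)
#' when the curve never reaches 0.5 within the window.
#'
#' @param fit a converged [fit_two_phase()] result.
#' @param t_end end of the observation window (s); defaults to the last
#'   fitted time point. Must not exceed the fitted window.
#' @return an object of class `frap_summary`: `mobile_pct`, `immobile_pct`,
#'   `t50_s`, `t50_defined`, `t_end`.
#' @export
summarize_fit <- function(fit, t_end = NULL) {
  stop_if_not(inherits(fit, "frap_fit"), "fit must be a frap_fit")
  stop_if_not(isTRUE(fit$converged), "fit did not converge")
  t_max <- max(fit$data$t)
  t_end <- t_end %||% t_max
  stop_if_not(is_number(t_end, 0) && t_end <= t_max + 1e-9,
              "t_end outside the fitted window [0, %g]", t_max)
  y_end <- predict(fit, t_end)
  mobile <- 100 * y_end
  if (predict(fit, 0) >= 0.5) {
    t50 <- 0; defined <- TRUE
  } else if (y_end < 0.5) {
    t50 <- NA_real_; defined <- FALSE
  } else {
    lo <- 0; hi <- t_end
    # model is non-decreasing (spans, rates >= 0): plain bisection
    while ((hi - lo) > 1e-6 * max(hi, 1)) {
      mid <- (lo + hi) / 2
      if (predict(fit, mid) < 0.5) lo <- mid else hi <- mid
    }
    t50 <- (lo + hi) / 2; defined <- TRUE
  }
  structure(list(mobile_pct = mobile, immobile_pct = 100 - mobile,
                 t50_s = t50, t50_defined = defined, t_end = t_end),
            class = "frap_summary")
}

#' @export
print.frap_summary <- function(x, ...) {
  cat(sprintf("mobile %.1f%% | immobile %.1f%% | T50 %s (t_end = %g s)\n",
              x$mobile_pct, x$immobile_pct,
              if (x$t50_defined) sprintf("%.2f s", x$t50_s) else "not reached",
              x$t_end))
  invisible(x)
}
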