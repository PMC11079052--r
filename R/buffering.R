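#' Least-squares line on a log10 x axis
#'
#' Ordinary least squares of `y` (optionally log10-transformed) on
#' `log10(x)`, as used for expression scatterplots where fluorescence spans
#' decades. The returned R-squared is the squared Pearson correlation of the
#' regressed variables.
#'
#' @param x positive predictor (total expression, a.u.).
#' @param y response; must be positive when `log_y = TRUE`.
#' @param log_y log10-transform the response.
#' @return list with `r2`, `slope`, `slope_se`, `intercept`, `n`.
#' @examples
#' loglog_r2(c(1, 10, 100), c(2, 20, 200))  # slope 1, r2 1
#' @export
loglog_r2 <- function(x, y, log_y = TRUE) {
  stop_if_not(length(x) == length(y), "x and y must have equal length")
  stop_if_not(length(x) >= 3, "need at least 3 points")
  stop_if_not(all(is.finite(x)) && all(x > 0), "x must be positive")
  if (log_y) stop_if_not(all(is.finite(y)) && all(y > 0),
                         "y must be positive when log_y = TRUE")
  lx <- log10(x)
  ly <- if (log_y) log10(y) else y
  if (var(lx) == 0) stop("expression range degenerate (zero variance in x)",
                         call. = FALSE)
  fit <- lm(ly ~ lx)
  # noise-free inputs fit exactly; summary.lm's perfect-fit warning is expected
  s <- suppressWarnings(summary(fit))
  list(r2 = if (var(ly) == 0) 0 else unname(s$r.squared),
       slope = unname(coef(fit)[2L]),
       slope_se = unname(s$coefficients[2L, 2L]),
       intercept = unname(coef(fit)[1L]),
       n = length(x))
}

#' Concentration-buffering versus size-buffering test
#'
#' The phase-separation diagnostic: regress foci concentration (log10), foci
#' area and foci count against log10 total expression over a population of
#' cells. Under concentration buffering the focus concentration is pinned at
#' the saturation concentration (low R-squared) while foci grow (high area
#' R-squared); under size buffering the concentration tracks expression
#' (high R-squared) while area and count do not.
#'
#' Decision rule (two thresholds, exposed in the result):
#' `concentration_buffering` when `r2_concentration <= r2_low` and
#' `r2_area >= r2_high`; `size_buffering` when `r2_concentration >= r2_high`
#' and `max(r2_area, r2_count) <= r2_low`; otherwise `indeterminate`.
#'
#' Cells without foci carry no focus concentration and are excluded (their
#' number is reported); at least 10 foci-bearing cells are required.
#'
#' @param records data frame with columns `total_expression`,
#'   `foci_concentration`, `foci_area_um2`, `foci_count` (e.g. from
#'   [simulate_population()] or assembled from [measure_nuclei()] output).
#' @param r2_high,r2_low decision thresholds.
#' @return an object of class `buffering_test`: `r2_concentration`,
#'   `r2_area`, `r2_count` (each with slope and SE), `n_cells`,
#'   `n_excluded`, `regime_call`, `thresholds`.
#' @examples
#' pop <- simulate_population(population_params("size_buffering", seed = 1))
#' run_buffering_test(pop)
#' @export
run_buffering_test <- function(records, r2_high = 0.5, r2_low = 0.2) {
  need <- c("total_expression", "foci_concentration", "foci_area_um2",
            "foci_count")
  stop_if_not(all(need %in% names(records)),
              "records must have columns %s", paste(need, collapse = ", "))
  stop_if_not(r2_high > r2_low && r2_low >= 0 && r2_high <= 1,
              "thresholds must satisfy 0 <= r2_low < r2_high <= 1")
  keep <- records$foci_count > 0 & !is.na(records$foci_concentration)
  n_excluded <- sum(!keep)
  rec <- records[keep, , drop = FALSE]
  stop_if_not(nrow(rec) >= 10,
              "fewer than 10 foci-bearing cells (%d excluded)", n_excluded)

  conc <- loglog_r2(rec$total_expression, rec$foci_concentration, log_y = TRUE)
  area <- loglog_r2(rec$total_expression, rec$foci_area_um2, log_y = FALSE)
  count <- loglog_r2(rec$total_expression, rec$foci_count, log_y = FALSE)

  call <- if (conc$r2 <= r2_low && area$r2 >= r2_high) "concentration_buffering"
          else if (conc$r2 >= r2_high && max(area$r2, count$r2) <= r2_low)
            "size_buffering"
          else "indeterminate"

  structure(list(r2_concentration = conc$r2, r2_area = area$r2,
                 r2_count = count$r2,
                 slopes = data.frame(
                   quantity = c("log10_foci_concentration", "foci_area_um2",
                                "foci_count"),
                   slope = c(conc$slope, area$slope, count$slope),
                   se = c(conc$slope_se, area$slope_se, count$slope_se)),
                 n_cells = nrow(rec), n_excluded = n_excluded,
                 regime_call = call,
                 thresholds = c(r2_high = r2_high, r2_low = r2_low)),
            class = "buffering_test")
}

#' @export
print.buffering_test <- function(x, ...) {
  cat("Buffering test (foci response to total expression)\n")
  cat(sprintf("  n = %d cells (%d without foci excluded)\n",
              x$n_cells, x$n_excluded))
  cat(sprintf("  R2: concentration %.3f | area %.3f | count %.3f\n",
              x$r2_concentration, x$r2_area, x$r2_count))
  cat(sprintf("  call: %s (r2_high = %.2f, r2_low = %.2f)\n",
              x$regime_call, x$thresholds[["r2_high"]],
              x$thresholds[["r2_low"]]))
  invisible(x)
}

#' Stability of the foci/nucleoplasm ratio across expression levels
#'
#' Regresses the per-cell foci/nucleoplasm concentration ratio on log10
#' total expression. A flat slope (the "stable ratio" pattern) is the
#' size-buffering signature; under concentration buffering the ratio falls
#' as the nucleoplasm rises past the pinned focus concentration.
#'
#' @param records data frame with `total_expression` and either
#'   `ratio_foci_nucleoplasm` or both concentration columns.
#' @param stable_slope_bound absolute slope (per decade of expression) below
#'   which the ratio is flagged stable.
#' @return list with `slope`, `slope_se`, `ci95`, `r2`, `stable`, `n`.
#' @export
ratio_stability <- function(records, stable_slope_bound = 0.1) {
  stop_if_not("total_expression" %in% names(records),
              "records must have total_expression")
  ratio <- records$ratio_foci_nucleoplasm %||%
    (records$foci_concentration / records$nucleoplasm_concentration)
  stop_if_not(!is.null(ratio), "no ratio or concentration columns found")
  keep <- is.finite(ratio) & is.finite(records$total_expression)
  x <- records$total_expression[keep]
  y <- ratio[keep]
  stop_if_not(length(x) >= 3, "need at least 3 cells")
  fit <- loglog_r2(x, y, log_y = FALSE)
  ci <- fit$slope + c(-1, 1) * qt(0.975, fit$n - 2) * fit$slope_se
  list(slope = fit$slope, slope_se = fit$slope_se, ci95 = ci, r2 = fit$r2,
       stable = abs(fit$slope) <= stable_slope_bound, n = fit$n)
}

#' Bin cells into expression categories
#'
#' Splits cells into `n_bins` categories (low/medium/high for the default 3)
#' by rank of log10 total expression. Bin sizes follow the largest-remainder
#' rule (`floor(n / k)` each, the remainder going to the lowest bins first);
#' ties in expression are broken by stable cell order.
#'
#' @param records data frame with `total_expression` (and optionally
#'   `cell_id`).
#' @param n_bins number of bins.
#' @return an object of class `expression_bins`: data frame `cell_id`,
#'   `total_expression`, `bin` (ordered factor), with attributes
#'   `rule` and `degenerate` (all-equal expression).
#' @export
bin_expression <- function(records, n_bins = 3L) {
  stop_if_not("total_expression" %in% names(records),
              "records must have total_expression")
  n <- nrow(records)
  stop_if_not(is_count(n_bins, 2), "n_bins must be an integer >= 2")
  stop_if_not(n >= n_bins, "need at least n_bins cells")
  e <- records$total_expression
  stop_if_not(all(is.finite(e)) && all(e > 0), "expression must be positive")
  ids <- records$cell_id %||% seq_len(n)
  ord <- order(log10(e), seq_len(n))  # stable tie-break by input order
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  labels <- if (n_bins == 3L) c("low", "medium", "high")
            else paste0("bin", seq_len(n_bins))
  bin <- character(n)
  bin[ord] <- rep(labels, times = sizes)
  out <- data.frame(cell_id = ids, total_expression = e,
                    bin = factor(bin, levels = labels, ordered = TRUE))
  attr(out, "rule") <- sprintf(
    "rank on log10 expression; largest-remainder sizes (%s); ties by input order",
    paste(sizes, collapse = "/"))
  attr(out, "degenerate") <- length(unique(e)) == 1L
  class(out) <- c("expression_bins", "data.frame")
  out
}
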