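# Statistical toolbox: Welch t, Welch ANOVA (+ Brown-Forsythe companion),
# Games-Howell post-hoc, Tukey outlier fences.

as_group_list <- function(groups, value = NULL) {
  if (is.data.frame(groups)) {
    stop_if_not(all(c("value", "group") %in% names(groups)),
                "data frame input needs columns value and group")
    groups <- split(groups$value, groups$group)
  }
  stop_if_not(is.list(groups) && length(groups) >= 2,
              "need at least 2 groups")
  lapply(groups, as.numeric)
}

check_groups <- function(gs) {
  for (i in seq_along(gs)) {
    stop_if_not(length(gs[[i]]) >= 2,
                "group %d has fewer than 2 observations", i)
    stop_if_not(all(is.finite(gs[[i]])), "group %d has non-finite values", i)
    stop_if_not(var(gs[[i]]) > 0, "group %d has zero variance", i)
  }
  gs
}

#' Two-tailed unpaired Welch t test
#'
#' Welch's t statistic with Satterthwaite degrees of freedom; the standard
#' two-condition comparison for unequal variances.
#'
#' @param x,y numeric samples (each `n >= 2`, non-degenerate).
#' @return an object of class `welch_t`: `t`, `df`, `p`, `means`, `n`.
#' @examples
#' welch_t(rnorm(10), rnorm(12, 1))
#' @export
welch_t <- function(x, y) {
  stop_if_not(length(x) >= 2 && length(y) >= 2,
              "each sample needs at least 2 observations")
  stop_if_not(all(is.finite(x)) && all(is.finite(y)), "non-finite values")
  stop_if_not(var(x) + var(y) > 0, "zero pooled variance")
  ht <- t.test(x, y, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 means = c(x = mean(x), y = mean(y)),
                 n = c(x = length(x), y = length(y))),
            class = "welch_t")
}

#' @export
print.welch_t <- function(x, ...) {
  cat(sprintf("Welch t test: t = %.4f, df = %.2f, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Welch one-way ANOVA (with Brown-Forsythe companion F)
#'
#' Welch's heteroscedastic F* with its Satterthwaite-type denominator
#' degrees of freedom is the inferential test; the Brown-Forsythe F
#' statistic (group means weighted by `1 - n_i / N` variances) is reported
#' alongside as a companion, both labeled in the output.
#'
#' @param groups named list of numeric vectors, or a data frame with
#'   columns `value` and `group`.
#' @return an object of class `welch_anova`: `f_star`, `df1`, `df2`, `p`,
#'   `bf_f`, `bf_df1`, `bf_df2`, `bf_p`, and `group_summaries`
#'   (n, mean, variance per group).
#' @examples
#' welch_anova(list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8)))
#' @export
welch_anova <- function(groups) {
  gs <- check_groups(as_group_list(groups))
  k <- length(gs)
  vals <- unlist(gs, use.names = FALSE)
  grp <- factor(rep(seq_len(k), lengths(gs)))
  ht <- oneway.test(vals ~ grp, var.equal = FALSE)

  n <- lengths(gs)
  m <- vapply(gs, mean, numeric(1))
  v <- vapply(gs, var, numeric(1))
  N <- sum(n)
  grand <- sum(n * m) / N
  bf_f <- sum(n * (m - grand)^2) / sum((1 - n / N) * v)
  ci <- (1 - n / N) * v / sum((1 - n / N) * v)
  bf_df2 <- 1 / sum(ci^2 / (n - 1))
  bf_p <- pf(bf_f, k - 1, bf_df2, lower.tail = FALSE)

  structure(list(
    f_star = unname(ht$statistic), df1 = unname(ht$parameter[1L]),
    df2 = unname(ht$parameter[2L]), p = ht$p.value,
    bf_f = bf_f, bf_df1 = k - 1, bf_df2 = bf_df2, bf_p = bf_p,
    group_summaries = data.frame(group = names(gs) %||% as.character(seq_len(k)),
                                 n = as.integer(n), mean = m, variance = v)),
    class = "welch_anova")
}

#' @export
print.welch_anova <- function(x, ...) {
  cat(sprintf("Welch ANOVA: F* = %.4f, df = (%g, %.2f), p = %.4g\n",
              x$f_star, x$df1, x$df2, x$p))
  cat(sprintf("Brown-Forsythe companion: F = %.4f, df = (%g, %.2f), p = %.4g\n",
              x$bf_f, x$bf_df1, x$bf_df2, x$bf_p))
  invisible(x)
}

#' Games-Howell post-hoc pairwise comparisons
#'
#' For every pair of groups: the mean difference, its unpooled standard
#' error, the studentized-range statistic
#' `q = |diff| / sqrt((v1/n1 + v2/n2) / 2)`, per-pair Welch degrees of
#' freedom, and the adjusted p value from the studentized range distribution
#' with `k` groups (`stats::ptukey`). For two groups this reduces to the
#' Welch t test (`q = t * sqrt(2)`).
#'
#' @inheritParams welch_anova
#' @return an object of class `games_howell`: a data frame with one row per
#'   pair (`group1`, `group2`, `diff`, `se`, `q`, `df`, `p_adj`).
#' @export
games_howell <- function(groups) {
  gs <- check_groups(as_group_list(groups))
  k <- length(gs)
  nm <- names(gs) %||% as.character(seq_len(k))
  n <- lengths(gs)
  m <- vapply(gs, mean, numeric(1))
  v <- vapply(gs, var, numeric(1))
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    vi <- v[i] / n[i]; vj <- v[j] / n[j]
    se <- sqrt((vi + vj) / 2)
    q <- abs(m[i] - m[j]) / se
    df <- (vi + vj)^2 / (vi^2 / (n[i] - 1) + vj^2 / (n[j] - 1))
    p <- ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    data.frame(group1 = nm[i], group2 = nm[j], diff = m[i] - m[j],
               se = se, q = q, df = df, p_adj = min(max(p, 0), 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("games_howell", "data.frame")
  out
}

#' Tukey outlier flags and box-plot summary
#'
#' Quartiles use linear interpolation between order statistics
#' (`quantile(type = 7)`); the fences sit 1.5 interquartile ranges beyond
#' them and points strictly outside are flagged (a value exactly on a fence
#' is not an outlier).
#'
#' @param values numeric vector, `n >= 4`.
#' @return an object of class `tukey_outliers`: `flags` (logical per
#'   value), `fences` (lower, upper), `quartiles` (q1, q3).
#' @examples
#' tukey_outliers(c(1, 2, 3, 4, 100))
#' @export
tukey_outliers <- function(values) {
  stop_if_not(is.numeric(values) && length(values) >= 4,
              "need at least 4 values")
  stop_if_not(all(is.finite(values)), "non-finite values")
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  fences <- c(lower = q[1L] - 1.5 * iqr, upper = q[2L] + 1.5 * iqr)
  structure(list(flags = values < fences[1L] | values > fences[2L],
                 fences = fences, quartiles = c(q1 = q[1L], q3 = q[2L])),
            class = "tukey_outliers")
}

#' @export
print.tukey_outliers <- function(x, ...) {
  cat(sprintf("Tukey fences [%.4g, %.4g]: %d of %d values flagged\n",
              x$fences[1L], x$fences[2L], sum(x$flags), length(x$flags)))
  invisible(x)
}

#' Box-plot summary in the Tukey convention
#'
#' Median, quartiles, whisker ends (most extreme values within the Tukey
#' fences) and outliers, matching the convention of box plots whose
#' whiskers extend up to 1.5 interquartile ranges.
#'
#' @param values numeric vector, `n >= 4`.
#' @return list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
box_stats <- function(values) {
  fl <- tukey_outliers(values)
  inside <- values[!fl$flags]
  list(median = median(values), q1 = fl$quartiles[["q1"]],
       q3 = fl$quartiles[["q3"]],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = values[fl$flags])
}
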