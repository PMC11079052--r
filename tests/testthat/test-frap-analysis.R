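make_manual_trace <- function(pre = c(110, 100, 10), post = c(60, 90, 10),
                              n_pre = 5L, n_post = 20L) {
  n <- n_pre + n_post
  frap_trace(time_s = 0:(n - 1),
             frap_spot = c(rep(pre[1], n_pre), rep(post[1], n_post)),
             control_spot = c(rep(pre[2], n_pre), rep(post[2], n_post)),
             background = c(rep(pre[3], n_pre), rep(post[3], n_post)),
             n_prebleach = n_pre)
}

test_that("normalization is the identity on a flat trace and matches direct substitution", {
  flat <- make_manual_trace(pre = c(100, 100, 0), post = c(100, 100, 0))
  nf <- normalize_frap(flat)
  expect_equal(nf$value, rep(1, 20))
  expect_equal(nf$prebleach_value_mean, 1)

  nt <- normalize_frap(make_manual_trace())
  # (60 - 10)/(90 - 10) x (100 - 10)/(110 - 10) = 0.5625
  expect_equal(nt$value, rep(0.5625, 20), tolerance = 1e-12)
  expect_equal(unname(nt$prebleach_means), c(110, 100, 10))
})

test_that("degenerate denominators error naming the frame", {
  tr <- make_manual_trace()
  tr$control_spot[8] <- tr$background[8]
  expect_error(normalize_frap(frap_trace(tr$time_s, tr$frap_spot,
                                         tr$control_spot, tr$background, 5L)),
               "frame 8")
})

test_that("normalized curves are invariant to bleach rate and background, scale included", {
  ref <- normalize_frap(simulate_frap_trace(
    frap_sim_params(noise_sd = 0, acquisition_bleach_rate = 0,
                    background_level = 0)))
  for (lambda in c(0, 0.001, 0.002)) {
    for (bg in c(0, 50, 200)) {
      nt <- normalize_frap(simulate_frap_trace(
        frap_sim_params(noise_sd = 0, acquisition_bleach_rate = lambda,
                        background_level = bg)))
      expect_lt(max(abs(nt$value - ref$value)), 1e-6)
      expect_lt(abs(nt$prebleach_value_mean - 1), 1e-9)
    }
  }
  # common gain on all three inputs cancels exactly
  tr <- simulate_frap_trace(frap_sim_params(noise_sd = 2, seed = 3))
  gained <- frap_trace(tr$time_s, tr$frap_spot * 3.7, tr$control_spot * 3.7,
                       tr$background * 3.7, attr(tr, "n_prebleach"))
  expect_equal(normalize_frap(gained)$value, normalize_frap(tr)$value,
               tolerance = 1e-12)
})

test_that("the two-phase fit recovers noise-free parameters to 1e-4 relative", {
  p <- frap_sim_params(y0 = 0.2, span_fast = 0.5, k_fast = 0.1,
                       span_slow = 0.2, k_slow = 0.01, noise_sd = 0)
  fit <- fit_two_phase(normalize_frap(simulate_frap_trace(p)))
  expect_true(fit$converged)
  cf <- coef(fit)
  truth <- c(y0 = 0.2, span_fast = 0.5, k_fast = 0.1,
             span_slow = 0.2, k_slow = 0.01)
  expect_equal(cf[names(truth)], truth, tolerance = 1e-4)
  expect_gte(cf[["k_fast"]], cf[["k_slow"]])
})

test_that("a constant series fits a flat curve with near-zero spans", {
  nt <- list(time_rel_s = 0:99, value = rep(1, 100))
  fit <- fit_two_phase(nt)
  expect_true(fit$converged)
  expect_lt(max(abs(predict(fit) - 1)), 1e-6)
  expect_lt(coef(fit)[["span_fast"]] + coef(fit)[["span_slow"]], 1e-6)
})

test_that("noisy replicate fits recover the plateau with small bias", {
  p0 <- frap_regime_params("slow")
  plateaus <- vapply(1:20, function(s) {
    p <- frap_regime_params("slow", noise_sd = 0.02 * p0$frap_level, seed = s)
    fit <- fit_two_phase(normalize_frap(simulate_frap_trace(p)))
    summarize_fit(fit)$mobile_pct
  }, numeric(1))
  expect_lt(abs(mean(plateaus) - 75.2), 1)
})

test_that("fit summaries follow the plateau-complement and T50 conventions", {
  # plateau 0.752 -> mobile 75.2, immobile 24.8, complement exact
  p <- frap_regime_params("slow", noise_sd = 0)
  fit <- fit_two_phase(normalize_frap(simulate_frap_trace(p)))
  sm <- summarize_fit(fit)
  expect_equal(sm$mobile_pct, 75.2, tolerance = 1e-4)
  expect_equal(sm$immobile_pct, 24.8, tolerance = 1e-4)
  expect_identical(sm$mobile_pct + sm$immobile_pct, 100)
  expect_equal(sm$t50_s, 75.5, tolerance = 1e-3)

  # single-phase closed form: t50 = ln(2)/k at k = ln(2)/75
  single <- list(time_rel_s = seq(0, 400), value = 1 - exp(-log(2) / 75 * seq(0, 400)))
  fs <- fit_two_phase(single)
  expect_equal(summarize_fit(fs)$t50_s, 75, tolerance = 1e-3)

  # plateau below 0.5: T50 absent and flagged
  low <- list(time_rel_s = seq(0, 400),
              value = 0.1 + 0.35 * (1 - exp(-0.05 * seq(0, 400))))
  sl <- summarize_fit(fit_two_phase(low))
  expect_false(sl$t50_defined)
  expect_true(is.na(sl$t50_s))
  expect_error(summarize_fit(fs, t_end = 1000), "outside the fitted window")
})

test_that("bisection T50 agrees with a dense-grid oracle within one grid step", {
  for (regime in c("slow", "fast")) {
    p <- frap_regime_params(regime, noise_sd = 0)
    fit <- fit_two_phase(normalize_frap(simulate_frap_trace(p)))
    sm <- summarize_fit(fit)
    grid <- seq(0, sm$t_end, length.out = 1e5)
    oracle <- grid[which.max(predict(fit, grid) >= 0.5)]
    expect_lt(abs(sm$t50_s - oracle), diff(grid[1:2]))
  }
})

test_that("trace aggregation computes mean and SEM per frame", {
  p <- frap_sim_params(noise_sd = 0)
  nt <- normalize_frap(simulate_frap_trace(p))
  agg <- aggregate_traces(list(nt, nt))
  expect_equal(agg$mean, nt$value)
  expect_equal(agg$sem, rep(0, length(nt$value)))

  a <- nt; a$value <- rep(0.4, length(nt$value))
  b <- nt; b$value <- rep(0.6, length(nt$value))
  ab <- aggregate_traces(list(a, b))
  expect_equal(ab$mean, rep(0.5, length(nt$value)))
  expect_equal(ab$sem, rep(0.1, length(nt$value)), tolerance = 1e-12)

  single <- aggregate_traces(list(nt))
  expect_true(all(is.na(single$sem)))
  expect_false(attr(single, "sem_defined"))

  shifted <- nt; shifted$time_rel_s <- nt$time_rel_s + 0.9
  expect_error(aggregate_traces(list(nt, shifted)), "different acquisition grid")
})
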