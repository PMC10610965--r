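test_that("median filter matches hand-evaluated truncated windows", {
  expect_equal(median_filter(c(1, 9, 1), 3), c(5, 1, 5))
  expect_equal(median_filter(c(4, 2, 7, 0), 1), c(4, 2, 7, 0))
  expect_equal(median_filter(rep(3.5, 6), 4), rep(3.5, 6))
  # even window: mean of the two central order statistics
  expect_equal(median_filter(c(1, 3, 100, 7), 2), c(2, 51.5, 53.5, 7))
  expect_error(median_filter(c(1, 2), 0), "window")
  expect_error(median_filter(numeric(0), 3), "empty")
})

test_that("noise term is the sum of squared residuals", {
  expect_equal(compute_noise(c(1, 2, 3), c(1, 1, 1)), 5)
  expect_equal(compute_noise(3, 0), 9)
  expect_equal(compute_noise(c(2, 2), c(2, 2)), 0)
  expect_error(compute_noise(1:3, 1:2), "length mismatch")
})

test_that("SNR report handles degenerate and scaling cases", {
  # constant profile: median filter reproduces it -> +Inf sentinel
  rep <- compute_snr(rep(4, 10), 5)
  expect_identical(rep$snr_db, Inf)
  expect_true(rep$degenerate)
  expect_equal(rep$noise, 0)
  # scale invariance of the dB value
  p <- c(5, 1, 8, 2, 9, 3)
  expect_equal(compute_snr(p, 3)$snr_db, compute_snr(7 * p, 3)$snr_db)
  expect_error(compute_snr(numeric(0), 3), "empty")
  expect_error(compute_snr(c(0, 0, 0), 3), "no ridge energy")
})

test_that("window selection maximizes SNR with smallest-window tie-break", {
  expect_equal(select_window_max_snr(c(1, 5, 2), window_grid = 7), 7L)
  # constant profile: every window is degenerate (+Inf), ties -> smallest
  expect_equal(select_window_max_snr(rep(2, 8), window_grid = 2:10), 2L)
  p <- c(1, 1, 9, 1, 1, 1, 7, 1)
  w <- select_window_max_snr(p, 2:8)
  snrs <- vapply(2:8, function(wi) compute_snr(p, wi)$snr_db, numeric(1))
  expect_equal(compute_snr(p, w)$snr_db, max(snrs))
  expect_error(select_window_max_snr(p, integer(0)), "empty")
})

test_that("cross-validation diagnostics are seeded and degrade gracefully", {
  set.seed(8)
  p <- abs(rnorm(40))
  one <- cv_window_diagnostics(p, window_grid = 5, k = 10, runs = 20, seed = 2)
  expect_true(all(one$per_run_optimum == 5L))
  expect_equal(one$coefficient_of_variation, 0)
  a <- cv_window_diagnostics(p, 1:15, k = 10, runs = 30, seed = 3)
  b <- cv_window_diagnostics(p, 1:15, k = 10, runs = 30, seed = 3)
  expect_identical(a$per_run_optimum, b$per_run_optimum)
  expect_error(cv_window_diagnostics(p[1:5], 1:3, k = 10), "shorter than")
})

test_that("no window dominates CV on a noisy profile", {
  set.seed(12)
  p <- abs(rnorm(60))
  cv <- cv_window_diagnostics(p, 1:15, k = 10, runs = 100, seed = 5)
  expect_gt(cv$coefficient_of_variation, 0.05)
  expect_true(all(cv$per_run_optimum %in% 1:15))
})

test_that("full pipeline is deterministic and scale-invariant", {
  sig <- generate_bioimpedance(
    synthetic_spec(duration_s = 30, noise_sigma = 0.1, seed = 17)
  )
  r1 <- estimate_snr(sig$total)
  r2 <- estimate_snr(sig$total)
  expect_identical(r1$snr_db, r2$snr_db)
  expect_identical(r1$window, r2$window)
  scaled <- time_series(13.7 * sig$total$samples, sig$total$fs)
  r3 <- estimate_snr(scaled)
  expect_equal(r3$snr_db, r1$snr_db, tolerance = 1e-9)
})

test_that("SNR-vs-window curve peaks early and flattens at large windows", {
  sig <- generate_bioimpedance(
    synthetic_spec(duration_s = 60, noise_sigma = 0.1, seed = 5)
  )
  rep <- estimate_snr(sig$total)
  prof <- weighted_energy_profile(rep$intermediates$ridge_set)
  grid <- 2:40
  curve <- vapply(grid, function(w) compute_snr(prof, w)$snr_db, numeric(1))
  expect_lte(grid[which.max(curve)], 10)
  expect_lt(abs(curve[grid == 30] - curve[grid == 40]), 0.1)
})

test_that("errors are tagged with the failing pipeline stage", {
  # all-zero input survives the band-pass unchanged, then has zero range
  zero <- time_series(rep(0, 256), 64)
  expect_error(estimate_snr(zero), "normalize")
})

test_that("adaptive SNR responds to noise as an inverted U across regimes", {
  # the indicator rises under weak-to-moderate additive noise (profile
  # smoothing) and falls once noise rivals the heartbeat amplitude;
  # both limbs are asserted against the extremes
  snr_at <- function(sig) {
    mean(vapply(1:5, function(seed) {
      s <- generate_bioimpedance(
        synthetic_spec(duration_s = 30, noise_sigma = sig, seed = seed)
      )
      estimate_snr(s$total)$snr_db
    }, numeric(1)))
  }
  low <- snr_at(0.02)
  mid <- snr_at(1)
  high <- snr_at(8)
  expect_gt(mid, low)
  expect_gt(mid, high)
})
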