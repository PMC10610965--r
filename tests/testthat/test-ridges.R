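test_that("ridge points are strict interior local maxima along scale", {
  cw <- fake_cwt(matrix(c(1, 5, 1), 3, 4))
  rm <- find_ridge_points(cw)
  expect_equal(rm$mask, matrix(c(FALSE, TRUE, FALSE), 3, 4))
  expect_true(all(rm$d2[rm$mask] < 0))
  # monotone column: no interior maximum
  cw2 <- fake_cwt(matrix(c(1, 2, 3), 3, 2))
  expect_false(any(find_ridge_points(cw2)$mask))
  expect_error(find_ridge_points(fake_cwt(matrix(1, 2, 3))), "3 scales")
})

test_that("edge rows never carry ridge points and d2 < 0 wherever masked", {
  set.seed(21)
  for (i in 1:10) {
    cw <- fake_cwt(matrix(abs(rnorm(20 * 30)), 20, 30))
    rm <- find_ridge_points(cw)
    expect_false(any(rm$mask[c(1, 20), ]))
    expect_true(all(rm$d2[rm$mask] < 0))
  }
})

test_that("plateaus contribute one ridge point at the lowest-scale member", {
  col <- c(1, 4, 4, 4, 2, 1)
  cw <- fake_cwt(matrix(col, 6, 3))
  rm <- find_ridge_points(cw)
  expect_equal(which(rm$mask[, 1]), 2L)
  expect_equal(rm$mask, ridge_oracle(matrix(col, 6, 3)))
})

test_that("detection agrees with the brute-force per-column oracle", {
  set.seed(33)
  for (i in 1:10) {
    a <- matrix(abs(rnorm(32 * 64)), 32, 64)
    cw <- fake_cwt(a)
    expect_identical(find_ridge_points(cw)$mask, ridge_oracle(a))
  }
})

test_that("a pure tone's ridge stays within one scale-step of its frequency", {
  cw <- compute_cwt(sine_ts(1.0, duration_s = 32))
  rm <- find_ridge_points(cw)
  step <- 2^(1 / cw$params$voices_per_octave)
  n <- ncol(rm$mask)
  interior <- seq(round(0.1 * n), round(0.9 * n))
  ok <- vapply(interior, function(j) {
    rows <- which(rm$mask[, j])
    any(pmax(cw$freqs_hz[rows], 1 / cw$freqs_hz[rows]) < step * 1.0001)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("ridge statistics follow their definitions on constructed masks", {
  # scale 2 wins every column, scale 4 wins half of them
  a <- matrix(1, 5, 8)
  a[2, ] <- 10
  a[4, 1:4] <- 5
  cw <- fake_cwt(a)
  rset <- assemble_ridges(find_ridge_points(cw), cw)
  r2 <- rset$ridges[rset$ridges$scale_index == 2, ]
  r4 <- rset$ridges[rset$ridges$scale_index == 4, ]
  expect_equal(r2$bn, 1)
  expect_equal(r4$bn, 0.5)
  expect_equal(r2$energy, 80)
  expect_equal(r2$en, 100 * 80 / sum(a))
  expect_equal(r2$ew, r2$en * r2$bn)
  expect_equal(r4$ew, r4$en * 0.5)
})

test_that("a full-duration ridge holding all energy reaches en = ew = 100", {
  a <- matrix(0, 3, 6)
  a[2, ] <- 7
  cw <- fake_cwt(a)
  rset <- assemble_ridges(find_ridge_points(cw), cw)
  expect_equal(nrow(rset$ridges), 1L)
  expect_equal(rset$ridges$bn, 1)
  expect_equal(rset$ridges$en, 100)
  expect_equal(rset$ridges$ew, 100)
})

test_that("ridge energies respect their bounds and the product rule", {
  set.seed(44)
  for (i in 1:5) {
    cw <- fake_cwt(matrix(abs(rnorm(24 * 50)), 24, 50))
    rset <- assemble_ridges(find_ridge_points(cw), cw)
    r <- rset$ridges
    expect_true(all(r$bn >= 0 & r$bn <= 1))
    expect_true(all(r$en >= 0 & r$en <= 100))
    expect_true(all(r$ew <= pmin(r$en, 100 * r$bn) + 1e-12))
    expect_lte(sum(r$en), 100 + 1e-9)
  }
})

test_that("energy_power = 2 sums squared magnitudes", {
  a <- matrix(1, 3, 4)
  a[2, ] <- 3
  cw <- fake_cwt(a)
  rset <- assemble_ridges(find_ridge_points(cw), cw, energy_power = 2)
  expect_equal(rset$ridges$energy, 4 * 9)
  expect_equal(rset$ridges$en, 100 * 36 / sum(a^2))
  expect_error(assemble_ridges(find_ridge_points(cw), cw, energy_power = 3))
})

test_that("empty masks give an empty ridge set and the profile then errors", {
  cw <- fake_cwt(matrix(c(1, 2, 3), 3, 4)) # monotone: no ridges
  rset <- assemble_ridges(find_ridge_points(cw), cw)
  expect_equal(nrow(rset$ridges), 0L)
  expect_error(weighted_energy_profile(rset), "no ridges")
})

test_that("profile is ordered by scale and maps back to frequencies", {
  sig <- generate_bioimpedance(
    synthetic_spec(duration_s = 30, noise_sigma = 0.02, seed = 5)
  )
  rep <- estimate_snr(sig$total)
  prof <- weighted_energy_profile(rep$intermediates$ridge_set)
  expect_true(all(diff(attr(prof, "scale_index")) > 0))
  expect_true(all(prof >= 0 & prof <= 100))
  # dominant ridge of a low-noise heartbeat signal sits at the heart rate
  step <- 2^(1 / 16)
  f <- rep$dominant_ridge$freq_hz
  expect_lt(max(f / 1.0, 1.0 / f), step * 1.0001)
})
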