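test_that("generated signals decompose exactly into their components", {
  for (gen in list(generate_bioimpedance, generate_ppg)) {
    sig <- gen(synthetic_spec(duration_s = 20, seed = 42))
    comp_sum <- Reduce(`+`, lapply(sig$components, `[[`, "samples"))
    expect_lt(max(abs(sig$total$samples - comp_sum)), 1e-9)
  }
})

test_that("generation is bit-reproducible for a fixed seed", {
  spec <- synthetic_spec(duration_s = 15, seed = 99, ibi_jitter_s = 0.03)
  a <- generate_bioimpedance(spec)
  b <- generate_bioimpedance(spec)
  expect_identical(a$total$samples, b$total$samples)
  expect_identical(
    generate_ppg(spec)$total$samples,
    generate_ppg(spec)$total$samples
  )
})

test_that("zero noise gives an all-zero noise component and infinite true SNR", {
  sig <- generate_bioimpedance(synthetic_spec(duration_s = 10, noise_sigma = 0))
  expect_true(all(sig$components$noise$samples == 0))
  expect_identical(sig$true_snr_db, Inf)
})

test_that("heartbeat component pulses at the requested rate", {
  sig <- generate_bioimpedance(
    synthetic_spec(duration_s = 60, fs = 64, heart_rate_hz = 1.0, noise_sigma = 0)
  )
  hb <- sig$components$heartbeat$samples
  n <- length(hb)
  peaks <- sum(hb[2:(n - 1)] > hb[1:(n - 2)] & hb[2:(n - 1)] > hb[3:n] &
    hb[2:(n - 1)] > 0.5 * max(hb))
  expect_gte(peaks, 59)
  expect_lte(peaks, 61)
})

test_that("PPG with no wander and no noise is exactly heartbeat + respiration", {
  spec <- synthetic_spec(
    duration_s = 10, noise_sigma = 0, wander_amplitude = 0
  )
  # wander_amplitude = 0 fails validation (must be >= 0 is fine, but the
  # wander_hz constraint still applies); construct via synthetic_spec
  sig <- generate_ppg(spec)
  expect_true(all(sig$components$trend$samples == 0))
  expect_lt(
    max(abs(
      sig$total$samples -
        sig$components$heartbeat$samples -
        sig$components$respiration$samples
    )),
    1e-12
  )
})

test_that("clean total's dominant spectral peak sits at the heart rate", {
  dur <- 30
  spec <- synthetic_spec(
    duration_s = dur, heart_rate_hz = 1.2, noise_sigma = 0,
    respiration_amplitude = 0.15, wander_amplitude = 0.15
  )
  sig <- generate_ppg(spec)
  v <- sig$total$samples - mean(sig$total$samples)
  spec_power <- Mod(stats::fft(v))^2
  n <- length(v)
  freqs <- (0:(n - 1)) * sig$total$fs / n
  half <- 2:(n %/% 2)
  peak_freq <- freqs[half][which.max(spec_power[half])]
  expect_lt(abs(peak_freq - 1.2), 1 / dur + 1e-9)
})

test_that("ground-truth SNR decreases strictly with noise level", {
  sigmas <- c(0.01, 0.05, 0.1, 0.5, 1)
  snrs <- vapply(sigmas, function(s) {
    generate_bioimpedance(
      synthetic_spec(duration_s = 10, noise_sigma = s, seed = 7)
    )$true_snr_db
  }, numeric(1))
  expect_true(all(diff(snrs) < 0))
})

test_that("heartbeat component keeps >= 90% of its energy through the band-pass", {
  sig <- generate_bioimpedance(synthetic_spec(duration_s = 60, noise_sigma = 0))
  hb <- sig$components$heartbeat
  filt <- design_bandpass(bandpass_spec())
  hb_f <- apply_filter(hb, filt)
  expect_gte(sum(hb_f$samples^2) / sum(hb$samples^2), 0.9)
})

test_that("invalid spec fields are rejected by name", {
  expect_error(synthetic_spec(fs = -1), "fs")
  expect_error(synthetic_spec(heart_rate_hz = 0.2), "heart_rate_hz")
  expect_error(synthetic_spec(respiration_hz = 0.5), "respiration_hz")
  expect_error(synthetic_spec(noise_sigma = -0.1), "noise_sigma")
  expect_error(synthetic_spec(settle_tau_s = 0), "settle_tau_s")
})

test_that("pink noise option produces the requested marginal scale", {
  spec <- synthetic_spec(duration_s = 30, noise_sigma = 0.3, noise_kind = "pink")
  noise <- generate_bioimpedance(spec)$components$noise$samples
  expect_equal(stats::sd(noise), 0.3, tolerance = 1e-6)
})
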