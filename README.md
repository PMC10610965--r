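# ridgesnr

Signal-quality assessment for wearable bioimpedance and PPG heart-rate
recordings, built around an adaptive wavelet-ridge SNR indicator.

## The problem and the method

Wrist bioimpedance carries a pulsatile heartbeat component buried in a
settling electrode trend, respiration, baseline wander, and noise. The
signal is non-stationary and non-normal, so classical SNR estimators
(autocorrelation-based, fixed-threshold wavelet denoising) rest on
assumptions these signals violate.

The adaptive indicator works in the time–frequency plane. With the analytic
Morlet CWT `W(s, b)` and the scale-to-frequency map `f = ω₀ / (2π s)`:

1. **Ridge points**: cells where `|W|` has a local maximum along the scale
   axis (`∂|W|/∂s = 0`, `∂²|W|/∂s² < 0`).
2. **Per-ridge statistics** at scale `s_k`: normalized duration
   `bₙ = (#ridge samples)/N`, normalized energy
   `eₙ = 100 · Σⱼ|W(s_k, bⱼ*)| / ΣΣ|W|` (percent), and weighted ridge
   energy `e_w = eₙ · bₙ` — rewarding components that are intense **and**
   persistent, the signature of the heartbeat.
3. **Noise** = `Σᵢ |e_w,ᵢ − e_w,ᵢᶠⁱˡᵗ|²`, the residual against a
   median-filtered profile (window chosen by maximum SNR over 2–40;
   a k-fold CV diagnostic shows no window is systematically optimal).
4. **SNR** = `10·log₁₀(Σ e_w² / noise)` dB.

Two reference estimators are included: autocorrelation SNR, and classical
DWT shrinkage (`T = TM·σ̂_MAD·√(2 ln N)`, soft) with the threshold
multiplier selected where the min–max-normalized MSE and SNR curves
intersect over a 100-point grid in `[0.5, 10]`. A normality/stationarity
battery (KS, Anderson–Darling, Jarque–Bera; ADF, variance-ratio) documents
why the simple estimators are inappropriate. A seeded synthetic generator
provides bioimpedance/PPG surrogates with known clean/noise decomposition.

## Worked example

```r
library(ridgesnr)

sig <- generate_bioimpedance(synthetic_spec(noise_sigma = 0.1, seed = 1))
sig
#> <ridgesnr_synth_signal> 3840 samples @ 64 Hz, true SNR 9.73 dB

rep <- estimate_snr(sig$total)
rep
#> <ridgesnr_snr_report> adaptive-ridge: SNR = 3.10 dB (window 2, noise 3.83)
rep$dominant_ridge[, c("freq_hz", "bn", "en", "ew")]
#>    freq_hz    bn     en     ew
#> 43  0.9549 0.882 2.7315 2.4093

classical_snr_curve(sig$total)
#> <ridgesnr_classical> sym4 level 4, soft threshold: TM = 4.690, SNR = 35.45 dB
```

The report says: the dominant ridge sits at 0.95 Hz (the generator's 1 Hz
heart rate, one scale-step off), persists through 88% of the recording, and
carries 2.7% of total coefficient magnitude; the weighted-energy profile is
spiky enough that the median filter attributes a large share of it to
noise, giving 3.10 dB. The adaptive and classical values are not on a
common scale — the classical figure measures residual energy after
shrinkage of this particular record, the adaptive figure measures ridge-
profile structure. The normality and stationarity batteries on the
band-passed signal reject normality in all three tests (e.g. Jarque–Bera
2.3e5 vs. critical 5.99 at α = 0.05), the context in which the adaptive
indicator is intended to replace autocorrelation-type estimators.

An important property, documented in the methods vignette
(`vignettes/adaptive-ridge-snr.Rmd`): on synthetic signals the adaptive
indicator responds to additive white noise as an inverted U — it *rises*
with weak-to-moderate noise and falls only once noise rivals the heartbeat
amplitude. It measures ridge-profile smoothness and dominance, not the
additive noise floor. Treat it as a comparative quality score between
similar recordings, not an absolute noise measurement.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ridge-snr.R", package = "ridgesnr"))')
Rscript "$CLI" simulate  --config spec.yaml --out signal.csv --truth truth.json
Rscript "$CLI" estimate  --in signal.csv --out report.json
Rscript "$CLI" classical --in signal.csv --out result.json
Rscript "$CLI" tests     --in signal.csv --alpha 0.05 --out battery.csv
Rscript "$CLI" batch     --config batch.yaml --out summary.csv --json summary.json
```

CSV signals use `time_s,value` with a header. Exit codes: 0 ok, 1
config/usage error, 2 data error.

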