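test_that("resampling a constant tachogram is exact and counts samples", {
  rr <- rr_series(rep(800, 800))   # 640 s span
  tach <- resample_tachogram(rr, fs = 4)
  expect_true(all(abs(tach$values - 800) < 1e-9))
  span <- rr$t[length(rr$t)] - rr$t[1]
  expect_equal(length(tach$values), floor(span * 4) + 1)
})

test_that("a 0.1 Hz modulated tachogram has its FFT peak at 0.1 Hz", {
  rr <- gen_modulated_rr(1500, mod_freq_hz = 0.1)
  tach <- resample_tachogram(rr, fs = 4)
  v <- tach$values - mean(tach$values)
  n <- length(v)
  p <- Mod(fft(v))[2:(n %/% 2)]
  fgrid <- (1:(n %/% 2 - 1)) * tach$fs / n
  expect_equal(fgrid[which.max(p)], 0.1, tolerance = 2 * tach$fs / n)
})

test_that("stft localizes a pure modulation to within one bin", {
  rr <- gen_modulated_rr(2000, mod_freq_hz = 0.25)
  tach <- resample_tachogram(rr)
  sg <- stft_spectrogram(tach, window_s = 64)
  df <- sg$freqs[2] - sg$freqs[1]
  peak_f <- sg$freqs[apply(sg$power, 1, which.max)]
  expect_true(all(abs(peak_f - 0.25) <= df + 1e-12))
  expect_true(all(sg$power >= 0))
})

test_that("a constant signal has no power above DC", {
  tach <- resample_tachogram(rr_series(rep(800, 500)))
  sg <- stft_spectrogram(tach, window_s = 30)
  expect_lt(max(sg$power[, sg$freqs > 0]), 1e-12)
})

test_that("white-noise tachograms are spectrally flat across the HRV band", {
  # flatness is judged inside 0-0.4 Hz: the cubic-spline resampling
  # necessarily attenuates frequencies approaching the mean beat rate
  ratios <- vapply(1:20, function(s) {
    tach <- resample_tachogram(gen_gaussian_rr(3000, seed = s + 300))
    psd <- welch_psd(tach, window_s = 100)
    sel <- psd$freqs > 0.02 & psd$freqs <= 0.4
    max(psd$psd[sel]) / median(psd$psd[sel])
  }, 0)
  expect_lt(mean(ratios), 10)
})

test_that("Welch PSD satisfies Parseval within 5% on white noise", {
  devs <- vapply(1:10, function(s) {
    tach <- resample_tachogram(gen_gaussian_rr(4000, seed = s + 600))
    psd <- welch_psd(tach, window_s = 100)
    total <- pracma::trapz(psd$freqs, psd$psd)
    total / var(tach$values)
  }, 0)
  expect_equal(mean(devs), 1, tolerance = 0.05)
})

test_that("cwt puts the ridge at the modulation frequency", {
  rr <- gen_modulated_rr(1200, mod_freq_hz = 0.1)
  tach <- resample_tachogram(rr)
  freqs <- seq(0.02, 0.5, by = 0.01)
  sp <- cwt_spectrum(tach, freqs)
  n <- length(sp$times)
  central <- seq(round(n * 0.25), round(n * 0.75))
  ridge <- freqs[apply(sp$power[central, ], 1, which.max)]
  expect_true(all(abs(ridge - 0.1) <= 0.01 + 1e-12))
})

test_that("cwt ridge tracks a frequency switch between halves", {
  n <- 1200
  tt <- (seq_len(n) - 1) * 0.8
  f <- ifelse(seq_len(n) <= n / 2, 0.1, 0.3)
  x <- 800 + 50 * sin(2 * pi * f * tt)
  tach <- resample_tachogram(rr_series(x))
  freqs <- seq(0.05, 0.45, by = 0.01)
  sp <- cwt_spectrum(tach, freqs)
  ridge <- freqs[apply(sp$power, 1, which.max)]
  nt <- length(sp$times)
  q1 <- ridge[seq(round(nt * 0.15), round(nt * 0.35))]
  q2 <- ridge[seq(round(nt * 0.65), round(nt * 0.85))]
  expect_lt(max(abs(q1 - 0.1)), 0.03)
  expect_lt(max(abs(q2 - 0.3)), 0.03)
})

test_that("zero signal yields all-zero wavelet power", {
  tach <- resample_tachogram(rr_series(rep(700, 400)))
  sp <- cwt_spectrum(tach, seq(0.05, 0.4, by = 0.05))
  expect_lt(max(sp$power), 1e-12)
})

test_that("stft and cwt agree on the dominant frequency of a single tone", {
  rr <- gen_modulated_rr(2000, mod_freq_hz = 0.25)
  tach <- resample_tachogram(rr)
  sg <- stft_spectrogram(tach, window_s = 64)
  avg_stft <- colMeans(sg$power)
  f_stft <- sg$freqs[which.max(avg_stft)]
  freqs <- seq(0.05, 0.45, by = 0.01)
  sp <- cwt_spectrum(tach, freqs)
  f_cwt <- freqs[which.max(colMeans(sp$power))]
  expect_lt(abs(f_stft - f_cwt),
            (sg$freqs[2] - sg$freqs[1]) + 0.01 + 1e-12)
})

test_that("band powers integrate where the tone lives", {
  lfp <- band_powers(welch_psd(resample_tachogram(
    gen_modulated_rr(2000, mod_freq_hz = 0.1)), window_s = 200))
  expect_gt(lfp$lf / lfp$hf, 10)
  hfp <- band_powers(welch_psd(resample_tachogram(
    gen_modulated_rr(2000, mod_freq_hz = 0.3)), window_s = 200))
  expect_gt(hfp$hf / hfp$lf, 10)
})

test_that("zero PSD gives zero bands and an absent ratio", {
  bp <- band_powers(list(freqs = seq(0, 0.5, by = 0.002),
                         psd = rep(0, 251)))
  expect_equal(bp$vlf, 0)
  expect_equal(bp$lf, 0)
  expect_equal(bp$hf, 0)
  expect_true(is.na(bp$lf_hf_ratio))
})

test_that("uncovered bands are flagged missing", {
  bp <- band_powers(list(freqs = seq(0.05, 0.5, by = 0.002),
                         psd = rep(1, 226)))
  expect_true(is.na(bp$vlf))
  expect_true("vlf" %in% bp$missing_bands)
  expect_false(is.na(bp$hf))
})

test_that("input contracts are enforced", {
  rr <- rr_series(rep(800, 100))
  expect_error(resample_tachogram(rr, fs = 0), "positive")
  tach <- resample_tachogram(rr)
  expect_error(stft_spectrogram(tach, window_s = 1), "16 samples")
  expect_error(stft_spectrogram(tach, window_s = 200), "shorter than one")
  expect_error(cwt_spectrum(tach, numeric(0)), "empty")
  expect_error(cwt_spectrum(tach, c(0.1, 3)), "inside")
})
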