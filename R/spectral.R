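#' Evenly resample a tachogram
#'
#' The RR tachogram is irregularly sampled (one value per beat), so Fourier
#' and wavelet methods require interpolation onto a uniform grid first. A
#' cubic spline through `(t, RR)` is evaluated at `fs` Hz over the span of
#' the beat times. 4 Hz is the HRV convention: comfortably above twice the
#' 0.4 Hz upper edge of the HF band.
#'
#' @param series an [rr_series], length >= 4.
#' @param fs target sampling rate, Hz.
#' @return An object of class `resampled_tachogram`: `fs`, `t0` (s),
#'   `values` (ms, uniformly spaced at `1/fs`).
#' @export
resample_tachogram <- function(series, fs = 4) {
  stopifnot(inherits(series, "rr_series"))
  if (fs <= 0) stop("fs must be positive")
  if (length(series$intervals) < 4L)
    stop("resampling needs at least 4 beats")
  grid <- seq(series$t[1], series$t[length(series$t)], by = 1 / fs)
  vals <- spline(series$t, series$intervals, xout = grid, method = "fmm")$y
  structure(list(fs = fs, t0 = grid[1], values = vals),
            class = "resampled_tachogram")
}

#' @export
print.resampled_tachogram <- function(x, ...) {
  cat(sprintf("<resampled_tachogram> %d samples at %g Hz (%.1f s)\n",
              length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}

# One-sided Hann-window PSD of a single segment (mean removed).
# Scaling: psd * df integrates to the segment variance (Parseval).
segment_psd <- function(seg, fs) {
  n <- length(seg)
  w <- signal::hanning(n)
  v <- (seg - mean(seg)) * w
  X <- fft(v)
  nf <- n %/% 2 + 1L
  p <- (Mod(X[seq_len(nf)])^2) / (fs * sum(w^2))
  # double the interior bins (one-sided); DC and Nyquist are unique
  if (nf > 2L) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
  if (n %% 2 == 1L && nf > 1L) p[nf] <- 2 * p[nf]
  list(freqs = (seq_len(nf) - 1L) * fs / n, psd = p)
}

#' Short-time Fourier spectrogram of a resampled tachogram
#'
#' The signal is divided into Hann-windowed segments of `window_s` seconds
#' overlapping by the given fraction; each segment is mean-removed and its
#' one-sided PSD computed. Power is in ms^2/Hz.
#'
#' @param tach a [resample_tachogram()] result.
#' @param window_s segment length, seconds; `window_s * fs` must be at
#'   least 16 samples.
#' @param overlap fraction in `[0, 1)` (default 0.5).
#' @return An object of class `hrv_spectrogram`: `times` (segment centers,
#'   s), `freqs` (Hz), `power` (times x freqs matrix), `method = "stft"`,
#'   `params`.
#' @export
stft_spectrogram <- function(tach, window_s = 64, overlap = 0.5) {
  stopifnot(inherits(tach, "resampled_tachogram"))
  nwin <- round(window_s * tach$fs)
  if (nwin < 16L) stop("window too short: need window_s * fs >= 16 samples")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  N <- length(tach$values)
  if (N < nwin) stop("signal shorter than one window")
  hop <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, N - nwin + 1L, by = hop)
  out <- lapply(starts, function(s)
    segment_psd(tach$values[s:(s + nwin - 1L)], tach$fs))
  power <- do.call(rbind, lapply(out, `[[`, "psd"))
  structure(
    list(times = tach$t0 + (starts - 1L + (nwin - 1L) / 2) / tach$fs,
         freqs = out[[1]]$freqs,
         power = power,
         method = "stft",
         params = list(window_s = window_s, overlap = overlap)),
    class = "hrv_spectrogram")
}

#' Welch power spectral density of a resampled tachogram
#'
#' Mean of the per-segment one-sided PSDs of [stft_spectrogram()]. With
#' the default 300 s window the frequency resolution (1/300 Hz) resolves
#' the VLF band lower edge at 0.003 Hz.
#'
#' @inheritParams stft_spectrogram
#' @return An object of class `hrv_psd`: `freqs` (Hz), `psd` (ms^2/Hz),
#'   `params`.
#' @export
welch_psd <- function(tach, window_s = 300, overlap = 0.5) {
  sg <- stft_spectrogram(tach, window_s = window_s, overlap = overlap)
  structure(list(freqs = sg$freqs, psd = colMeans(sg$power),
                 params = sg$params),
            class = "hrv_psd")
}

#' Morlet continuous wavelet spectrum of a resampled tachogram
#'
#' FFT-based continuous wavelet transform with an analytic Morlet mother
#' wavelet (center frequency `omega0`, default 6). The requested frequency
#' grid is mapped to scales through the Morlet center-frequency relation
#' `f = (omega0 + sqrt(2 + omega0^2)) / (4 * pi * s)`; power is the squared
#' coefficient magnitude.
#'
#' @param tach a [resample_tachogram()] result.
#' @param freqs frequency grid, Hz, inside `(0, fs/2)`.
#' @param omega0 Morlet non-dimensional center frequency.
#' @return An object of class `hrv_spectrogram` with `method = "cwt"`;
#'   `power` is a times x freqs matrix.
#' @export
cwt_spectrum <- function(tach, freqs = seq(0.02, 0.5, by = 0.01),
                         omega0 = 6) {
  stopifnot(inherits(tach, "resampled_tachogram"))
  if (length(freqs) == 0L) stop("empty frequency grid")
  if (any(freqs <= 0 | freqs >= tach$fs / 2))
    stop("frequencies must lie strictly inside (0, fs/2)")
  x <- tach$values - mean(tach$values)
  N <- length(x)
  dt <- 1 / tach$fs
  xh <- fft(x)
  k <- 0:(N - 1)
  omega <- ifelse(k <= N / 2, 2 * pi * k / (N * dt),
                  -2 * pi * (N - k) / (N * dt))
  fourier_factor <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
  scales <- fourier_factor / freqs
  power <- vapply(scales, function(s) {
    psi_hat <- ifelse(omega > 0,
                      pi^(-0.25) * exp(-(s * omega - omega0)^2 / 2), 0)
    norm <- sqrt(2 * pi * s / dt)
    Mod(fft(xh * norm * psi_hat, inverse = TRUE) / N)^2
  }, numeric(N))
  structure(
    list(times = tach$t0 + (k) * dt,
         freqs = freqs,
         power = power,
         method = "cwt",
         params = list(wavelet = "morlet", omega0 = omega0)),
    class = "hrv_spectrogram")
}

#' @export
print.hrv_spectrogram <- function(x, ...) {
  cat(sprintf("<hrv_spectrogram> %s: %d times x %d freqs (%.3g-%.3g Hz)\n",
              x$method, length(x$times), length(x$freqs),
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' @export
plot.hrv_spectrogram <- function(x, xlab = "time (s)",
                                 ylab = "frequency (Hz)", ...) {
  graphics::image(x$times, x$freqs, x$power, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Standard HRV frequency bands
#'
#' The Task-Force convention: VLF 0.003-0.04 Hz, LF 0.04-0.15 Hz,
#' HF 0.15-0.4 Hz.
#'
#' @return Named list of `c(lo, hi)` pairs, Hz.
#' @export
hrv_bands <- function() {
  list(vlf = c(0.003, 0.04), lf = c(0.04, 0.15), hf = c(0.15, 0.4))
}

#' Band powers from a one-sided PSD
#'
#' Trapezoidal integration of the PSD over the VLF, LF and HF bands.
#' A band whose range is not covered by the frequency grid is returned as
#' `NA` with a `missing_bands` attribute.
#'
#' @param psd an `hrv_psd` (from [welch_psd()]), or a list with numeric
#'   `freqs` (Hz) and `psd` (ms^2/Hz).
#' @param bands named list of `c(lo, hi)` band edges, Hz.
#' @return An object of class `band_powers`: `vlf`, `lf`, `hf` (ms^2) and
#'   `lf_hf_ratio` (`NA` when `hf` is 0 or missing).
#' @export
band_powers <- function(psd, bands = hrv_bands()) {
  freqs <- psd$freqs
  pv <- psd$psd
  missing_bands <- character(0)
  pow <- lapply(names(bands), function(nm) {
    b <- bands[[nm]]
    if (min(freqs) > b[1] + 1e-9 || max(freqs) < b[2] - 1e-9) {
      missing_bands <<- c(missing_bands, nm)
      return(NA_real_)
    }
    sel <- freqs >= b[1] & freqs <= b[2]
    if (sum(sel) < 2L) {
      missing_bands <<- c(missing_bands, nm)
      return(NA_real_)
    }
    pracma::trapz(freqs[sel], pv[sel])
  })
  names(pow) <- names(bands)
  ratio <- if (!is.na(pow$lf) && !is.na(pow$hf) && pow$hf > 0)
    pow$lf / pow$hf else NA_real_
  structure(c(pow, list(lf_hf_ratio = ratio,
                        missing_bands = missing_bands)),
            class = "band_powers")
}

#' @export
print.band_powers <- function(x, ...) {
  cat(sprintf("<band_powers> VLF %s  LF %s  HF %s ms^2  LF/HF %s\n",
              fmt_or_na(x$vlf), fmt_or_na(x$lf), fmt_or_na(x$hf),
              fmt_or_na(x$lf_hf_ratio, "%.3f")))
  invisible(x)
}
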