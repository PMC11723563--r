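#' Power-law (1/f^alpha) background noise
#'
#' Generates Gaussian noise whose power spectral density falls off as
#' `1/f^alpha`, by spectrally shaping white Gaussian noise. The spectrum is
#' flattened below `f_min` to keep the low-frequency power finite, and the
#' draw is rescaled so its sample RMS equals `sigma` exactly.
#'
#' @param n Number of samples.
#' @param fs Sampling rate, Hz.
#' @param sigma Target RMS, uV. `sigma = 0` returns zeros.
#' @param alpha Spectral slope exponent (0 = white, 1 = pink).
#' @param f_min Flattening frequency for the 1/f divergence, Hz.
#' @return Numeric waveform of length `n`.
#' @export
powerlaw_noise <- function(n, fs, sigma, alpha = 1, f_min = 1) {
  stopifnot(n >= 1, fs > 0, sigma >= 0, f_min > 0)
  if (sigma == 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (alpha != 0) {
    f <- pmax(abs(fft_bin_freqs(n, fs)), f_min)
    g <- f^(-alpha / 2)
    g[1] <- 0 # remove DC
    w <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / n
  } else {
    w <- w - mean(w)
  }
  w * sigma / sqrt(mean(w^2))
}

#' Welch power spectral density estimate
#'
#' Averaged Hann-windowed periodograms over 50%-overlapping segments;
#' one-sided density. Used by the noise-calibration checks (background slope,
#' thermal-noise PSD).
#'
#' @param x Waveform.
#' @param fs Sampling rate, Hz.
#' @param nperseg Segment length in samples.
#' @return `data.frame(freq, psd)` with `psd` in (units of x)^2 / Hz.
#' @export
welch_psd <- function(x, fs, nperseg = 1024L) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1))
  u <- sum(win^2)
  nf <- floor(nperseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * win
    p <- Mod(stats::fft(seg))^2 / (fs * u)
    acc <- acc + p[1:nf]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nf] <- 1
  data.frame(freq = (0:(nf - 1)) * fs / nperseg, psd = psd * dbl)
}
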