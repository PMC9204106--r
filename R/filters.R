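#' @useDynLib mobigait, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft rnorm runif sd var median mad approx cor t.test p.adjust
#'   aov nextn quantile coef lm pt
#' @importFrom utils head tail
NULL

next_pow2 <- function(n) 2^ceiling(log2(max(n, 1)))

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x numeric vector.
#' @return complex vector of the same length whose real part is `x` and whose
#'   modulus is the instantaneous amplitude.
#' @keywords internal
analytic_signal <- function(x) {
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))   # pad to an FFT-friendly length
  X <- fft(c(x, numeric(n - n0)))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  (fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

#' Instantaneous amplitude (Hilbert envelope)
#' @param x numeric vector.
#' @return nonnegative numeric vector, `Mod(analytic_signal(x))`.
#' @keywords internal
hilbert_env <- function(x) Mod(analytic_signal(x))

# Windowed-sinc (Hamming) low-pass kernel, odd length
sinc_lowpass <- function(fc_norm, L) {
  m <- seq_len(L) - 1 - (L - 1) / 2
  h <- 2 * fc_norm * sinc_(2 * fc_norm * m)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  h <- h * w
  h / sum(h)
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Design a zero-phase FIR band-pass kernel
#'
#' Windowed-sinc (Hamming) design. Cutoffs are placed at the band edges minus/
#' plus half the transition bandwidth so that the band edges sit at the -6 dB
#' points, the convention used by standard EEG filtering tools.
#'
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges in Hz; `lo = 0` gives a low-pass, `hi >= fs/2` a
#'   high-pass.
#' @param trans_lo,trans_hi transition bandwidths (Hz); defaults scale with the
#'   corresponding edge.
#' @return numeric kernel of odd length.
#' @keywords internal
fir_design <- function(fs, lo, hi, trans_lo = NULL, trans_hi = NULL) {
  nyq <- fs / 2
  if (is.null(trans_lo)) trans_lo <- min(max(lo * 0.25, 0.5), lo)
  if (is.null(trans_hi)) trans_hi <- min(max(hi * 0.125, 2), max(nyq - hi, 1))
  trans <- c(if (lo > 0) trans_lo, if (hi < nyq) trans_hi)
  if (length(trans) == 0) stop("degenerate band: nothing to filter")
  L <- ceiling(3.3 / min(trans) * fs)
  if (L %% 2 == 0) L <- L + 1
  delta <- function(L) { d <- numeric(L); d[(L + 1) / 2] <- 1; d }
  if (lo <= 0) {                       # low-pass
    h <- sinc_lowpass((hi + trans_hi / 2) / fs, L)
  } else if (hi >= nyq) {              # high-pass
    h <- delta(L) - sinc_lowpass((lo - trans_lo / 2) / fs, L)
  } else {                             # band-pass
    h <- sinc_lowpass((hi + trans_hi / 2) / fs, L) -
      sinc_lowpass((lo - trans_lo / 2) / fs, L)
  }
  h
}

#' Apply an FIR kernel with zero net delay and reflected edges
#' @param x numeric vector.
#' @param h odd-length FIR kernel.
#' @return filtered vector, same length as `x`.
#' @keywords internal
fir_apply <- function(x, h) {
  n <- length(x)
  L <- length(h)
  half <- (L - 1) / 2
  pad <- min(half, n - 1)
  # reflect edges to limit transients
  xp <- c(2 * x[1] - x[pad:1 + 1], x, 2 * x[n] - x[n - (1:pad)])
  nf <- next_pow2(length(xp) + L - 1)
  y <- Re(fft(fft(c(xp, numeric(nf - length(xp)))) *
               fft(c(h, numeric(nf - L))), inverse = TRUE)) / nf
  y[(pad + half + 1):(pad + half + n)]
}

#' Zero-phase band-pass filter
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges in Hz (`lo = 0` low-pass only, `hi = Inf`
#'   high-pass only).
#' @param trans_lo,trans_hi optional transition bandwidths (Hz).
#' @return filtered vector, same length as `x`.
#' @export
filter_band <- function(x, fs, lo, hi, trans_lo = NULL, trans_hi = NULL) {
  stopifnot(fs > 0)
  hi <- min(hi, fs / 2)
  if (lo >= fs / 2) stop("low edge at or above Nyquist")
  h <- fir_design(fs, lo, hi, trans_lo, trans_hi)
  fir_apply(x, h)
}

#' Anti-aliased resampling to a target rate
#'
#' Applies a zero-phase FIR low-pass at 0.45 of the target rate when
#' downsampling, then linearly interpolates onto the new uniform grid.
#'
#' @param x numeric vector sampled at `fs`.
#' @param fs original sampling rate (Hz).
#' @param target_fs requested rate (Hz), must not exceed `fs`.
#' @return numeric vector of length `floor(length(x) * target_fs / fs)`.
#' @export
resample_sig <- function(x, fs, target_fs) {
  if (target_fs > fs) stop("target_fs exceeds the original sampling rate")
  if (target_fs == fs) return(x)
  xf <- filter_band(x, fs, 0, 0.45 * target_fs,
                    trans_hi = 0.1 * target_fs)
  n_out <- floor(length(x) * target_fs / fs)
  t_old <- (seq_along(x) - 1) / fs
  t_new <- (seq_len(n_out) - 1) / target_fs
  approx(t_old, xf, xout = t_new, rule = 2)$y
}

#' Band-limited Gaussian noise
#'
#' White Gaussian noise restricted to `[lo, hi]` Hz by Fourier masking and
#' rescaled to unit standard deviation. With `slope < 0` the in-band amplitude
#' spectrum is shaped as `f^slope` (e.g. `slope = -0.5` gives 1/f power,
#' pink-like noise).
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges (Hz).
#' @param slope spectral amplitude exponent (0 = flat).
#' @return numeric vector, unit SD, zero mean.
#' @export
bandlimited_noise <- function(n, fs, lo, hi, slope = 0) {
  n0 <- n
  n <- stats::nextn(n0, c(2, 3, 5))   # FFT-friendly length, then truncate
  X <- fft(rnorm(n))
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  af <- abs(f)
  mask <- as.numeric(af >= lo & af <= hi)
  if (slope != 0) {
    shape <- ifelse(af > 0, af^slope, 0)
    mask <- mask * shape
  }
  x <- Re(fft(X * mask, inverse = TRUE) / n)[seq_len(n0)]
  s <- sd(x)
  if (s == 0) stop("empty band")
  (x - mean(x)) / s
}

#' Welch power spectral density
#'
#' Hann-windowed segments with 50% overlap, one-sided density.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param seg_s segment length in seconds.
#' @return list with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_s = 2) {
  nseg <- min(length(x), round(seg_s * fs))
  step <- max(1, floor(nseg / 2))
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  acc <- numeric(floor(nseg / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(fft(seg))^2 / (fs * sum(w^2))
    half <- P[1:(floor(nseg / 2) + 1)]
    half[2:(length(half) - 1)] <- 2 * half[2:(length(half) - 1)]
    acc <- acc + half
  }
  list(freq = seq(0, floor(nseg / 2)) * fs / nseg, psd = acc / length(starts))
}

#' Band power from a Welch spectrum
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges (Hz), half-open `[lo, hi)`.
#' @param seg_s Welch segment length (s).
#' @return scalar power.
#' @keywords internal
band_power <- function(x, fs, lo, hi, seg_s = 2) {
  p <- welch_psd(x, fs, seg_s)
  sel <- p$freq >= lo & p$freq < hi
  sum(p$psd[sel]) * (p$freq[2] - p$freq[1])
}

#' Moving RMS envelope
#' @keywords internal
moving_rms <- function(x, n) {
  n <- max(1L, round(n))
  N <- length(x)
  half <- n %/% 2
  cs <- cumsum(c(0, x^2))
  i0 <- pmax(seq_len(N) - half, 1L)
  i1 <- pmin(seq_len(N) - half + n - 1L, N)
  sqrt((cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L))
}

#' Excess (Fisher) kurtosis
#' @keywords internal
excess_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(NA_real_)
  mean(x^4) / m2^2 - 3
}
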