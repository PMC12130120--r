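# Continuous-signal conditioning chain for surface EMG:
# band-pass -> notch -> rectification -> amplitude envelope.
#
# No DSP dependency is available, so IIR design is implemented here from
# first principles: Butterworth analog prototype, lowpass->bandpass
# transform, bilinear transform with prewarping, second-order-section
# realization. All filters are applied forward-backward (zero phase), so the
# effective attenuation order doubles and burst timing is not shifted.

# ---- filter design -------------------------------------------------------

# Butterworth band-pass as cascaded biquads (second-order sections).
# `order` is the analog prototype order; the band-pass has 2*order poles.
butter_bandpass_sos <- function(order, low, high, fs) {
  check_count(order, "order")
  check_number(low, "low", lower = 0)
  check_number(high, "high", lower = 0)
  if (low >= high) stop2("band-pass requires low < high (got %g >= %g)", low, high)
  if (fs <= 2 * high) {
    stop2("sampling rate %g Hz violates Nyquist for high cutoff %g Hz", fs, high)
  }
  # analog prototype poles on the unit circle, left half-plane
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  p_proto <- complex(modulus = 1, argument = theta)
  # bilinear prewarping of band edges
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # lowpass -> bandpass: pole p maps to roots of s^2 - p*bw*s + w0^2 = 0
  half <- p_proto * bw / 2
  disc <- sqrt(half^2 - w0^2)
  p_a <- c(half + disc, half - disc)
  z_a <- rep(0 + 0i, order)          # plus `order` zeros at infinity
  k_a <- bw^order
  # bilinear transform
  p_z <- (1 + p_a / fs2) / (1 - p_a / fs2)
  k_z <- k_a * Re(prod(fs2 - z_a) / prod(fs2 - p_a))
  # digital zeros: `order` at z = +1 (from s = 0), `order` at z = -1 (from inf)
  # pair conjugate poles into biquads, each with one (+1, -1) zero pair so
  # every section is the band-pass kernel k_i * (1 - z^-2)
  pu <- p_z[Im(p_z) > 1e-12]
  if (length(pu) != order) {
    # numerically real poles (possible for odd orders); fall back to pairing
    # sorted-by-modulus poles
    ord <- order(Mod(p_z))
    pu <- p_z[ord][seq(1, 2 * order, by = 2)]
  }
  g <- abs(k_z)^(1 / order)
  sg <- sign(k_z)
  sos <- matrix(0, nrow = order, ncol = 6,
                dimnames = list(NULL, c("b0", "b1", "b2", "a0", "a1", "a2")))
  for (i in seq_len(order)) {
    pp <- pu[i]
    a <- Re(c(1, -(pp + Conj(pp)), pp * Conj(pp)))
    s <- if (i == 1L) sg * g else g
    sos[i, ] <- c(s * c(1, 0, -1), a)
  }
  structure(sos, class = "emg_sos",
            settings = list(type = "butter_bandpass", order = order,
                            low = low, high = high, fs = fs))
}

# Second-order IIR notch (constrained pole-zero placement). Quality factor
# q sets the -3 dB rejection bandwidth freq/q.
notch_sos <- function(freq, fs, q = 30) {
  check_number(freq, "freq", lower = 0)
  check_number(q, "q", lower = 0)
  if (fs <= 2 * freq) {
    stop2("sampling rate %g Hz violates Nyquist for notch at %g Hz", fs, freq)
  }
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  sos <- matrix(c(b / a[1], a / a[1]), nrow = 1,
                dimnames = list(NULL, c("b0", "b1", "b2", "a0", "a1", "a2")))
  structure(sos, class = "emg_sos",
            settings = list(type = "iir_notch", freq = freq, q = q, fs = fs))
}

# Complex frequency response of an SOS cascade at frequencies f (Hz).
# Closed-form evaluation on the unit circle; used for documentation and by
# the test suite as one of two independent routes.
sos_freq_response <- function(sos, f, fs) {
  z1 <- exp(-2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(sos))) {
    num <- sos[i, 1] + sos[i, 2] * z1 + sos[i, 3] * z1^2
    den <- sos[i, 4] + sos[i, 5] * z1 + sos[i, 6] * z1^2
    h <- h * num / den
  }
  unname(h)
}

# ---- filtering -----------------------------------------------------------

# Single biquad, direct form I. The FIR part is vectorized; the recursive
# part runs in C via stats::filter.
biquad_filter <- function(x, s) {
  n <- length(x)
  w <- s[1] * x
  if (n > 1) w[2:n] <- w[2:n] + s[2] * x[1:(n - 1)]
  if (n > 2) w[3:n] <- w[3:n] + s[3] * x[1:(n - 2)]
  y <- stats::filter(w, filter = c(-s[5], -s[6]), method = "recursive")
  as.numeric(y)
}

sos_filter <- function(x, sos) {
  for (i in seq_len(nrow(sos))) x <- biquad_filter(x, sos[i, ])
  x
}

# Zero-phase filtering: odd-extension padding, forward pass, time reversal,
# second pass. Pad length covers the slowest transient of the cascade.
filtfilt_sos <- function(x, sos, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- 600L
  padlen <- min(n - 1L, as.integer(padlen))
  if (padlen > 0L) {
    pre <- 2 * x[1] - x[(padlen + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - padlen)]
    xe <- c(pre, x, post)
  } else {
    xe <- x
  }
  y <- sos_filter(xe, sos)
  y <- rev(sos_filter(rev(y), sos))
  if (padlen > 0L) y <- y[(padlen + 1):(padlen + n)]
  y
}

# ---- user-facing operations ---------------------------------------------

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (default 10--400 Hz, 4th-order analog
#' prototype) forward and backward, so the output has zero phase lag and the
#' effective attenuation order is doubled. This is the first stage of the
#' standard surface-EMG conditioning chain.
#'
#' @param x numeric vector, signal in microvolts.
#' @param fs sampling rate in Hz; must exceed `2 * high`.
#' @param low,high band edges in Hz.
#' @param order analog prototype order (the band-pass itself has
#'   `2 * order` poles; forward-backward application doubles attenuation).
#' @param padlen samples of odd-symmetric edge padding used to suppress
#'   start-up transients. Default 600 samples covers the 10 Hz edge at 1 kHz.
#' @return numeric vector of the same length as `x`.
#' @examples
#' x <- sin(2 * pi * 100 * seq(0, 1, by = 1e-3))
#' y <- emg_bandpass(x, fs = 1000)
#' @export
emg_bandpass <- function(x, fs, low = 10, high = 400, order = 4,
                         padlen = 600) {
  check_finite_vector(x, "x")
  sos <- butter_bandpass_sos(order, low, high, fs)
  if (length(x) < 3L) return(x - mean(x)) # degenerate input: remove DC only
  filtfilt_sos(x, sos, padlen = padlen)
}

#' Zero-phase mains-interference notch filter
#'
#' Narrow-band rejection of power-line interference (default 50 Hz) with a
#' second-order IIR notch of quality factor `q`, applied forward-backward.
#'
#' @inheritParams emg_bandpass
#' @param freq notch center frequency in Hz.
#' @param q quality factor; rejection bandwidth is `freq / q` Hz. The
#'   default 30 leaves 45/55 Hz essentially unattenuated.
#' @return numeric vector of the same length as `x`.
#' @export
emg_notch <- function(x, fs, freq = 50, q = 30, padlen = NULL) {
  check_finite_vector(x, "x")
  sos <- notch_sos(freq, fs, q)
  if (is.null(padlen)) padlen <- ceiling(3 * fs * q / freq)
  if (length(x) < 3L) return(x)
  filtfilt_sos(x, sos, padlen = padlen)
}

#' Full-wave rectification
#'
#' Elementwise absolute value, the conventional rectification step before
#' envelope extraction.
#'
#' @param x numeric vector (microvolts).
#' @return non-negative numeric vector.
#' @export
emg_rectify <- function(x) {
  check_finite_vector(x, "x")
  abs(x)
}

#' Moving-average amplitude envelope
#'
#' Centered moving average of the rectified signal over a window of
#' `window_ms` (default 30 ms). At the edges the window shrinks to the
#' available samples, so the output has the same length as the input and no
#' systematic onset bias is introduced.
#'
#' @param x numeric vector, rectified signal (microvolts).
#' @param fs sampling rate in Hz.
#' @param window_ms averaging window width in milliseconds; must cover at
#'   least one sample and not exceed the signal length.
#' @return numeric vector of the same length as `x`, all values `>= 0` when
#'   the input is non-negative.
#' @examples
#' env <- emg_envelope(abs(rnorm(1000)), fs = 1000)
#' @export
emg_envelope <- function(x, fs, window_ms = 30) {
  check_finite_vector(x, "x")
  w <- round(window_ms * fs / 1000)
  if (w < 1) stop2("envelope window of %g ms spans no sample at %g Hz", window_ms, fs)
  n <- length(x)
  if (w > n) stop2("envelope window (%d samples) longer than signal (%d)", w, n)
  # centered window: floor((w-1)/2) samples before, the rest after
  hb <- (w - 1L) %/% 2L
  ha <- w - 1L - hb
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - hb)
  hi <- pmin(n, i + ha)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Run the full conditioning chain on one channel
#'
#' Band-pass, notch, rectification and envelope extraction in the standard
#' order, returning the non-negative amplitude envelope together with the
#' settings that produced it.
#'
#' @inheritParams emg_bandpass
#' @param notch_freq notch center (Hz); `NA` disables the notch stage.
#' @param q notch quality factor.
#' @param window_ms envelope window (ms).
#' @return numeric envelope with attribute `"settings"` recording every
#'   filter parameter applied.
#' @export
emg_preprocess <- function(x, fs, low = 10, high = 400, order = 4,
                           notch_freq = 50, q = 30, window_ms = 30) {
  y <- emg_bandpass(x, fs, low = low, high = high, order = order)
  if (!is.na(notch_freq)) y <- emg_notch(y, fs, freq = notch_freq, q = q)
  env <- emg_envelope(emg_rectify(y), fs, window_ms = window_ms)
  structure(env, settings = list(
    fs = fs, bandpass = c(low = low, high = high, order = order),
    notch = c(freq = notch_freq, q = q), envelope_window_ms = window_ms,
    phase = "zero (forward-backward)"
  ))
}
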