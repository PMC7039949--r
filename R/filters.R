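#' @title IIR filter primitives
#'
#' @description
#' Minimal digital-filter toolkit used by the preprocessing pipeline and the
#' lowpass threshold model: Butterworth bandpass design via the bilinear
#' transform, direct-form-II-transposed filtering, steady-state initial
#' conditions, and zero-phase (forward-backward) application with
#' odd-reflection padding. The design path mirrors the standard
#' analog-prototype / band transform / bilinear construction so coefficients
#' agree with reference implementations to near machine precision.
#'
#' @name filters
#' @keywords internal
NULL

# Polynomial coefficients (descending powers) from complex roots; result is
# real up to rounding because roots come in conjugate pairs.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p) * rt
  Re(p)
}

#' Design a Butterworth bandpass filter
#'
#' Returns transfer-function coefficients of an order-`n` Butterworth
#' bandpass (final order `2n`) with passband edges `low`..`high` Hz at
#' sampling rate `fs`, designed by bilinear transform with frequency
#' prewarping.
#'
#' @param n prototype order (4 for the standard eABR setting).
#' @param low,high passband edge frequencies in Hz; `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz.
#' @return list with numerator `b` and denominator `a` (length `2n + 1`).
#' @examples
#' bf <- butter_bandpass(4, 100, 3000, 48828)
#' length(bf$b)
#' @export
butter_bandpass <- function(n, low, high, fs) {
  stopifnot(n >= 1, low > 0, high > low)
  if (high >= fs / 2) {
    stop("bandpass cutoffs must lie strictly below the Nyquist frequency (",
         fs / 2, " Hz)")
  }
  fs2 <- 2 * fs
  # prewarped analog edge frequencies (rad/s)
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # analog lowpass prototype poles (Butterworth circle, left half plane)
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # lowpass -> bandpass: each pole maps to a conjugate-symmetric pair
  ph <- p_lp * bw / 2
  disc <- sqrt(ph^2 - w0^2 + 0i)
  p_bp <- c(ph + disc, ph - disc)
  z_bp <- rep(0, n)                       # n zeros at s = 0 (plus n at Inf)
  gain <- bw^n
  # bilinear transform z = (1 + s/fs2) / (1 - s/fs2)
  pz <- (1 + p_bp / fs2) / (1 - p_bp / fs2)
  zz <- c((1 + z_bp / fs2) / (1 - z_bp / fs2), rep(-1, n))
  gz <- gain * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  b <- gz * poly_from_roots(zz)
  a <- poly_from_roots(pz)
  list(b = b, a = a)
}

#' Apply an IIR filter (single pass)
#'
#' Direct-form II transposed implementation of the standard difference
#' equation `a[1] y[t] = sum(b * x[t...]) - sum(a[-1] * y[t-1...])`.
#'
#' @param b,a transfer-function coefficients.
#' @param x numeric input signal.
#' @param zi optional initial delay-line state (length `max(length(a),
#'   length(b)) - 1`); default zeros.
#' @return filtered signal, same length as `x`.
#' @export
iir_filter <- function(b, a, x, zi = NULL) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b))) / a[1]
  a <- c(a, rep(0, nfilt - length(a))) / a[1]
  if (is.null(zi)) {
    # zero initial state: C-level moving-average + recursive passes
    xp <- c(rep(0, nfilt - 1), x)
    ma <- stats::filter(xp, b, method = "convolution", sides = 1)
    ma <- as.numeric(ma)[nfilt:(nfilt - 1 + length(x))]
    if (nfilt > 1) {
      ma <- as.numeric(stats::filter(ma, -a[2:nfilt], method = "recursive"))
    }
    return(ma)
  }
  z <- as.numeric(zi)
  stopifnot(length(z) == nfilt - 1)
  y <- numeric(length(x))
  nz <- nfilt - 1
  for (t in seq_along(x)) {
    xt <- x[t]
    yt <- b[1] * xt + z[1]
    if (nz > 1) {
      z[1:(nz - 1)] <- b[2:nz] * xt - a[2:nz] * yt + z[2:nz]
    }
    z[nz] <- b[nfilt] * xt - a[nfilt] * yt
    y[t] <- yt
  }
  y
}

# Steady-state delay-line state for a unit-step input (companion-matrix
# method); scaled by the first signal sample inside filtfilt.
lfilter_zi <- function(b, a) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b))) / a[1]
  a <- c(a, rep(0, nfilt - length(a))) / a[1]
  n <- nfilt - 1
  comp_t <- cbind(-a[2:nfilt], rbind(diag(1, n - 1), 0))
  rhs <- b[2:nfilt] - a[2:nfilt] * b[1]
  solve(diag(1, n) - comp_t, rhs)
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forwards and backwards so the net phase response is
#' zero and the magnitude response is squared. The signal is extended at
#' both ends by odd reflection before filtering and steady-state initial
#' conditions are used, which suppresses startup transients.
#'
#' @inheritParams iir_filter
#' @param padlen extension length per end; default `3 * (max(length(a),
#'   length(b)) - 1)`.
#' @return zero-phase filtered signal, same length as `x`.
#' @export
filtfilt_iir <- function(b, a, x, padlen = NULL) {
  nfilt <- max(length(a), length(b))
  if (is.null(padlen)) padlen <- 3 * (nfilt - 1)
  if (length(x) <= padlen) {
    stop("signal too short for zero-phase filtering (need > ", padlen,
         " samples)")
  }
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, ext, zi = zi * ext[1])
  y <- rev(y)
  y <- iir_filter(b, a, y, zi = zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + length(x))]
}

#' Design a Butterworth bandpass as second-order sections
#'
#' Same design as [butter_bandpass()] but returned as a cascade of
#' biquad sections. At narrow normalized bands (e.g. 100 Hz at a 48.8 kHz
#' rate) the expanded order-8 polynomial is numerically unstable (poles
#' cluster near `z = 1`), so all actual filtering uses this form.
#'
#' @inheritParams butter_bandpass
#' @return list of sections, each `list(b, a)` with length-3 coefficient
#'   vectors; the overall gain is folded into the first section.
#' @export
butter_bandpass_sos <- function(n, low, high, fs) {
  stopifnot(n >= 1, low > 0, high > low, high < fs / 2)
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  ph <- p_lp * bw / 2
  disc <- sqrt(ph^2 - w0^2 + 0i)
  p_bp <- c(ph + disc, ph - disc)
  gz <- bw^n * Re(fs2^n / prod(fs2 - p_bp))
  pz <- (1 + p_bp / fs2) / (1 - p_bp / fs2)
  # pair each pole with its conjugate into one section; zeros: one at +1
  # and one at -1 per section
  keep <- pz[Im(pz) >= 0]
  keep <- keep[order(-abs(keep))]
  sections <- lapply(seq_len(n), function(i) {
    p <- keep[i]
    a <- c(1, -2 * Re(p), abs(p)^2)
    b <- c(1, 0, -1)
    if (i == 1) b <- b * gz
    list(b = b, a = a)
  })
  sections
}

#' Apply a second-order-section cascade (single pass)
#'
#' @param sos sections from [butter_bandpass_sos()].
#' @param x numeric signal.
#' @return filtered signal.
#' @export
sos_filter <- function(sos, x) {
  for (s in sos) x <- iir_filter(s$b, s$a, x)
  x
}

#' Zero-phase filtering with a second-order-section cascade
#'
#' Forward-backward application with odd-reflection padding and per-pass
#' steady-state initial conditions per section.
#'
#' @inheritParams sos_filter
#' @param padlen extension length per end (default `3 * 2 * n_sections`).
#' @return zero-phase filtered signal, same length as `x`.
#' @export
sos_filtfilt <- function(sos, x, padlen = NULL) {
  if (is.null(padlen)) padlen <- 6 * length(sos)
  if (length(x) <= padlen) {
    stop("signal too short for zero-phase filtering (need > ", padlen,
         " samples)")
  }
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)])
  pass <- function(v) {
    for (s in sos) {
      zi <- lfilter_zi(s$b, s$a)
      v <- iir_filter(s$b, s$a, v, zi = zi * v[1])
    }
    v
  }
  y <- rev(pass(ext))
  y <- rev(pass(y))
  y[(padlen + 1):(padlen + length(x))]
}

#' Frequency response magnitude of a digital filter
#'
#' @param b,a transfer-function coefficients.
#' @param f frequencies in Hz at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return complex response at each frequency.
#' @export
freqz_response <- function(b, a, f, fs) {
  w <- 2 * pi * f / fs
  ejw <- exp(-1i * outer(w, seq_along(b) - 1))
  num <- as.vector(ejw %*% b)
  ejwa <- exp(-1i * outer(w, seq_along(a) - 1))
  den <- as.vector(ejwa %*% a)
  num / den
}
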