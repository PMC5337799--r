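#' Discrete Hilbert transform
#'
#' Computes the Hilbert transform of a real vector by the standard
#' frequency-domain analytic-signal construction: negative-frequency
#' bins are zeroed, positive bins doubled, DC and Nyquist left
#' untouched; the transform is the imaginary part of the inverse FFT.
#' For band-limited discrete signals this realises the continuous
#' principal-value convolution exactly.
#'
#' @param x Real numeric vector, length >= 4, finite values.
#' @return Numeric vector: the Hilbert transform of `x`.
#' @examples
#' t <- (0:1023) / 200
#' max(abs(hilbert_transform(cos(2 * pi * 5 * t))[100:900] -
#'         sin(2 * pi * 5 * t)[100:900]))
#' @export
hilbert_transform <- function(x) {
  Im(analytic_fft(x))
}

# Complex analytic signal z = x + i*H(x) via FFT.
analytic_fft <- function(x) {
  check_numeric_vector(x, "x", min_len = 4L)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Phase unwrapping: add multiples of 2*pi so jumps never exceed pi.
unwrap_phase <- function(p) {
  d <- diff(p)
  steps <- -round(d / (2 * pi))
  p + c(0, cumsum(steps)) * 2 * pi
}

#' Analytic signal and instantaneous quantities
#'
#' Builds the analytic signal `z = c + i * H(c)` of an IMF (or any
#' narrow-band vector) and derives the instantaneous amplitude
#' `a = |z|`, the unwrapped four-quadrant phase `phi = Arg(z)`, and the
#' instantaneous frequency as the discrete derivative of the phase
#' (central differences in the interior, one-sided at the ends). With
#' `fs` supplied the frequency is in Hz, otherwise in radians per
#' sample.
#'
#' @param x Real numeric vector, length >= 4.
#' @param fs Optional sampling rate in Hz.
#' @return An object of class `analytic_signal` with elements `signal`,
#'   `hilbert`, `amplitude`, `phase`, `frequency`, `fs`.
#' @examples
#' a <- analytic_signal(cos(2 * pi * 1 * (0:2047) / 200), fs = 200)
#' range(a$amplitude[200:1800])   # ~1
#' range(a$frequency[200:1800])   # ~1 Hz
#' @export
analytic_signal <- function(x, fs = NULL) {
  z <- analytic_fft(x)
  amplitude <- Mod(z)
  phase <- unwrap_phase(Arg(z))
  n <- length(x)
  freq <- numeric(n)
  freq[1] <- phase[2] - phase[1]
  freq[n] <- phase[n] - phase[n - 1]
  if (n > 2) freq[2:(n - 1)] <- (phase[3:n] - phase[1:(n - 2)]) / 2
  if (!is.null(fs)) freq <- freq * fs / (2 * pi)
  structure(list(signal = x, hilbert = Im(z), amplitude = amplitude,
                 phase = phase, frequency = freq, fs = fs),
            class = "analytic_signal")
}

#' @export
print.analytic_signal <- function(x, ...) {
  unit <- if (is.null(x$fs)) "rad/sample" else "Hz"
  cat(sprintf("<analytic_signal> %d points, peak amplitude %.4g, median frequency %.4g %s\n",
              length(x$signal), max(x$amplitude),
              stats::median(x$frequency), unit))
  invisible(x)
}

#' @export
plot.analytic_signal <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$signal, type = "l", ylab = "signal", xlab = "", ...)
  graphics::lines(x$amplitude, col = 2)
  graphics::lines(-x$amplitude, col = 2)
  graphics::plot(x$frequency, type = "l",
                 ylab = if (is.null(x$fs)) "freq (rad/sample)" else "freq (Hz)",
                 xlab = "sample", ...)
  invisible(x)
}
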