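#' Band-pass filter specification
#'
#' The physiologically informative EHG band lies between 0.1 and 3 Hz;
#' everything below (baseline drift, motion) and above (maternal ECG,
#' mains and EMG interference) is noise for contraction analysis. The
#' default specification is a 6th-order Butterworth band-pass at
#' 0.1-3 Hz for 200 Hz recordings, applied forward-backward
#' (zero-phase) so burst timing and peak amplitudes are not skewed by
#' filter delay.
#'
#' @param low_cut Lower cutoff in Hz.
#' @param high_cut Upper cutoff in Hz.
#' @param order Butterworth order (of the underlying low-pass prototype).
#' @param fs Sampling rate in Hz.
#' @param zero_phase Apply forward-backward (TRUE, default) or single
#'   pass causal (FALSE). Forward-backward doubles the effective order.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 0.1, high_cut = 3, order = 6, fs = 200,
                        zero_phase = TRUE) {
  if (!is.numeric(low_cut) || !is.numeric(high_cut) ||
      low_cut <= 0 || high_cut <= low_cut) {
    stopf("need 0 < low_cut < high_cut (got %s, %s)", low_cut, high_cut)
  }
  if (high_cut >= fs / 2) {
    stopf("high_cut (%g Hz) must be below the Nyquist frequency %g Hz",
          high_cut, fs / 2)
  }
  if (order < 1 || order != round(order)) stopf("`order` must be a positive integer")
  if (fs <= 0) stopf("`fs` must be positive")
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order), fs = fs,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> Butterworth band-pass %g-%g Hz, order %d, fs %g Hz, %s\n",
              x$low_cut, x$high_cut, x$order, x$fs,
              if (x$zero_phase) "zero-phase" else "causal"))
  invisible(x)
}

#' Design a Butterworth band-pass as second-order sections
#'
#' Designs the band-pass in zero-pole form — analog Butterworth low-pass
#' prototype, low-pass-to-band-pass transform, bilinear transform with
#' frequency prewarping — and returns cascaded biquad sections. The
#' design is never expanded into a single transfer function: at cutoff /
#' sampling-rate ratios as small as 0.1 Hz / 200 Hz the expanded
#' polynomial is so ill-conditioned that its computed poles leave the
#' unit circle, whereas the biquad poles stay strictly inside it.
#'
#' @param spec A [filter_spec()].
#' @return An object of class `bandpass_sos`: a list of `b`/`a` biquad
#'   coefficient pairs, a scalar `gain` normalising the response to 1 at
#'   the geometric mid-band, and `fs`.
#' @examples
#' co <- design_bandpass(filter_spec())
#' abs(freq_response(co, sqrt(0.1 * 3)))  # ~1 at mid-band
#' @export
design_bandpass <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  fs <- spec$fs
  # prewarped analog band edges
  w1 <- 2 * fs * tan(pi * spec$low_cut / fs)
  w2 <- 2 * fs * tan(pi * spec$high_cut / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(spec$order)
  proto <- exp(1i * pi * (2 * k + spec$order - 1) / (2 * spec$order))
  # low-pass prototype pole -> conjugate band-pass pole pair
  b <- proto * bw / 2
  d <- sqrt(b^2 - w0^2)
  poles <- c(b + d, b - d)
  zp <- (2 * fs + poles) / (2 * fs - poles)          # bilinear
  zp <- zp[Im(zp) >= 0]
  zp <- zp[order(Mod(zp))]
  sos <- lapply(zp, function(p) {
    list(b = c(1, 0, -1),                            # zeros at z = +1 and -1
         a = c(1, -2 * Re(p), Mod(p)^2))
  })
  out <- structure(list(sos = sos, gain = 1, fs = fs), class = "bandpass_sos")
  fmid <- sqrt(spec$low_cut * spec$high_cut)
  out$gain <- 1 / Mod(freq_response(out, fmid))
  out
}

#' Complex frequency response of a designed band-pass
#'
#' @param coefs A `bandpass_sos` object from [design_bandpass()].
#' @param f Frequencies in Hz at which to evaluate.
#' @return Complex response values, one per frequency.
#' @export
freq_response <- function(coefs, f) {
  stopifnot(inherits(coefs, "bandpass_sos"))
  z <- exp(-2i * pi * f / coefs$fs)
  h <- rep(complex(real = coefs$gain), length(f))
  for (s in coefs$sos) {
    h <- h * (s$b[1] + s$b[2] * z + s$b[3] * z^2) /
      (s$a[1] + s$a[2] * z + s$a[3] * z^2)
  }
  h
}

# Number of samples for the slowest pole's transient to decay by ~e^-1.
settle_length <- function(coefs) {
  pm <- max(vapply(coefs$sos, function(s) {
    max(Mod(polyroot(rev(s$a))))
  }, numeric(1)))
  ceiling(1 / max(1 - pm, 1e-6))
}

# One causal pass of the full cascade.
sos_pass <- function(coefs, x) {
  for (s in coefs$sos) {
    x <- as.numeric(signal::filter(signal::Arma(s$b, s$a), x))
  }
  x * coefs$gain
}

# Extend a vector m samples to the left by repeated odd (point)
# reflection about the running first sample; rev() of the result of the
# same operation on rev(x) extends to the right.
extend_left <- function(x, m) {
  out <- x
  while (m > 0L) {
    k <- min(m, length(out) - 1L)
    block <- rev(2 * out[1] - out[2:(k + 1L)])
    out <- c(block, out)
    m <- m - k
  }
  out
}

filter_channel <- function(x, coefs, zero_phase) {
  n <- length(x)
  # odd-reflect padding damps the startup transient that would
  # otherwise corrupt burst amplitudes; the band-edge poles ring for
  # ~settle_length samples, so six settle lengths leave a residual
  # transient of order e^-6 at the window boundary
  np <- min(6L * settle_length(coefs), 100000L)
  xp <- rev(extend_left(rev(extend_left(x, np)), np))
  y <- sos_pass(coefs, xp)
  if (zero_phase) y <- rev(sos_pass(coefs, rev(y)))
  y[(np + 1):(np + n)]
}

#' Band-pass filter a recording or sample
#'
#' Filters every channel with the band-pass described by `spec`.
#' Channels are reflect-padded by three settle lengths of the slowest
#' pole before filtering; in zero-phase mode the cascade is applied
#' forward then backward, giving zero phase distortion at twice the
#' stated order.
#'
#' @param x An [ehg_recording()] or [ehg_sample()].
#' @param spec A [filter_spec()]; its `fs` must match the signal's.
#' @return An object of the same class with filtered channels.
#' @export
apply_filter <- function(x, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (!inherits(x, c("ehg_recording", "ehg_sample"))) {
    stopf("`x` must be an ehg_recording or ehg_sample")
  }
  if (!isTRUE(all.equal(x$fs, spec$fs))) {
    stopf("sampling-rate mismatch: signal fs = %g, filter fs = %g",
          x$fs, spec$fs)
  }
  if (ncol(x$data) <= 3L * spec$order) {
    stopf("channels too short (%d points) for an order-%d filter",
          ncol(x$data), spec$order)
  }
  coefs <- design_bandpass(spec)
  out <- x
  out$data <- t(apply(x$data, 1L, filter_channel,
                      coefs = coefs, zero_phase = spec$zero_phase))
  rownames(out$data) <- x$channel_labels
  out
}
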