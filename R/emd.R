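#' Sifting configuration for empirical mode decomposition
#'
#' Controls the inner sifting loop that extracts one intrinsic mode
#' function (IMF) at a time. Sifting stops when the Cauchy-type
#' criterion `sum((h_prev - h)^2) / sum(h_prev^2) < sd_threshold` is met
#' (classic threshold 0.2) or after `max_sift_iterations` passes.
#'
#' @param sd_threshold Dimensionless stopping threshold (> 0).
#' @param max_sift_iterations Cap on sifting passes per IMF.
#' @param max_imfs Maximum number of IMFs to extract (`Inf` = run until
#'   the residue is monotonic).
#' @param boundary Envelope boundary handling: `"mirror"` reflects the
#'   two edge extrema about each end point before spline fitting
#'   (default, suppresses end swings); `"clamp"` adds the end samples
#'   themselves as envelope knots.
#' @return An object of class `sift_config`.
#' @export
sift_config <- function(sd_threshold = 0.2, max_sift_iterations = 50L,
                        max_imfs = Inf, boundary = c("mirror", "clamp")) {
  boundary <- match.arg(boundary)
  if (!is.numeric(sd_threshold) || sd_threshold <= 0) {
    stopf("`sd_threshold` must be > 0")
  }
  if (max_sift_iterations < 1) stopf("`max_sift_iterations` must be >= 1")
  if (!(is.infinite(max_imfs) || (max_imfs >= 1 && max_imfs == round(max_imfs)))) {
    stopf("`max_imfs` must be a positive integer or Inf")
  }
  structure(list(sd_threshold = sd_threshold,
                 max_sift_iterations = as.integer(max_sift_iterations),
                 max_imfs = max_imfs, boundary = boundary),
            class = "sift_config")
}

# Strict local extrema with plateaus counted once at the plateau centre.
# Returns 1-based indices into x.
find_extrema <- function(x) {
  r <- rle(x)
  vals <- r$values
  lens <- r$lengths
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  m <- length(vals)
  if (m < 3L) return(list(max = integer(0), min = integer(0)))
  j <- 2:(m - 1L)
  centres <- (starts + ends) %/% 2L
  is_max <- vals[j] > vals[j - 1L] & vals[j] > vals[j + 1L]
  is_min <- vals[j] < vals[j - 1L] & vals[j] < vals[j + 1L]
  list(max = centres[j][is_max], min = centres[j][is_min])
}

#' Count extrema and zero crossings
#'
#' An intrinsic mode function must have extrema and zero-crossing counts
#' equal or differing by one. Plateaus (runs of equal values) count as a
#' single extremum at the plateau centre; a run of exact zeros counts as
#' one crossing when the signs on either side differ, so counts are
#' deterministic on quantised (e.g. 16-bit) data.
#'
#' @param x Numeric vector, length >= 3.
#' @return A list with integer counts `n_max`, `n_min`, `n_zc`.
#' @examples
#' t <- seq(0, 2 * pi, length.out = 65)[-65]
#' count_extrema(sin(t))  # 1 max, 1 min, 2 crossings
#' @export
count_extrema <- function(x) {
  check_numeric_vector(x, "x", min_len = 3L)
  e <- find_extrema(x)
  s <- sign(x)
  if (all(s == 0)) {
    n_zc <- 0L
  } else {
    # crossings = opposite-sign adjacencies among nonzero samples plus
    # one per run of exact zeros (a zero run between opposite signs is
    # not double-counted: the adjacency is computed on nonzeros only,
    # so the run itself carries the single crossing)
    nz <- s[s != 0]
    n_zero_runs <- sum(rle(s == 0)$values)
    n_flip <- if (length(nz) > 1L) sum(diff(nz) != 0) else 0L
    # flips across a zero run are already counted by the run itself
    s_runs <- rle(s)$values
    flips_thru_zero <- 0L
    if (length(s_runs) >= 3L) {
      zpos <- which(s_runs == 0)
      zpos <- zpos[zpos > 1L & zpos < length(s_runs)]
      flips_thru_zero <- sum(s_runs[zpos - 1L] != s_runs[zpos + 1L])
    }
    n_zc <- n_flip - flips_thru_zero + n_zero_runs
  }
  list(n_max = length(e$max), n_min = length(e$min), n_zc = as.integer(n_zc))
}

#' Mean of the upper and lower spline envelopes
#'
#' Fits a cubic spline through the local maxima (upper envelope) and the
#' local minima (lower envelope), after boundary extension, and returns
#' their pointwise mean. This is the quantity subtracted at each sifting
#' pass; an IMF is characterised by this mean being (locally) zero.
#'
#' @param x Numeric vector.
#' @param boundary `"mirror"` or `"clamp"`, see [sift_config()].
#' @return Numeric vector of the same length as `x`.
#' @section Monotonic residue: if fewer than two maxima or two minima
#'   exist, a condition of class `ehgelm_monotonic` is signalled; the
#'   decomposition loop uses it as its stop signal.
#' @export
envelope_mean <- function(x, boundary = c("mirror", "clamp")) {
  boundary <- match.arg(boundary)
  n <- length(x)
  e <- find_extrema(x)
  mx <- e$max
  mn <- e$min
  if (boundary == "clamp") {
    mx <- unique(c(1L, mx, n))
    mn <- unique(c(1L, mn, n))
  }
  # canonical stop rule: sifting needs at least one maximum, one
  # minimum and three extrema overall; mirror extension supplies the
  # remaining spline knots when only one extremum of a kind exists
  if (length(mx) < 1L || length(mn) < 1L || length(mx) + length(mn) < 3L) {
    stop(structure(class = c("ehgelm_monotonic", "error", "condition"),
                   list(message = "monotonic residue: too few extrema for envelopes",
                        call = sys.call(-1))))
  }
  upper <- env_spline(mx, x, n, boundary)
  lower <- env_spline(mn, x, n, boundary)
  (upper + lower) / 2
}

# Spline through extrema `idx`, extended by mirroring the two edge
# extrema about the end points (mirror mode only).
env_spline <- function(idx, x, n, boundary) {
  ti <- as.numeric(idx)
  vi <- x[idx]
  if (boundary == "mirror") {
    k <- length(idx)
    m2 <- min(2L, k)
    lead_t <- 2 - rev(ti[seq_len(m2)])          # reflect about t = 1
    lead_v <- rev(vi[seq_len(m2)])
    tail_t <- 2 * n - rev(ti[(k - m2 + 1L):k])  # reflect about t = n
    tail_v <- rev(vi[(k - m2 + 1L):k])
    tt <- c(lead_t, ti, tail_t)
    vv <- c(lead_v, vi, tail_v)
    ord <- order(tt)
    tt <- tt[ord]; vv <- vv[ord]
    keep <- !duplicated(tt)
    tt <- tt[keep]; vv <- vv[keep]
  } else {
    tt <- ti; vv <- vi
  }
  stats::splinefun(tt, vv, method = "fmm")(seq_len(n))
}

#' Is a vector an intrinsic mode function?
#'
#' Checks the two defining IMF conditions: (1) the number of extrema and
#' the number of zero crossings are equal or differ by one; (2) the mean
#' of the upper and lower envelopes is (near) zero — here
#' `mean(abs(envelope_mean(x)))` below `tol` times the signal RMS.
#'
#' @param x Numeric vector, length >= 3.
#' @param tol Envelope-mean tolerance relative to signal RMS.
#' @param boundary Envelope boundary mode, see [sift_config()].
#' @return `TRUE` or `FALSE`.
#' @export
is_imf <- function(x, tol = 0.05, boundary = "mirror") {
  check_numeric_vector(x, "x", min_len = 3L)
  cnt <- count_extrema(x)
  n_ext <- cnt$n_max + cnt$n_min
  if (abs(n_ext - cnt$n_zc) > 1L) return(FALSE)
  m <- tryCatch(envelope_mean(x, boundary),
                ehgelm_monotonic = function(e) NULL)
  if (is.null(m)) return(FALSE)
  rms <- sqrt(mean(x^2))
  if (rms == 0) return(TRUE)
  mean(abs(m)) < tol * rms
}

#' Extract one intrinsic mode function by sifting
#'
#' Repeatedly subtracts the envelope mean, `h <- h - envelope_mean(h)`,
#' until the Cauchy stopping criterion of [sift_config()] is met or the
#' iteration cap is reached (a message is emitted in the latter case).
#'
#' @param x Numeric vector (not monotonic).
#' @param cfg A [sift_config()].
#' @return Numeric vector: the candidate IMF.
#' @export
sift <- function(x, cfg = sift_config()) {
  stopifnot(inherits(cfg, "sift_config"))
  h <- x
  converged <- FALSE
  for (i in seq_len(cfg$max_sift_iterations)) {
    m <- if (i == 1L) {
      envelope_mean(h, cfg$boundary)    # propagate monotonic-input signal
    } else {
      # extrema exhausted mid-sift: the current proto-mode is the IMF
      tryCatch(envelope_mean(h, cfg$boundary),
               ehgelm_monotonic = function(e) NULL)
    }
    if (is.null(m)) { converged <- TRUE; break }
    h_new <- h - m
    denom <- sum(h^2)
    sd_val <- if (denom > 0) sum((h - h_new)^2) / denom else 0
    h <- h_new
    if (sd_val < cfg$sd_threshold) {
      # SD alone does not guarantee the defining alternation property;
      # keep sifting until extrema and zero crossings balance too
      cnt <- count_extrema(h)
      if (abs(cnt$n_max + cnt$n_min - cnt$n_zc) <= 1L) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    message(sprintf("sift: iteration cap (%d) reached before SD threshold",
                    cfg$max_sift_iterations))
  }
  h
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions `c_1, ..., c_n`
#' plus a residue `r_n`, such that `x = sum(c_i) + r_n` exactly (to
#' numerical precision, by construction). IMFs are ordered fastest to
#' slowest: IMF1 carries the highest-frequency oscillation. Extraction
#' stops when the residue is monotonic (or has fewer than three
#' extrema), or when `cfg$max_imfs` modes have been removed.
#'
#' @param x Numeric vector, length >= 16.
#' @param cfg A [sift_config()].
#' @return An object of class `imf_set`: list with `imfs` (list of
#'   numeric vectors), `residue`, `n` (number of IMFs) and `input`
#'   (the original signal).
#' @examples
#' t <- (0:2047) / 200
#' d <- emd(sin(2 * pi * 1 * t) + sin(2 * pi * 8 * t))
#' d
#' @export
emd <- function(x, cfg = sift_config()) {
  check_numeric_vector(x, "x", min_len = 16L)
  stopifnot(inherits(cfg, "sift_config"))
  imfs <- list()
  r <- x
  while (length(imfs) < cfg$max_imfs) {
    e <- find_extrema(r)
    if (length(e$max) < 1L || length(e$min) < 1L ||
        length(e$max) + length(e$min) < 3L) break
    ci <- tryCatch(sift(r, cfg), ehgelm_monotonic = function(e) NULL)
    if (is.null(ci)) break
    imfs[[length(imfs) + 1L]] <- ci
    r <- r - ci
  }
  structure(list(imfs = imfs, residue = r, n = length(imfs), input = x),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) + residue, %d points\n",
              x$n, length(x$residue)))
  invisible(x)
}

#' @export
plot.imf_set <- function(x, ...) {
  k <- x$n + 2L
  op <- graphics::par(mfrow = c(k, 1), mar = c(1.5, 4, 0.5, 0.5))
  on.exit(graphics::par(op))
  graphics::plot(x$input, type = "l", ylab = "signal", xlab = "", ...)
  for (i in seq_len(x$n)) {
    graphics::plot(x$imfs[[i]], type = "l",
                   ylab = sprintf("IMF%d", i), xlab = "", ...)
  }
  graphics::plot(x$residue, type = "l", ylab = "residue", xlab = "", ...)
  invisible(x)
}
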