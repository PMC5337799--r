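# Shared fixtures: deterministic test signals and a small synthetic
# corpus configuration that keeps unit tests fast (full-size windows are
# exercised in the acceptance tests).

tone <- function(f, fs = 200, n = 4096, phase = 0) {
  cos(2 * pi * f * (seq_len(n) - 1) / fs + phase)
}

sine <- function(f, fs = 200, n = 4096) {
  sin(2 * pi * f * (seq_len(n) - 1) / fs)
}

# linear chirp f0 -> f1 over the window; instantaneous frequency
# f(t) = f0 + (f1 - f0) * t / T
chirp <- function(f0, f1, fs = 200, n = 4096) {
  t <- (seq_len(n) - 1) / fs
  T <- t[n]
  cos(2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * T)))
}

# amplitude-modulated tone with known envelope 1 + m*cos(2*pi*fm*t)
am_signal <- function(fc = 1, fm = 0.1, m = 0.5, fs = 200, n = 4096) {
  t <- (seq_len(n) - 1) / fs
  env <- 1 + m * cos(2 * pi * fm * t)
  list(x = env * cos(2 * pi * fc * t), envelope = env)
}

interior <- function(n, frac = 0.1) {
  k <- floor(frac * n)
  (k + 1):(n - k)
}

# small corpus config: 4 channels x 1024 points, keeps EMD cheap
small_synth <- function(n_per_class = 4L, seed = 11L, ...) {
  synth_config(n_per_class = n_per_class, window_length = 1024L,
               channels = 4L, seed = seed, ...)
}

# corpus of three-mode channels (0.3, 1, 2.8 Hz) with class-dependent
# amplitude, so every channel decomposes at least three levels deep
# even at short windows
make_deep_corpus <- function(n_per_class = 6L, seed = 71L, n = 2048L) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / 200
  lapply(rep(c(1L, 2L), n_per_class), function(lab) {
    amp <- if (lab == 1L) 0.05 else 0.15
    chans <- t(vapply(1:4, function(ch) {
      a <- amp * runif(1, 0.8, 1.2)
      a * (cos(2 * pi * 2.8 * t + runif(1, 0, 2 * pi)) +
             cos(2 * pi * 1.0 * t + runif(1, 0, 2 * pi)) +
             cos(2 * pi * 0.3 * t + runif(1, 0, 2 * pi))) +
        0.002 * rnorm(n)
    }, numeric(n)))
    ehg_sample(chans, label = lab, fs = 200)
  })
}

# brute-force extrema / zero-crossing oracle: plain triple scan,
# independent of the package's rle-based implementation
scan_extrema <- function(x) {
  n_max <- 0L; n_min <- 0L
  for (i in 2:(length(x) - 1L)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) n_max <- n_max + 1L
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) n_min <- n_min + 1L
  }
  s <- sign(x); s <- s[s != 0]
  list(n_max = n_max, n_min = n_min, n_zc = sum(diff(s) != 0))
}

# pairwise Mann-Whitney AUC oracle (ties count 1/2)
mw_auc <- function(truth, scores) {
  pos <- scores[truth == 2]; neg <- scores[truth == 1]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
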