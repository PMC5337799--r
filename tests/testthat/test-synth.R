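test_that("generation is deterministic given the RNG state", {
  cfg <- small_synth()
  set.seed(30); s1 <- generate_sample(2, cfg)
  set.seed(30); s2 <- generate_sample(2, cfg)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$label, 2L)
  expect_error(generate_sample(4, cfg), "label")

  ds1 <- generate_dataset(small_synth(seed = 77))
  ds2 <- generate_dataset(small_synth(seed = 77))
  expect_identical(ds1$samples[[3]]$data, ds2$samples[[3]]$data)
  expect_identical(ds1$manifest, ds2$manifest)
})

test_that("a dataset is balanced with a regenerable manifest", {
  cfg <- small_synth(n_per_class = 2L, seed = 55)
  ds <- generate_dataset(cfg)
  expect_length(ds$samples, 4L)
  expect_identical(sum(ds$manifest$label == 1), 2L)
  expect_identical(sum(ds$manifest$label == 2), 2L)
  # per-sample seed in the manifest regenerates the sample
  i <- 2L
  set.seed(ds$manifest$seed[i])
  regen <- generate_sample(ds$manifest$label[i], cfg)
  expect_identical(regen$data, ds$samples[[i]]$data)
})

test_that("dominant post-filter frequency lies in the class band", {
  # noise components silenced: the periodogram argmax then isolates the
  # burst oscillation itself (with noise on, a weak-amplitude draw can
  # be out-peaked by the deliberate background waves)
  cfg <- synth_config(n_per_class = 1L, channels = 4L,
                      noise = list(white_sd = 1e-5, slow_amp = 0,
                                   mid_amp = 0, drift_amp = 0,
                                   drift_freq = 0.02, hf_amp = 0,
                                   hf_freq = 50))
  set.seed(60)
  s <- generate_sample(2, cfg)
  sf <- apply_filter(s, filter_spec())
  for (ch in 1:4) {
    x <- sf$data[ch, ]
    sp <- stats::spec.pgram(stats::ts(x, frequency = 200), plot = FALSE,
                            taper = 0)
    fpeak <- sp$freq[which.max(sp$spec)]
    expect_gte(fpeak, cfg$labour$f_low - 0.1)
    expect_lte(fpeak, cfg$labour$f_high + 0.1)
  }
})

test_that("the band-pass removes drift and interference from raw samples", {
  # long window (164 s) + Hann taper: at the default 20 s window the
  # 0.05 Hz spectral resolution smears genuine passband noise across
  # the 0.1 Hz cutoff, which would measure the window, not the filter
  cfg <- synth_config(n_per_class = 1L, channels = 2L,
                      window_length = 32768L)
  set.seed(61)
  s <- generate_sample(1, cfg)
  sf <- apply_filter(s, filter_spec())
  n <- cfg$window_length
  hann <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  f <- (0:(n - 1)) * 200 / n
  fa <- pmin(f, 200 - f)
  out_frac <- function(x) {
    pw <- Mod(stats::fft(x * hann))^2
    sum(pw[fa < 0.1 | fa > 3]) / sum(pw)
  }
  for (ch in 1:2) {
    expect_gt(out_frac(s$data[ch, ]), 0.5)    # raw: noise dominates
    expect_lt(out_frac(sf$data[ch, ]), 0.01)  # filtered: essentially gone
  }
})

test_that("labour samples carry larger IMF1 features than pregnancy", {
  cfg <- synth_config(n_per_class = 5L, channels = 4L,
                      window_length = 2048L, seed = 62)
  ds <- generate_dataset(cfg)
  filtered <- lapply(ds$samples, apply_filter, spec = filter_spec())
  tab <- feature_table(filtered)
  fmean <- rowMeans(tab[, 1:4])
  expect_gt(mean(fmean[tab$label == 2]), mean(fmean[tab$label == 1]))
})

test_that("config invariants are enforced", {
  expect_error(synth_config(pregnancy = list(amp_mean = 0.05, amp_sd = 0.01,
                                             f_low = 0.05, f_high = 0.8,
                                             burst_fraction = 0.6)),
               "0.1")
  expect_error(synth_config(labour = list(amp_mean = 0.1, amp_sd = 0.01,
                                          f_low = 0.5, f_high = 1.2,
                                          burst_fraction = 1.5)),
               "burst_fraction")
  expect_error(synth_config(n_per_class = 0), "n_per_class")
})
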