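test_that("extrema and zero-crossing counts match a brute-force scan", {
  t <- seq(0, 2 * pi, length.out = 65)[-65]
  cnt <- count_extrema(sin(t))
  expect_identical(cnt, list(n_max = 1L, n_min = 1L, n_zc = 2L))

  # strictly monotonic ramp: no extrema, at most one crossing (the
  # ramp below starts at an exact zero, which counts as one)
  ramp <- count_extrema(seq(0, 1, length.out = 32))
  expect_identical(ramp$n_max, 0L)
  expect_identical(ramp$n_min, 0L)
  expect_lte(ramp$n_zc, 1L)
  expect_identical(count_extrema(seq(1, 2, length.out = 32))$n_zc, 0L)
  expect_identical(count_extrema(rep(2, 10)),
                   list(n_max = 0L, n_min = 0L, n_zc = 0L))

  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(100)
    expect_identical(unlist(count_extrema(x)), unlist(scan_extrema(x)))
  }
  # plateau counted once; a run of zeros is one crossing
  x <- c(-1, 0, 0, 0, 1, 2, 2, 2, 1, -1)
  cnt <- count_extrema(x)
  expect_identical(cnt$n_max, 1L)
  expect_identical(cnt$n_zc, 2L)
  expect_error(count_extrema(c(1, 2)), "length")
})

test_that("is_imf accepts monocomponents and rejects offsets/mixtures", {
  expect_true(is_imf(sine(1, n = 2048)))
  expect_false(is_imf(sine(1, n = 2048) + 5))
  # two-tone mixture: the slow component is the envelope mean, which is
  # far from zero relative to RMS, so the mixture is not a single mode
  mix <- sine(1, n = 2048) + sine(8, n = 2048)
  expect_false(is_imf(mix))
})

test_that("envelope mean tracks symmetry, offsets and AM envelopes", {
  n <- 4096
  x <- sine(1, n = n)
  int <- interior(n)
  expect_lt(max(abs(envelope_mean(x)[int])), 0.05)
  # shift equivariance
  expect_lt(max(abs(envelope_mean(x + 3)[int] - 3)), 0.05)
  # AM signal with symmetric modulation: envelope mean stays near zero
  # while the envelope swing itself is large (closed-form oracle: the
  # upper envelope is 1 + 0.5*cos(2*pi*0.1*t), the lower its negative)
  am <- am_signal(fc = 1, fm = 0.1, m = 0.5, n = n)
  expect_lt(max(abs(envelope_mean(am$x)[int])), 0.05 * max(am$envelope))
  a <- analytic_signal(am$x)$amplitude
  expect_lt(max(abs(a[int] - am$envelope[int]) / am$envelope[int]), 0.05)
  expect_error(envelope_mean(seq_len(32)), class = "ehgelm_monotonic")
})

test_that("sifting fixes pure tones and separates a two-tone mixture", {
  x <- sine(1, n = 4096)
  h <- sift(x)
  expect_gt(stats::cor(h, x), 0.999)

  two <- sine(1, n = 4096) + sine(8, n = 4096)
  imf1 <- sift(two)
  int <- interior(4096)
  expect_gt(stats::cor(imf1[int], sine(8, n = 4096)[int]), 0.95)
})

test_that("emd reconstructs exactly and orders modes fast to slow", {
  x <- sine(1, n = 4096) + sine(8, n = 4096)
  d <- emd(x)
  expect_gte(d$n, 2L)
  int <- interior(4096)
  expect_gt(stats::cor(d$imfs[[1]][int], sine(8, n = 4096)[int]), 0.95)
  expect_gt(stats::cor(d$imfs[[2]][int], sine(1, n = 4096)[int]), 0.95)
  rec <- Reduce(`+`, d$imfs) + d$residue
  expect_lt(sqrt(sum((rec - x)^2) / sum(x^2)), 1e-8)

  # monotonic input: no IMFs, residue is the input
  ramp <- emd(as.numeric(1:64))
  expect_identical(ramp$n, 0L)
  expect_equal(ramp$residue, as.numeric(1:64))
})

test_that("every emitted IMF satisfies the extrema/zero-crossing condition", {
  set.seed(33)
  t <- (0:2047) / 200
  corpus <- list(
    rnorm(2048),
    sine(0.5, n = 2048) + 0.3 * sine(3, n = 2048) + 0.1 * rnorm(2048),
    chirp(0.5, 2, n = 2048),
    cumsum(rnorm(2048)) / 10 + sine(1, n = 2048)
  )
  for (x in corpus) {
    d <- emd(x)
    rec <- Reduce(`+`, c(d$imfs, list(d$residue)))
    expect_lt(sqrt(sum((rec - x)^2) / sum(x^2)), 1e-8)
    for (ci in d$imfs) {
      cnt <- count_extrema(ci)
      expect_lte(abs(cnt$n_max + cnt$n_min - cnt$n_zc), 1L)
    }
  }
})

test_that("decomposition is homogeneous under positive scaling", {
  set.seed(41)
  x <- sine(0.7, n = 1024) + 0.2 * rnorm(1024)
  d1 <- emd(x)
  d2 <- emd(5 * x)
  expect_identical(d1$n, d2$n)
  for (i in seq_len(d1$n)) {
    expect_lt(max(abs(d2$imfs[[i]] - 5 * d1$imfs[[i]])) /
                max(abs(d1$imfs[[i]])), 1e-6)
  }
})

test_that("max_imfs truncates the decomposition", {
  x <- sine(1, n = 2048) + sine(8, n = 2048) + 0.05 * rnorm(2048)
  d <- emd(x, sift_config(max_imfs = 1))
  expect_identical(d$n, 1L)
})
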