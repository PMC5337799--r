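#' Maximum instantaneous amplitude of one IMF
#'
#' The scalar feature used per channel: the maximum over time of the
#' analytic-signal amplitude `a(t)` of the mode. Labour contractions
#' produce markedly larger burst amplitudes than pregnancy
#' contractions, so this single number is discriminative.
#'
#' @param imf Numeric vector, length >= 4.
#' @param trim Fraction of samples to exclude at each end before taking
#'   the maximum (default 0: plain maximum over the full window). A
#'   small trim (e.g. 0.05) guards against FFT edge swings dominating.
#' @return Non-negative scalar. A constant (zero-bandwidth) input is
#'   degenerate for the analytic construction and returns 0 with a
#'   warning.
#' @export
max_analytic_amplitude <- function(imf, trim = 0) {
  check_numeric_vector(imf, "imf", min_len = 4L)
  if (stats::sd(imf) == 0) {
    if (any(imf != 0)) {
      warning("constant input: amplitude feature is degenerate, returning 0")
    }
    return(0)
  }
  a <- analytic_signal(imf)$amplitude
  n <- length(a)
  k <- floor(trim * n)
  if (k > 0) a <- a[(k + 1):(n - k)]
  max(a)
}

#' Per-channel maximum-amplitude feature vector of an EHG sample
#'
#' For each channel: decompose with EMD, take the `imf_index`-th mode
#' (IMF1 = fastest), and record its maximum analytic amplitude. The
#' result is one feature per channel (16 for a standard 4-by-4
#' electrode grid), in channel order. The sample is assumed already
#' band-pass filtered (see [apply_filter()]).
#'
#' @param sample An [ehg_sample()] (or [ehg_recording()]; then the
#'   returned label is `NA`).
#' @param imf_index Which IMF supplies the feature (1, 2 or 3 in normal
#'   use).
#' @param sift_cfg A [sift_config()]. Decomposition stops after
#'   `imf_index` modes, so feature extraction does not pay for a full
#'   decomposition.
#' @param trim Edge-trim fraction passed to [max_analytic_amplitude()].
#' @return Named numeric vector of length `n_channels` with attributes
#'   `label` and `imf_index`.
#' @export
extract_features <- function(sample, imf_index = 1L,
                             sift_cfg = sift_config(), trim = 0) {
  if (!inherits(sample, c("ehg_sample", "ehg_recording"))) {
    stopf("`sample` must be an ehg_sample or ehg_recording")
  }
  imf_index <- as.integer(imf_index)
  if (imf_index < 1L) stopf("`imf_index` must be >= 1")
  cfg <- sift_cfg
  cfg$max_imfs <- min(cfg$max_imfs, imf_index)
  vals <- vapply(seq_len(nrow(sample$data)), function(ch) {
    d <- emd(sample$data[ch, ], cfg)
    if (d$n < imf_index) {
      stopf("channel %s decomposed into %d IMF(s); IMF%d requested",
            sample$channel_labels[ch], d$n, imf_index)
    }
    max_analytic_amplitude(d$imfs[[imf_index]], trim = trim)
  }, numeric(1))
  names(vals) <- sample$channel_labels
  structure(vals, label = if (inherits(sample, "ehg_sample")) sample$label else NA_integer_,
            imf_index = imf_index)
}

#' Feature table for a set of samples
#'
#' Runs [extract_features()] on every sample and assembles the standard
#' modelling table: one row per sample, one column per channel feature,
#' plus `label` and `imf_index` columns. With `imf_index` a vector, all
#' requested modes are extracted from a single decomposition per
#' channel and a list of tables (one per index) is returned.
#'
#' @param samples List of [ehg_sample()] objects.
#' @param imf_index Integer (or integer vector) of IMF indices.
#' @param sift_cfg A [sift_config()].
#' @param trim Edge-trim fraction.
#' @return A `data.frame` (or named list of data.frames when
#'   `length(imf_index) > 1`).
#' @export
feature_table <- function(samples, imf_index = 1L,
                          sift_cfg = sift_config(), trim = 0) {
  stopifnot(length(samples) >= 1L)
  idx <- sort(unique(as.integer(imf_index)))
  kmax <- max(idx)
  cfg <- sift_cfg
  cfg$max_imfs <- min(cfg$max_imfs, kmax)
  per_sample <- lapply(samples, function(s) {
    mat <- vapply(seq_len(nrow(s$data)), function(ch) {
      d <- emd(s$data[ch, ], cfg)
      if (d$n < kmax) {
        stopf("channel %s decomposed into %d IMF(s); IMF%d requested",
              s$channel_labels[ch], d$n, kmax)
      }
      vapply(idx, function(k) max_analytic_amplitude(d$imfs[[k]], trim = trim),
             numeric(1))
    }, numeric(length(idx)))
    # vapply returns idx x channels; keep as matrix
    matrix(mat, nrow = length(idx))
  })
  labels <- vapply(samples, function(s) {
    if (inherits(s, "ehg_sample")) s$label else NA_integer_
  }, integer(1))
  ch_names <- samples[[1]]$channel_labels
  tabs <- lapply(seq_along(idx), function(i) {
    m <- t(vapply(per_sample, function(p) p[i, ], numeric(length(ch_names))))
    df <- as.data.frame(m)
    names(df) <- ch_names
    df$label <- labels
    df$imf_index <- idx[i]
    df
  })
  names(tabs) <- paste0("IMF", idx)
  if (length(tabs) == 1L) tabs[[1]] else tabs
}

#' Write a feature table as TSV
#'
#' @param features A data.frame from [feature_table()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
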