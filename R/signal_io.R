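#' Multichannel EHG recording
#'
#' Container for a multichannel electrohysterogram (uterine EMG) signal:
#' a channels-by-timepoints numeric matrix plus sampling rate and channel
#' labels. Surface EHG grids (e.g. a 4-by-4 abdominal electrode matrix)
#' are stored one channel per row.
#'
#' @param data Numeric matrix, channels in rows, timepoints in columns.
#'   A plain numeric vector is treated as a single channel.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Optional character vector of channel names;
#'   defaults to `"ch1"`, `"ch2"`, ...
#' @return An object of class `ehg_recording` with elements `data`, `fs`
#'   and `channel_labels`.
#' @examples
#' rec <- ehg_recording(matrix(rnorm(32), nrow = 2), fs = 200)
#' rec
#' @export
ehg_recording <- function(data, fs, channel_labels = NULL) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data)) {
    stopf("`data` must be a numeric matrix (channels x timepoints)")
  }
  if (ncol(data) < 1L) stopf("recording must contain at least one timepoint")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stopf("`fs` must be a single positive number (Hz)")
  }
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data)) {
    stopf("`channel_labels` length (%d) != number of channels (%d)",
          length(channel_labels), nrow(data))
  }
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels)),
            class = "ehg_recording")
}

#' @export
print.ehg_recording <- function(x, ...) {
  cat(sprintf("<ehg_recording> %d channel(s) x %d points @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Segmented EHG sample
#'
#' One windowed EHG segment (typically a contraction burst) with a class
#' label: 1 = pregnancy, 2 = labour.
#'
#' @param data Numeric matrix, channels x window points.
#' @param label Class label, 1 (pregnancy) or 2 (labour).
#' @param fs Sampling rate in Hz.
#' @return An object of class `ehg_sample`.
#' @export
ehg_sample <- function(data, label, fs) {
  rec <- ehg_recording(data, fs)
  label <- check_label(label)
  structure(list(data = rec$data, label = label, fs = fs,
                 channel_labels = rec$channel_labels),
            class = "ehg_sample")
}

check_label <- function(label) {
  if (length(label) != 1L || !label %in% c(1, 2)) {
    stopf("`label` must be 1 (pregnancy) or 2 (labour)")
  }
  as.integer(label)
}

#' @export
print.ehg_sample <- function(x, ...) {
  cat(sprintf("<ehg_sample> %d channel(s) x %d points @ %g Hz, label = %d (%s)\n",
              nrow(x$data), ncol(x$data), x$fs, x$label,
              c("pregnancy", "labour")[x$label]))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a multichannel recording from delimited text
#'
#' Reads a channels-in-rows (default) or channels-in-columns delimited
#' numeric file. A JSON sidecar `<path>.json` with fields `fs` and
#' `channel_labels`, as written by [write_recording()], is used when
#' present; an explicit `fs` argument overrides it.
#'
#' @param path Path to the delimited text file.
#' @param fs Sampling rate in Hz; required if no sidecar is present.
#' @param delimiter Field delimiter (default tab).
#' @param orientation `"channels_rows"` (default) or `"channels_cols"`.
#' @return An [ehg_recording()].
#' @export
read_recording <- function(path, fs = NULL, delimiter = "\t",
                           orientation = c("channels_rows", "channels_cols")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("empty input file: %s", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stopf("ragged input in %s: row %d has %d fields, expected %d",
          path, bad, widths[bad], widths[1])
  }
  vals <- suppressWarnings(lapply(fields, as.numeric))
  nas <- vapply(vals, anyNA, logical(1))
  if (any(nas)) {
    stopf("non-numeric value in %s at row %d", path, which(nas)[1])
  }
  m <- do.call(rbind, vals)
  if (orientation == "channels_cols") m <- t(m)
  labels <- NULL
  side <- sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(fs) && !is.null(meta$fs)) fs <- meta$fs
    if (!is.null(meta$channel_labels) &&
        length(meta$channel_labels) == nrow(m)) {
      labels <- meta$channel_labels
    }
  }
  if (is.null(fs)) stopf("`fs` not given and no sidecar found for %s", path)
  ehg_recording(m, fs = fs, channel_labels = labels)
}

#' Write a multichannel recording to delimited text
#'
#' Writes channels as rows with full double precision (15 significant
#' digits) plus a JSON sidecar `<path>.json` holding `fs` and
#' `channel_labels`, so that [read_recording()] inverts it to within
#' 1e-12 per element.
#'
#' @param rec An [ehg_recording()].
#' @param path Destination file path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, delimiter = "\t") {
  stopifnot(inherits(rec, "ehg_recording"))
  rows <- apply(rec$data, 1L, function(v) {
    paste(formatC(v, digits = 15, format = "g"), collapse = delimiter)
  })
  ok <- tryCatch({ writeLines(rows, path); TRUE },
                 error = function(e) stopf("cannot write %s: %s", path,
                                           conditionMessage(e)))
  jsonlite::write_json(list(fs = rec$fs, channel_labels = rec$channel_labels),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Cut fixed-length labelled windows out of a recording
#'
#' Slices `window_length`-point windows starting at the given onsets
#' (1-based sample indices; the window covers
#' `onset, ..., onset + window_length - 1`). Values are copied verbatim:
#' no filtering or scaling is applied. Overlapping windows are permitted
#' but reported via a message, since contraction-burst corpora are
#' normally non-overlapping.
#'
#' @param rec An [ehg_recording()].
#' @param onsets Integer vector of 1-based window start indices.
#' @param window_length Window length in samples (default 4096).
#' @param label Class label for every produced sample (1 or 2).
#' @return A list of [ehg_sample()] objects, one per onset.
#' @export
segment_recording <- function(rec, onsets, window_length = 4096L, label) {
  stopifnot(inherits(rec, "ehg_recording"))
  label <- check_label(label)
  window_length <- as.integer(window_length)
  if (window_length < 1L) stopf("`window_length` must be >= 1")
  onsets <- as.integer(onsets)
  n <- ncol(rec$data)
  bad <- onsets < 1L | onsets + window_length - 1L > n
  if (any(bad)) {
    stopf("onset %d out of range: window [%d, %d] exceeds recording length %d",
          onsets[bad][1], onsets[bad][1],
          onsets[bad][1] + window_length - 1L, n)
  }
  if (length(onsets) > 1L) {
    o <- sort(onsets)
    if (any(diff(o) < window_length)) {
      message("segment_recording: requested windows overlap")
    }
  }
  lapply(onsets, function(s) {
    ehg_sample(rec$data[, s:(s + window_length - 1L), drop = FALSE],
               label = label, fs = rec$fs)
  })
}

#' Write / read one labelled EHG sample
#'
#' Samples are stored as the recording format plus `label` in the JSON
#' sidecar.
#'
#' @param sample An [ehg_sample()].
#' @param path Destination path.
#' @param delimiter Field delimiter.
#' @return `path` (write) or an [ehg_sample()] (read).
#' @export
write_sample <- function(sample, path, delimiter = "\t") {
  stopifnot(inherits(sample, "ehg_sample"))
  rec <- ehg_recording(sample$data, sample$fs, sample$channel_labels)
  write_recording(rec, path, delimiter)
  jsonlite::write_json(list(fs = sample$fs,
                            channel_labels = sample$channel_labels,
                            label = sample$label),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sample
#' @export
read_sample <- function(path, delimiter = "\t") {
  rec <- read_recording(path, delimiter = delimiter)
  side <- sidecar_path(path)
  if (!file.exists(side)) stopf("sample sidecar missing: %s", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$label)) stopf("sidecar %s has no `label` field", side)
  ehg_sample(rec$data, label = meta$label, fs = rec$fs)
}
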