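#' Uniformly sampled multichannel recording
#'
#' The basic container for both local field potential (LFP) and ground
#' reaction force data: a channels-by-samples numeric matrix together with
#' its sampling rate, ordered channel labels and a start time.
#'
#' @param data numeric matrix, channels x samples (a vector is treated as a
#'   single channel).
#' @param fs sampling rate in Hz, positive scalar.
#' @param channel_labels character vector, one label per channel. Defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param t0 start time of the first sample in seconds.
#' @return An object of class `"recording"`.
#' @examples
#' rec <- recording(rbind(sin(1:100), cos(1:100)), fs = 100,
#'                  channel_labels = c("STN_L", "STN_R"))
#' n_samples(rec)
#' @export
recording <- function(data, fs, channel_labels = NULL, t0 = 0) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar (Hz)")
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels length must match the number of channels")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("recording data contains NaN/Inf values")
  }
  structure(
    list(data = data, fs = as.numeric(fs),
         channel_labels = as.character(channel_labels), t0 = as.numeric(t0)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$t0))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples per channel
#' @param rec a [recording()].
#' @return integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Sample times of a recording
#' @param rec a [recording()].
#' @return numeric vector of times in seconds (`t0 + (0:(n-1))/fs`).
#' @export
rec_times <- function(rec) rec$t0 + (seq_len(n_samples(rec)) - 1) / rec$fs

#' Extract a time interval from a recording
#' @param rec a [recording()].
#' @param from,to interval bounds in seconds (inclusive, on the sample grid).
#' @return a [recording()] restricted to `[from, to]`.
#' @export
crop_recording <- function(rec, from, to) {
  tt <- rec_times(rec)
  keep <- tt >= from - 1e-9 & tt <= to + 1e-9
  if (!any(keep)) stop("crop interval outside recording")
  recording(rec$data[, keep, drop = FALSE], rec$fs, rec$channel_labels,
            t0 = tt[which(keep)[1]])
}

#' Read a recording from a delimited text file
#'
#' Expects a CSV with a header `time,<ch1>,<ch2>,...`, time in seconds,
#' uniformly sampled. The sampling rate is inferred from the time column and
#' validated against `expected_fs` within 0.1%.
#'
#' @param path CSV file path.
#' @param expected_fs expected sampling rate in Hz, or `NULL` to skip the
#'   check.
#' @param expected_channels expected channel count, or `NULL`.
#' @return a [recording()].
#' @export
read_recording <- function(path, expected_fs = NULL, expected_channels = NULL) {
  if (!file.exists(path)) stop(sprintf("recording file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) {
    stop(sprintf("load error in %s: missing 'time' column", path))
  }
  ch_names <- setdiff(names(df), "time")
  if (length(ch_names) < 1L) {
    stop(sprintf("load error in %s: no channel columns", path))
  }
  if (!is.null(expected_channels) && length(ch_names) != expected_channels) {
    stop(sprintf("load error in %s: expected %d channels, found %d",
                 path, expected_channels, length(ch_names)))
  }
  na_rows <- which(rowSums(is.na(df)) > 0)
  if (length(na_rows) > 0) {
    stop(sprintf("load error in %s: NaN cell at row %d", path, na_rows[1]))
  }
  tt <- df$time
  if (length(tt) < 2L) stop(sprintf("load error in %s: fewer than 2 samples", path))
  dt <- diff(tt)
  dt_med <- stats::median(dt)
  if (dt_med <= 0) stop(sprintf("load error in %s: non-increasing time", path))
  bad <- which(abs(dt - dt_med) > 1e-3 * dt_med)
  if (length(bad) > 0) {
    stop(sprintf("load error in %s: non-uniform sampling at row %d", path, bad[1] + 1L))
  }
  fs <- 1 / dt_med
  ## snap to a round rate when within tolerance (counters accumulated
  ## rounding in the written time column)
  if (abs(fs - round(fs)) / fs < 1e-3) fs <- round(fs)
  if (!is.null(expected_fs) && abs(fs - expected_fs) > 1e-3 * expected_fs) {
    stop(sprintf("load error in %s: inferred fs %.4f Hz differs from expected %g Hz",
                 path, fs, expected_fs))
  }
  recording(t(as.matrix(df[, ch_names, drop = FALSE])), fs = fs,
            channel_labels = ch_names, t0 = tt[1])
}

#' Write a recording to CSV
#'
#' Inverse of [read_recording()]; round-trips data to better than 1e-9
#' relative precision.
#'
#' @param rec a [recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  tt <- rec_times(rec)
  df <- data.frame(time = format(tt, digits = 15, scientific = FALSE, trim = TRUE))
  for (i in seq_along(rec$channel_labels)) {
    df[[rec$channel_labels[i]]] <-
      format(rec$data[i, ], digits = 15, scientific = TRUE, trim = TRUE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
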