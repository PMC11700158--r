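## Gait quantification from dual force plates:
##   rescale by body weight -> merge the two plates (max, with the right
##   plate mirrored about half weight) -> total variation over 2 s windows
##   at 0.1 s stride -> per-participant normalization across visits.

#' Rescale force-plate channels to body-weight fraction
#'
#' Divides every sample by the participant's weight so that balanced quiet
#' stance reads ~0.5 on each plate, making the measure robust to weight
#' changes between visits.
#'
#' @param force a 2-channel force [recording()].
#' @param weight positive scalar in the same units as `force`.
#' @return a [recording()] in body-weight fraction units.
#' @export
rescale_by_weight <- function(force, weight) {
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0) {
    stop("weight must be a positive scalar")
  }
  out <- force
  out$data <- force$data / weight
  out
}

#' Merge the two plates into a single trace, mirroring the right plate
#'
#' Per sample, takes the higher of the two body-weight-fraction plate
#' values; when the right plate wins, its value is mirrored about 0.5 (half
#' the participant's weight). Full loading of the left plate maps to 1, full
#' loading of the right plate to 0, balanced stance to 0.5. Ties go to the
#' left plate (both branches agree at 0.5).
#'
#' @param left,right numeric vectors in body-weight fraction, equal length.
#' @param fs sampling rate in Hz (default 100).
#' @param t0 start time in seconds.
#' @return a `"merged_trace"`: list with `values`, `fs`, `t0` and
#'   `origin_flags` (`"L"`/`"R"`, which plate supplied each sample).
#' @export
merge_and_mirror <- function(left, right, fs = 100, t0 = 0) {
  if (length(left) != length(right)) {
    stop("left/right force traces have different lengths")
  }
  take_left <- left >= right
  values <- ifelse(take_left, left, 1 - right)
  structure(
    list(values = as.numeric(values), fs = fs, t0 = t0,
         origin_flags = ifelse(take_left, "L", "R")),
    class = "merged_trace"
  )
}

#' @export
print.merged_trace <- function(x, ...) {
  cat(sprintf("<merged_trace> %d samples @ %g Hz, range [%.3f, %.3f]\n",
              length(x$values), x$fs, min(x$values), max(x$values)))
  invisible(x)
}

#' Windowed weight-shift series from a merged trace
#'
#' For each window of `window_s` seconds ending on the `stride_s` grid, the
#' raw shift value is the total variation (sum of absolute first
#' differences) of the merged trace inside the window. A completely
#' motionless trace yields 0; the value grows with both excursion amplitude
#' and stepping cadence. Window end times start at `window_s` and are
#' anchored on the force-sample grid.
#'
#' @param merged a `"merged_trace"` from [merge_and_mirror()].
#' @param window_s window length in seconds (default 2).
#' @param stride_s stride between window ends in seconds (default 0.1).
#' @return a `"weight_shift_series"`: list with `times` (window END times,
#'   seconds), `raw_values`, `normalized_values` (NA until
#'   [normalize_across_visits()]), `normalizer` (NA), `window_s`, `stride_s`.
#' @export
windowed_shift <- function(merged, window_s = 2, stride_s = 0.1) {
  fs <- merged$fs
  wlen <- round(window_s * fs)
  slen <- round(stride_s * fs)
  n <- length(merged$values)
  if (n < wlen) {
    warning("recording shorter than one window: empty weight-shift series")
    return(new_shift_series(numeric(0), numeric(0), window_s, stride_s))
  }
  ends <- seq(wlen, n, by = slen)
  absd <- c(0, abs(diff(merged$values)))
  csum <- cumsum(absd)
  ## TV over samples (end - wlen + 1) .. end  => csum[end] - csum[start]
  starts <- ends - wlen + 1L
  raw <- csum[ends] - csum[starts]
  ## sample `end` closes the window (t_end - window_s, t_end], t_end = t0 + end/fs
  times <- merged$t0 + ends / fs
  new_shift_series(times, raw, window_s, stride_s)
}

new_shift_series <- function(times, raw, window_s, stride_s,
                             normalized = rep(NA_real_, length(raw)),
                             normalizer = NA_real_) {
  structure(
    list(times = times, raw_values = raw, normalized_values = normalized,
         normalizer = normalizer, window_s = window_s, stride_s = stride_s),
    class = "weight_shift_series"
  )
}

#' @export
print.weight_shift_series <- function(x, ...) {
  cat(sprintf("<weight_shift_series> %d windows (%gs window / %gs stride)",
              length(x$times), x$window_s, x$stride_s))
  if (length(x$times)) {
    cat(sprintf(", t in [%.1f, %.1f] s, raw max %.4g", min(x$times),
                max(x$times), max(x$raw_values)))
  }
  cat(if (is.na(x$normalizer)) " [unnormalized]\n"
      else sprintf(" [normalizer %.4g]\n", x$normalizer))
  invisible(x)
}

#' Normalize weight-shift series within a participant
#'
#' Divides every visit's raw values by a single participant-level
#' normalizer: the maximum raw 2-s shift over the provided visits (so the
#' participant's global maximum maps to 1 and motionless windows stay 0).
#' `normalizer_from = "train"` restricts the normalizer to the training
#' visit for strict train/test separation.
#'
#' @param series_by_visit named list of `"weight_shift_series"`, one per
#'   visit.
#' @param normalizer_from `"all"` (default, all visits jointly) or
#'   `"train"`.
#' @param train_visit name of the training visit (needed for `"train"`).
#' @return the input list with `normalized_values` and `normalizer` filled.
#' @export
normalize_across_visits <- function(series_by_visit,
                                    normalizer_from = c("all", "train"),
                                    train_visit = NULL) {
  normalizer_from <- match.arg(normalizer_from)
  stopifnot(length(series_by_visit) >= 1L)
  pool <- if (normalizer_from == "all") {
    unlist(lapply(series_by_visit, `[[`, "raw_values"))
  } else {
    if (is.null(train_visit) || !train_visit %in% names(series_by_visit)) {
      stop("normalizer_from = 'train' needs a valid train_visit name")
    }
    series_by_visit[[train_visit]]$raw_values
  }
  normalizer <- max(pool)
  if (!is.finite(normalizer) || normalizer <= 0) {
    stop("no movement detected; normalizer undefined")
  }
  lapply(series_by_visit, function(s) {
    s$normalized_values <- s$raw_values / normalizer
    s$normalizer <- normalizer
    s
  })
}

#' Write a weight-shift series to CSV
#' @param series a `"weight_shift_series"`.
#' @param path output path; columns `time_s, raw, normalized`.
#' @return `path`, invisibly.
#' @export
write_weight_shift <- function(series, path) {
  utils::write.csv(
    data.frame(time_s = series$times, raw = series$raw_values,
               normalized = series$normalized_values),
    path, row.names = FALSE)
  invisible(path)
}

#' Full force-plate to weight-shift pipeline for one visit
#'
#' Convenience composition: 2 Hz low-pass, rescale by weight, merge/mirror,
#' windowed total variation. Normalization across visits is a separate step.
#'
#' @param force raw force [recording()] at 100 Hz.
#' @param weight participant body weight (same units as `force`).
#' @param window_s,stride_s window geometry (defaults 2 s / 0.1 s).
#' @return an unnormalized `"weight_shift_series"`.
#' @export
force_to_shift <- function(force, weight, window_s = 2, stride_s = 0.1) {
  sm <- lowpass_force(force)
  bw <- rescale_by_weight(sm, weight)
  merged <- merge_and_mirror(bw$data[1, ], bw$data[2, ], fs = bw$fs, t0 = bw$t0)
  windowed_shift(merged, window_s, stride_s)
}
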