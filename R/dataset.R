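## Windowed (LFP, label) example assembly: 5-second two-channel LFP windows
## at 211 Hz paired with the weight shift over the window's final 2 seconds,
## one example every 0.1 s.

LFP_FS <- 211
FORCE_FS <- 100
WIN_S <- 5
LABEL_WIN_S <- 2
STRIDE_S <- 0.1

#' Build a windowed dataset from an LFP recording and a label series
#'
#' One example per weight-shift label whose window end time is at least
#' `win_s` seconds into the recording. The LFP window holds the last `win_s`
#' seconds before the label time (window length `round(win_s * fs)`
#' samples); the 0.1 s label grid does not fall on integer 211 Hz sample
#' counts, so each end time is mapped to the nearest LFP sample (max
#' misalignment ~2.4 ms).
#'
#' @param lfp a 2-channel [recording()] at 211 Hz (preprocessed).
#' @param labels a `"weight_shift_series"` with `normalized_values` filled
#'   (falls back to `raw_values` with a warning if not normalized).
#' @param win_s input window length in seconds (default 5).
#' @param stride_s label stride in seconds (default 0.1).
#' @param role split role string.
#' @param participant_id participant identifier.
#' @param subsample keep every `subsample`-th example (default 1 = all);
#'   used by the fast CI profile.
#' @return a `"windowed_dataset"`: list with `x` (array `2 x L x N`), `y`
#'   (length-N labels), `end_times`, `role`, `participant_id`, `win_s`,
#'   `stride_s`.
#' @export
build_windowed_dataset <- function(lfp, labels, win_s = WIN_S,
                                   stride_s = STRIDE_S, role = "train",
                                   participant_id = "p", subsample = 1L) {
  stopifnot(inherits(lfp, "recording"), nrow(lfp$data) == 2L)
  if (length(labels$times) > 0) {
    ## label end times must land on the stride grid of the LFP time base
    off <- (labels$times[1] - lfp$t0) / stride_s
    if (abs(off - round(off)) * stride_s > 1 / (2 * FORCE_FS)) {
      stop("LFP and label streams misaligned beyond half a force sample")
    }
  }
  L <- round(win_s * lfp$fs)
  yv <- labels$normalized_values
  if (all(is.na(yv))) {
    warning("labels not normalized; using raw shift values")
    yv <- labels$raw_values
  }
  keep <- labels$times >= win_s - 1e-9
  times <- labels$times[keep]
  yv <- yv[keep]
  ## drop label windows whose LFP window would overrun the recording
  max_t <- lfp$t0 + n_samples(lfp) / lfp$fs + 1e-9
  ok <- times <= max_t
  times <- times[ok]; yv <- yv[ok]
  if (subsample > 1L && length(times) > 0) {
    idx <- seq(1L, length(times), by = as.integer(subsample))
    times <- times[idx]; yv <- yv[idx]
  }
  n <- length(times)
  if (n == 0L) {
    warning("task shorter than one input window: empty dataset")
    return(new_windowed_dataset(array(0, c(2, L, 0)), numeric(0), numeric(0),
                                role, participant_id, win_s, stride_s))
  }
  x <- array(0, c(2L, L, n))
  for (i in seq_len(n)) {
    end_idx <- round((times[i] - lfp$t0) * lfp$fs)  # nearest sample
    start_idx <- end_idx - L + 1L
    if (start_idx < 1L || end_idx > n_samples(lfp)) {
      stop(sprintf("LFP window for label at %.2f s extends past recording bounds",
                   times[i]))
    }
    x[, , i] <- lfp$data[, start_idx:end_idx]
  }
  new_windowed_dataset(x, yv, times, role, participant_id, win_s, stride_s)
}

new_windowed_dataset <- function(x, y, end_times, role, participant_id,
                                 win_s, stride_s) {
  structure(
    list(x = x, y = y, end_times = end_times, role = role,
         participant_id = participant_id, win_s = win_s, stride_s = stride_s),
    class = "windowed_dataset"
  )
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %s/%s: %d examples (2 x %d windows)",
              x$participant_id, x$role, length(x$y), dim(x$x)[2]))
  if (length(x$y)) cat(sprintf(", labels in [%.3f, %.3f]", min(x$y), max(x$y)))
  cat("\n")
  invisible(x)
}

#' @export
length.windowed_dataset <- function(x) length(x$y)

#' Load and preprocess one visit's paired session
#'
#' Reads the visit's LFP and force CSVs, decimates to the analysis rates
#' (211 Hz / 100 Hz), band-pass filters the LFP to 8-100 Hz, low-pass
#' filters the force at 2 Hz, estimates body weight from the baseline
#' interval, and computes the raw weight-shift series.
#'
#' @param visit one visit entry from a `"session_manifest"`.
#' @return list with `lfp` (filtered 211 Hz recording), `lfp_raw211`
#'   (decimated but not band-passed), `force` (2 Hz low-passed 100 Hz
#'   recording), `weight`, `shift` (raw `"weight_shift_series"`).
#' @export
load_visit <- function(visit) {
  lfp_fs <- if (is.null(visit$lfp_fs)) 422 else visit$lfp_fs
  force_fs <- if (is.null(visit$force_fs)) 100 else visit$force_fs
  lfp <- read_recording(visit$lfp_path, expected_fs = lfp_fs,
                        expected_channels = 2)
  force <- read_recording(visit$force_path, expected_fs = force_fs,
                          expected_channels = 2)
  if (lfp$fs != LFP_FS) lfp <- resample_recording(lfp, LFP_FS)
  if (force$fs != FORCE_FS) force <- resample_recording(force, FORCE_FS)
  if (!is.null(visit$task_interval)) {
    lfp <- crop_recording(lfp, visit$task_interval[1], visit$task_interval[2])
    force <- crop_recording(force, visit$task_interval[1], visit$task_interval[2])
  }
  weight <- estimate_body_weight(force, visit$baseline_interval)
  lfp_filt <- bandpass_iir(lfp, 8, 100, order = 4)
  shift <- force_to_shift(force, weight)
  force_sm <- lowpass_force(force)
  list(lfp = lfp_filt, lfp_raw211 = lfp, force = force_sm, weight = weight,
       shift = shift)
}

#' Assemble train/validation/test datasets from a manifest
#'
#' Loads all three visits of one participant (subject-dependent: no
#' cross-participant mixing), normalizes the weight-shift labels across
#' visits, and windows each visit into examples.
#'
#' @param manifest a `"session_manifest"`.
#' @param normalizer_from `"all"` (paper behaviour: participant max over all
#'   three visits) or `"train"`.
#' @param subsample keep every n-th example (fast profile), default 1.
#' @return list with `train`, `validation`, `test` (each a
#'   `"windowed_dataset"`), `sessions` (per-role [load_visit()] outputs) and
#'   `normalizer`.
#' @export
assemble_splits <- function(manifest, normalizer_from = "all", subsample = 1L) {
  validate_manifest(manifest)
  roles <- c("train", "validation", "test")
  sessions <- lapply(roles, function(r) load_visit(visit_by_role(manifest, r)))
  names(sessions) <- roles
  shifts <- lapply(sessions, `[[`, "shift")
  shifts <- normalize_across_visits(shifts, normalizer_from = normalizer_from,
                                    train_visit = "train")
  out <- lapply(roles, function(r) {
    build_windowed_dataset(sessions[[r]]$lfp, shifts[[r]], role = r,
                           participant_id = manifest$participant_id,
                           subsample = if (r == "test") 1L else subsample)
  })
  names(out) <- roles
  out$sessions <- sessions
  out$labels <- shifts
  out$normalizer <- shifts$train$normalizer
  out
}
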