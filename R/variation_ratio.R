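## Frequency-band attribution by output variance ("variation ratio"):
## band-filter the training LFP into six canonical bands, run each filtered
## stream through the trained model, collect the pre-ReLU outputs, and
## normalize the per-band output variances to sum to 1.

#' The six canonical attribution bands
#'
#' delta/theta (<= 8 Hz, implemented as 1-8 Hz to keep the 4th-order IIR
#' stable away from DC), alpha (8-13), low-beta (13-20), high-beta (20-36),
#' low-gamma (36-70) and high-gamma (>= 70 Hz, implemented as 70-104 Hz just
#' below the 105.5 Hz Nyquist).
#'
#' @return named list of `c(lo, hi)` band edges in Hz.
#' @export
frequency_bands <- function() {
  list(delta_theta = c(1, 8), alpha = c(8, 13), low_beta = c(13, 20),
       high_beta = c(20, 36), low_gamma = c(36, 70), high_gamma = c(70, 104))
}

window_grid_lfp <- function(lfp, win_s, stride_s) {
  ## window end times on the stride grid, starting at win_s
  Tdur <- n_samples(lfp) / lfp$fs
  if (Tdur < win_s) stop("recording shorter than one window")
  seq(win_s, Tdur + 1e-9, by = stride_s) + lfp$t0
}

windows_from_lfp <- function(lfp, end_times, win_len) {
  n <- length(end_times)
  x <- array(0, c(2L, win_len, n))
  for (i in seq_len(n)) {
    e <- round((end_times[i] - lfp$t0) * lfp$fs)
    x[, , i] <- lfp$data[, (e - win_len + 1L):e]
  }
  x
}

#' Variation ratio of a trained model across frequency bands
#'
#' For each band: causally band-pass filter the LFP, cut it into model
#' windows on the stride grid, collect the model's pre-ReLU outputs, and
#' take their unbiased sample variance. Ratios are the variances normalized
#' to sum to 1 across bands.
#'
#' @param model a trained `"model_handle"` (or `"train_result"`), or a plain
#'   function `f(x_array) -> numeric` mapping a window array `(2, L, N)` to
#'   N pre-activation values (used by analytic toy models in tests).
#' @param lfp the training visit's 2-channel 211 Hz LFP [recording()]. By
#'   convention this is the 8-100 Hz analysis stream feeding training (set
#'   `prefiltered_stream = FALSE` to pass the unfiltered 211 Hz stream
#'   instead; both orderings are supported, this merely documents intent).
#' @param bands named list of `c(lo, hi)` Hz edges (default
#'   [frequency_bands()]).
#' @param win_s,stride_s window geometry; stride defaults to the training
#'   grid (0.1 s), coarser grids subsample the windows.
#' @param win_len window length in samples (defaults to the model's
#'   `input_len`, or `round(win_s * fs)` for function models).
#' @param prefiltered_stream documentation flag recorded in the report.
#' @return a `"variation_ratio_report"`: `ratios` (named, sums to 1),
#'   `variances`, `n_windows_per_band`, `argmax_band`.
#' @export
variation_ratio <- function(model, lfp, bands = frequency_bands(),
                            win_s = 5, stride_s = 0.1, win_len = NULL,
                            prefiltered_stream = TRUE) {
  if (inherits(model, "train_result")) model <- model$model
  predict_fn <- if (is.function(model)) {
    model
  } else {
    if (is.null(win_len)) win_len <- model$config$input_len
    function(x) predict_model(model, x)$preact
  }
  if (is.null(win_len)) win_len <- round(win_s * lfp$fs)
  ends <- window_grid_lfp(lfp, win_s, stride_s)
  ends <- ends[round((ends - lfp$t0) * lfp$fs) >= win_len]
  if (length(ends) < 2L) stop("need at least 2 windows per band")
  variances <- vapply(bands, function(bd) {
    filt <- bandpass_iir(lfp, bd[1], bd[2], order = 4)
    x <- windows_from_lfp(filt, ends, win_len)
    stats::var(predict_fn(x))
  }, 0)
  total <- sum(variances)
  if (!is.finite(total) || total <= 0) {
    stop("degenerate model output: zero total variance across bands")
  }
  ratios <- variances / total
  structure(
    list(ratios = ratios, variances = variances,
         n_windows_per_band = length(ends),
         argmax_band = names(which.max(ratios)),
         prefiltered_stream = prefiltered_stream),
    class = "variation_ratio_report"
  )
}

#' @export
print.variation_ratio_report <- function(x, ...) {
  cat(sprintf("<variation_ratio_report> %d windows/band, argmax = %s\n",
              x$n_windows_per_band, x$argmax_band))
  print(round(x$ratios, 4))
  invisible(x)
}

#' Percentile bootstrap confidence intervals for band ratios
#'
#' Resamples replicate ratio vectors (rows = replicates, e.g. participants
#' or synthetic runs; columns = bands) and returns per-band percentile
#' intervals of the mean ratio.
#'
#' @param ratios matrix of replicate ratio vectors (rows = replicates).
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed RNG seed.
#' @return data.frame with `band`, `mean`, `lower`, `upper`.
#' @export
bootstrap_ci <- function(ratios, level = 0.95, n_boot = 10000L, seed = 1L) {
  ratios <- as.matrix(ratios)
  n <- nrow(ratios)
  if (n < 2L) stop("need at least 2 replicates for a bootstrap CI")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
  boot_means <- apply(idx, 1, function(ii) colMeans(ratios[ii, , drop = FALSE]))
  if (is.null(dim(boot_means))) boot_means <- matrix(boot_means, nrow = 1)
  alpha <- (1 - level) / 2
  qs <- apply(boot_means, 1, stats::quantile, probs = c(alpha, 1 - alpha))
  data.frame(band = colnames(ratios), mean = colMeans(ratios),
             lower = qs[1, ], upper = qs[2, ], row.names = NULL)
}
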