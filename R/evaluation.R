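## Evaluation: MAE/MSE, tie-corrected Kendall tau, and the per-lead 2-second
## beta-power baseline the model is compared against.

#' Mean absolute error
#' @param pred,label equal-length numeric vectors.
#' @return scalar `mean(|pred - label|)`.
#' @export
mae <- function(pred, label) {
  if (length(pred) != length(label)) stop("length mismatch")
  stopifnot(length(pred) >= 1L)
  mean(abs(pred - label))
}

#' Mean squared error
#' @param pred,label equal-length numeric vectors.
#' @return scalar `mean((pred - label)^2)`.
#' @export
mse <- function(pred, label) {
  if (length(pred) != length(label)) stop("length mismatch")
  stopifnot(length(pred) >= 1L)
  mean((pred - label)^2)
}

#' Kendall tau-b rank correlation
#'
#' Tie-corrected (tau-b) coefficient; the tie correction matters here
#' because both the zero-floored labels (motionless windows) and the ReLU
#' predictions produce ties at 0.
#'
#' @param x,y equal-length numeric vectors, length >= 2.
#' @return scalar in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Kendall tau undefined for constant input")
  }
  unname(stats::cor(x, y, method = "kendall"))
}

#' Per-lead average beta power over the label windows
#'
#' Band-pass filters each LFP lead to the beta band (4th-order causal
#' Butterworth), squares, and averages over each 2-second label interval —
#' the classical band-power biomarker the network is benchmarked against.
#'
#' @param lfp a 2-channel [recording()] at 211 Hz (the 8-100 Hz analysis
#'   stream).
#' @param label_times window END times in seconds.
#' @param band `c(lo, hi)` in Hz (default beta, 13-36).
#' @param window_s averaging window (default 2 s).
#' @return matrix `length(label_times) x 2` (columns = leads).
#' @export
beta_power_labels <- function(lfp, label_times, band = c(13, 36),
                              window_s = 2) {
  filt <- bandpass_iir(lfp, band[1], band[2], order = 4)
  sq <- filt$data^2
  fs <- lfp$fs
  n <- n_samples(lfp)
  out <- matrix(NA_real_, length(label_times), 2)
  colnames(out) <- lfp$channel_labels
  for (i in seq_along(label_times)) {
    end_idx <- round((label_times[i] - lfp$t0) * fs)
    start_idx <- end_idx - round(window_s * fs) + 1L
    if (start_idx < 1L || end_idx > n) {
      stop(sprintf("beta-power interval at %.2f s out of recording bounds",
                   label_times[i]))
    }
    out[i, ] <- rowMeans(sq[, start_idx:end_idx, drop = FALSE])
  }
  out
}

#' Full metrics report: errors plus correlation comparison with beta power
#'
#' Computes MAE/MSE of the predictions, the Kendall tau between predictions
#' and weight-shift labels, and the per-lead taus between 2-s beta power and
#' the labels (reported as lower/higher of the two leads).
#'
#' @param pred prediction vector aligned with `labels`.
#' @param lfp the split's 2-channel 211 Hz LFP [recording()] (analysis
#'   stream).
#' @param label_times label window end times (seconds).
#' @param labels label values in `[0, 1]` aligned with `label_times`.
#' @param split split name for the report.
#' @return a `"metrics_report"` list: `mae`, `mse`, `tau_model`,
#'   `tau_beta_left`, `tau_beta_right`, `tau_beta_lower`, `tau_beta_higher`,
#'   `n_examples`, `split`.
#' @export
correlation_comparison <- function(pred, lfp, label_times, labels,
                                   split = "test") {
  stopifnot(length(pred) == length(labels),
            length(label_times) == length(labels))
  bp <- beta_power_labels(lfp, label_times)
  ## degenerate (constant) series make tau undefined; report NA with a flag
  ## rather than aborting a whole evaluation run
  safe_tau <- function(x, y) {
    tryCatch(kendall_tau(x, y), error = function(e) NA_real_)
  }
  tau_l <- safe_tau(bp[, 1], labels)
  tau_r <- safe_tau(bp[, 2], labels)
  tau_m <- safe_tau(pred, labels)
  rep <- list(mae = mae(pred, labels), mse = mse(pred, labels),
              tau_model = tau_m,
              tau_beta_left = tau_l, tau_beta_right = tau_r,
              tau_beta_lower = min(tau_l, tau_r),
              tau_beta_higher = max(tau_l, tau_r),
              tau_defined = !anyNA(c(tau_m, tau_l, tau_r)),
              n_examples = length(labels), split = split)
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat(sprintf("<metrics_report> %s (n=%d): MAE %.4f MSE %.4f | tau model %s, beta [%s, %s]\n",
              x$split, x$n_examples, x$mae, x$mse, fmt(x$tau_model),
              fmt(x$tau_beta_lower), fmt(x$tau_beta_higher)))
  invisible(x)
}

#' Group-level nonparametric comparisons over per-participant reports
#'
#' Thin reporting utility: Mann-Whitney U between two groups of
#' per-participant metric values, or Wilcoxon signed-rank for paired
#' comparisons (model tau vs higher-coefficient beta tau), with the
#' conventional thresholds 0.05 (Mann-Whitney) and 0.025
#' (Bonferroni-corrected Wilcoxon over the two splits).
#'
#' @param a,b numeric vectors of per-participant values.
#' @param paired logical: Wilcoxon signed-rank when `TRUE`, else
#'   Mann-Whitney U.
#' @return list with `statistic`, `p_value`, `test`, `significant`.
#' @export
group_compare <- function(a, b, paired = FALSE) {
  ht <- stats::wilcox.test(a, b, paired = paired, exact = FALSE)
  threshold <- if (paired) 0.025 else 0.05
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       test = if (paired) "wilcoxon_signed_rank" else "mann_whitney_u",
       significant = ht$p.value < threshold, threshold = threshold)
}
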