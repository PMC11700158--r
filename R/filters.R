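## Butterworth IIR design via the classical route: analog low-pass prototype
## poles -> frequency-band transform in the s-plane -> bilinear transform.
## Kept in zero-pole-gain form until the final polynomial expansion for
## numerical stability at the orders used here (<= 8 poles).

#' Design a digital Butterworth filter
#'
#' Designs a causal Butterworth filter by bilinear transform of the analog
#' prototype, matching the conventions of scipy's `butter` / MATLAB's
#' `butter`: for `type = "band"` the returned transfer function has `2 *
#' order` poles.
#'
#' @param order prototype order (number of analog poles), e.g. 4.
#' @param w critical frequency(ies) as a fraction of the Nyquist rate: a
#'   scalar in (0, 1) for `"low"`/`"high"`, a length-2 vector for `"band"`.
#' @param type `"low"`, `"high"` or `"band"`.
#' @return list with numerator `b`, denominator `a` (leading coefficient 1),
#'   `order`, `w`, `type`; class `"iir_filter"`.
#' @examples
#' f <- butter_design(4, c(8, 100) / (211 / 2), "band")
#' Mod(freq_response(f, 50, fs = 211))   # ~1 in the passband
#' @export
butter_design <- function(order, w, type = c("low", "high", "band")) {
  type <- match.arg(type)
  if (any(w <= 0) || any(w >= 1)) {
    stop("critical frequencies must lie strictly inside (0, 1) x Nyquist")
  }
  if (type == "band" && (length(w) != 2L || w[1] >= w[2])) {
    stop("band design needs w = c(lo, hi) with lo < hi")
  }
  n <- as.integer(order)
  stopifnot(n >= 1L)
  ## analog Butterworth prototype: poles on the unit circle, left half plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  z <- complex(0)
  gain <- 1
  ## prewarp digital edges to analog frequencies (bilinear with c = 1)
  warped <- tan(pi * w / 2)
  if (type == "low") {
    p <- p * warped
    gain <- gain * warped^n
  } else if (type == "high") {
    ## lp2hp: s -> warped / s; Butterworth prototype has prod(-p) = 1, so
    ## the transformed gain stays 1
    p <- warped / p
    z <- rep(0 + 0i, n)
    gain <- 1
  } else {
    bw <- warped[2] - warped[1]
    w0 <- sqrt(warped[1] * warped[2])
    ## each prototype pole maps to a conjugate pair
    p_lp <- p * bw / 2
    disc <- sqrt(p_lp^2 - w0^2)
    p <- c(p_lp + disc, p_lp - disc)
    z <- rep(0 + 0i, n)
    gain <- gain * bw^n
  }
  ## bilinear transform s = (z - 1)/(z + 1)
  nz <- length(z)
  np <- length(p)
  zd <- (1 + z) / (1 - z)
  pd <- (1 + p) / (1 - p)
  gain_d <- gain * Re(prod(1 - z) / prod(1 - p))
  zd <- c(zd, rep(-1 + 0i, np - nz))  # zeros at Nyquist from relative degree
  b <- Re(poly_from_roots(zd)) * gain_d
  a <- Re(poly_from_roots(pd))
  structure(list(b = b, a = a, order = n, w = w, type = type),
            class = "iir_filter")
}

## expand prod (x - r_i) into descending-power coefficients
poly_from_roots <- function(r) {
  cf <- 1 + 0i
  for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
  cf
}

#' Frequency response of a designed filter
#'
#' Evaluates the transfer function `H(e^{i 2 pi f / fs})` at physical
#' frequencies `f`.
#'
#' @param filt an `"iir_filter"` from [butter_design()].
#' @param f frequencies in Hz.
#' @param fs sampling rate in Hz the normalized design refers to.
#' @return complex response values; take `Mod()` for gain.
#' @export
freq_response <- function(filt, f, fs) {
  zi <- exp(-1i * 2 * pi * f / fs)
  polyeval <- function(cf, x) {
    acc <- rep(0 + 0i, length(x))
    for (c0 in cf) acc <- acc * x + c0
    acc
  }
  ## coefficients are in ascending delay order b0 + b1 z^-1 + ...
  num <- polyeval(rev(filt$b), 1 / zi) * zi^(length(filt$b) - 1)
  den <- polyeval(rev(filt$a), 1 / zi) * zi^(length(filt$a) - 1)
  num / den
}

#' Apply an IIR filter causally to a signal
#'
#' Direct-form difference equation, single causal pass (no zero-phase
#' refiltering, matching real-time use). By default the filter state is
#' initialized at the DC steady state of the first sample (the signal minus
#' `x[1]` is filtered and `x[1] * H(0)` added back), so a constant input
#' produces a constant output from the first sample instead of a start-up
#' step transient.
#'
#' @param filt an `"iir_filter"`.
#' @param x numeric vector.
#' @param dc_init initialize at the first sample's DC steady state
#'   (default `TRUE`); `FALSE` gives zero initial conditions.
#' @return filtered vector, same length.
#' @export
iir_apply <- function(filt, x, dc_init = TRUE) {
  b <- filt$b / filt$a[1]
  a <- filt$a / filt$a[1]
  nb <- length(b)
  if (dc_init) {
    x0 <- x[1]
    h0 <- sum(b) / sum(a)
    xw <- x - x0
  } else {
    x0 <- 0
    h0 <- 0
    xw <- x
  }
  ## moving-average part via padded convolution
  z <- stats::filter(c(rep(0, nb - 1), xw), b, method = "convolution", sides = 1)
  z <- as.numeric(z)[nb:(nb - 1 + length(xw))]
  if (length(a) > 1L) {
    y <- stats::filter(z, -a[-1], method = "recursive")
    y <- as.numeric(y)
  } else {
    y <- z
  }
  y <- y + x0 * h0
  if (any(!is.finite(y))) stop("IIR filter produced non-finite output (unstable?)")
  y
}

#' Check filter stability
#' @param filt an `"iir_filter"`.
#' @return `TRUE` when all poles are strictly inside the unit circle.
#' @export
is_stable <- function(filt) {
  a <- filt$a / filt$a[1]
  if (length(a) == 1L) return(TRUE)
  all(Mod(polyroot(rev(a))) < 1)
}

filter_recording <- function(rec, filt) {
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    out$data[i, ] <- iir_apply(filt, rec$data[i, ])
  }
  out
}

#' Band-pass filter a recording
#'
#' Causal Butterworth band-pass (default 4th order), applied per channel.
#' One-sided bands are supported: omit `lo` for a low-pass at `hi`, omit
#' `hi` for a high-pass at `lo`.
#'
#' @param rec a [recording()].
#' @param lo lower edge in Hz, or `NULL` for low-pass.
#' @param hi upper edge in Hz, or `NULL` for high-pass.
#' @param order Butterworth prototype order (default 4).
#' @return filtered [recording()], same shape and rate.
#' @export
bandpass_iir <- function(rec, lo = NULL, hi = NULL, order = 4) {
  nyq <- rec$fs / 2
  for (edge in c(lo, hi)) {
    if (!is.null(edge) && (edge <= 0 || edge >= nyq)) {
      stop(sprintf("band edge %g Hz outside (0, %g) Hz", edge, nyq))
    }
  }
  filt <- if (!is.null(lo) && !is.null(hi)) {
    if (lo >= hi) stop("lo must be < hi")
    butter_design(order, c(lo, hi) / nyq, "band")
  } else if (!is.null(hi)) {
    butter_design(order, hi / nyq, "low")
  } else if (!is.null(lo)) {
    butter_design(order, lo / nyq, "high")
  } else {
    stop("at least one of lo, hi must be given")
  }
  out <- filter_recording(rec, filt)
  attr(out, "filter") <- filt
  out
}

#' Low-pass filter force-plate data at 2 Hz
#'
#' The fixed smoothing applied to ground-reaction-force traces to suppress
#' jerky non-gait noise before weight-shift quantification.
#'
#' @param rec a force [recording()] (100 Hz).
#' @param cutoff cutoff in Hz (default 2).
#' @param order Butterworth order (default 4).
#' @return filtered [recording()].
#' @export
lowpass_force <- function(rec, cutoff = 2, order = 4) {
  bandpass_iir(rec, lo = NULL, hi = cutoff, order = order)
}

#' Decimate a recording to a lower sampling rate
#'
#' Anti-alias filters (8th-order Butterworth low-pass at 0.8 x the target
#' Nyquist) and keeps every `factor`-th sample. The factor must be an
#' integer (422 -> 211 Hz for LFP, 1000 -> 100 Hz for force).
#'
#' @param rec a [recording()].
#' @param target_fs target rate in Hz; must divide `rec$fs` exactly.
#' @return a [recording()] at `target_fs` with `ceiling(n / factor)` samples.
#' @export
resample_recording <- function(rec, target_fs) {
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop(sprintf("target fs %g does not divide %g by an integer factor",
                 target_fs, rec$fs))
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  aa <- butter_design(8, 0.8 * (target_fs / 2) / (rec$fs / 2), "low")
  out <- filter_recording(rec, aa)
  idx <- seq(1L, n_samples(rec), by = factor)
  recording(out$data[, idx, drop = FALSE], target_fs, rec$channel_labels,
            t0 = rec$t0)
}

#' Estimate body weight from a motionless baseline
#'
#' Mean over the baseline interval of the summed left + right plate signal.
#' Applied to the raw (unfiltered) force trace so the causal low-pass
#' start-up transient cannot bias the estimate.
#'
#' @param force a 2-channel force [recording()].
#' @param baseline_interval `c(start_s, end_s)` within the recording,
#'   duration at least 1 s.
#' @return scalar weight in the units of `force`.
#' @export
estimate_body_weight <- function(force, baseline_interval) {
  stopifnot(length(baseline_interval) == 2L)
  if (diff(baseline_interval) < 1) {
    stop("baseline interval shorter than 1 s: unreliable weight estimate")
  }
  seg <- crop_recording(force, baseline_interval[1], baseline_interval[2])
  mean(colSums(seg$data))
}
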