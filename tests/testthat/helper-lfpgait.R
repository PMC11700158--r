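## Shared fixtures: a miniature model configuration (fast to build and
## differentiate) and small signal builders. All fixtures are generated in
## code; nothing is read from disk.

tiny_cfg <- function(...) {
  args <- list(n_filters_per_channel = 4L, conv_kernel_len = 7L,
               pool_len = 10L, pool_stride = 5L, se_reduction = 4L,
               lstm_hidden = 3L, lstm_layers = 2L, input_len = 40L,
               head_kernel_len = 3L, head_channels_per_group = 4L,
               head_merge_channels = 4L, seed = 42L)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

sine_recording <- function(freq, fs, dur, amp = 1, channels = 2) {
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq * tt)
  recording(matrix(rep(x, channels), nrow = channels, byrow = TRUE), fs)
}

## steady-state amplitude of a (filtered) sinusoid: discard the transient,
## take max |x| over whole cycles
steady_amp <- function(x, fs, skip_s = 2) {
  seg <- x[-seq_len(round(skip_s * fs))]
  max(abs(seg))
}

## independent straight-line reimplementation of the merge/mirror + windowed
## total-variation pipeline (the oracle for the weight-shift module)
brute_weight_shift <- function(left, right, fs = 100, window_s = 2,
                               stride_s = 0.1) {
  n <- length(left)
  merged <- numeric(n)
  for (i in seq_len(n)) {
    merged[i] <- if (left[i] >= right[i]) left[i] else 1 - right[i]
  }
  wlen <- round(window_s * fs)
  slen <- round(stride_s * fs)
  ends <- seq(wlen, n, by = slen)
  raw <- numeric(length(ends))
  for (j in seq_along(ends)) {
    acc <- 0
    for (i in (ends[j] - wlen + 2L):ends[j]) {
      acc <- acc + abs(merged[i] - merged[i - 1L])
    }
    raw[j] <- acc
  }
  list(merged = merged, times = ends / fs, raw = raw)
}

## O(n^2) brute-force Kendall tau-b with tie correction
brute_tau_b <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0; tie_x <- 0; tie_y <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tie_x <- tie_x + 1
      else if (dy == 0) tie_y <- tie_y + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tie_x) * (conc + disc + tie_y))
}

## tiny but learnable synthetic datasets for training-loop tests: labels are
## a monotone function of channel-1 signal power, so even a few epochs of a
## tiny model can reduce the loss
tiny_dataset <- function(n = 24, seed = 1, input_len = 40L, role = "train") {
  set.seed(seed)
  x <- array(0, c(2, input_len, n))
  y <- numeric(n)
  for (i in seq_len(n)) {
    a <- stats::runif(1, 0.2, 2)
    x[1, , i] <- a * sin(2 * pi * 8 * seq_len(input_len) / input_len) +
      stats::rnorm(input_len, sd = 0.05)
    x[2, , i] <- stats::rnorm(input_len, sd = 0.3)
    y[i] <- min(a / 2, 1)
  }
  lfpgait:::new_windowed_dataset(x, y, seq_len(n) * 0.1, role, "tinyP",
                                 win_s = input_len / 211, stride_s = 0.1)
}
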