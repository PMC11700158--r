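# Frequency-band attribution: normalization contract, toy-model
# identifiability with filter-leakage awareness, bootstrap CIs.

## analytic toy model: preactivation = mean band power of the window in a
## chosen band, computed with the package's own filters
toy_band_power_model <- function(band, fs = 211, win_len) {
  force(band)
  function(x) {
    n <- dim(x)[3]
    vapply(seq_len(n), function(i) {
      rec <- recording(x[, , i], fs)
      filt <- bandpass_iir(rec, band[1], band[2], order = 4)
      mean(filt$data^2)
    }, 0)
  }
}

test_that("the six canonical bands tile 1-104 Hz at the stated edges", {
  fb <- frequency_bands()
  expect_identical(names(fb), c("delta_theta", "alpha", "low_beta",
                                "high_beta", "low_gamma", "high_gamma"))
  edges <- unname(sapply(fb, `[`, 1))
  expect_equal(edges, c(1, 8, 13, 20, 36, 70))
  expect_true(all(sapply(fb, function(b) b[1] < b[2])))
  expect_lt(fb$high_gamma[2], 211 / 2)
})

test_that("ratios are a proper distribution over exactly six bands", {
  set.seed(14)
  lfp <- recording(matrix(rnorm(2 * 211 * 30), 2), fs = 211)
  fn <- function(x) colSums(matrix(x[1, 1, ], nrow = 1)) + rnorm(dim(x)[3], sd = 0.1)
  vr <- variation_ratio(fn, lfp, win_s = 5, stride_s = 1, win_len = 1055)
  expect_length(vr$ratios, 6)
  expect_true(all(vr$ratios >= 0 & vr$ratios <= 1))
  expect_equal(sum(vr$ratios), 1, tolerance = 1e-9)
  expect_gte(vr$n_windows_per_band, 2)
})

test_that("a low-beta-power toy model attributes to low_beta over neighbours", {
  set.seed(15)
  fs <- 211
  n <- fs * 60
  tt <- (0:(n - 1)) / fs
  ## randomized low-beta amplitude plus broadband background
  amp <- 1 + 0.8 * abs(sin(2 * pi * 0.04 * tt))
  sig1 <- amp * sin(2 * pi * 16 * tt) + 0.3 * rnorm(n)
  sig2 <- amp * sin(2 * pi * 16 * tt + 1) + 0.3 * rnorm(n)
  lfp <- recording(rbind(sig1, sig2), fs)
  model <- toy_band_power_model(c(13, 20), fs)
  vr <- variation_ratio(model, lfp, win_s = 5, stride_s = 1, win_len = 1055)
  expect_identical(vr$argmax_band, "low_beta")
  expect_gt(vr$ratios[["low_beta"]], 0.9)
  ## leakage exists but adjacent bands stay strictly smaller
  expect_gt(vr$ratios[["low_beta"]], vr$ratios[["alpha"]])
  expect_gt(vr$ratios[["low_beta"]], vr$ratios[["high_beta"]])
})

test_that("band order permutation permutes the report identically", {
  set.seed(16)
  lfp <- recording(matrix(rnorm(2 * 211 * 20), 2), fs = 211)
  fn <- function(x) apply(x, 3, function(w) mean(w^2))
  b1 <- frequency_bands()
  b2 <- b1[c(3, 1, 6, 2, 5, 4)]
  v1 <- variation_ratio(fn, lfp, bands = b1, win_s = 5, stride_s = 1,
                        win_len = 1055)
  v2 <- variation_ratio(fn, lfp, bands = b2, win_s = 5, stride_s = 1,
                        win_len = 1055)
  expect_equal(v2$ratios, v1$ratios[names(b2)])
  expect_identical(v1$argmax_band, v2$argmax_band)
})

test_that("degenerate model output is rejected", {
  lfp <- recording(matrix(rnorm(2 * 211 * 20), 2), fs = 211)
  expect_error(variation_ratio(function(x) rep(1, dim(x)[3]), lfp,
                               win_s = 5, stride_s = 1, win_len = 1055),
               "degenerate")
})

test_that("bootstrap CIs are seeded, contain the mean, and collapse on ties", {
  reps <- matrix(rep(c(0.1, 0.2, 0.3, 0.15, 0.15, 0.1), each = 5), nrow = 5)
  colnames(reps) <- names(frequency_bands())
  ci <- bootstrap_ci(reps, n_boot = 200, seed = 3)
  expect_equal(ci$lower, ci$mean, tolerance = 1e-12)  # identical replicates
  expect_equal(ci$upper, ci$mean, tolerance = 1e-12)

  set.seed(20)
  reps2 <- matrix(runif(8 * 6), 8, 6,
                  dimnames = list(NULL, names(frequency_bands())))
  reps2 <- reps2 / rowSums(reps2)
  c1 <- bootstrap_ci(reps2, n_boot = 500, seed = 7)
  c2 <- bootstrap_ci(reps2, n_boot = 500, seed = 7)
  expect_identical(c1, c2)
  expect_true(all(c1$lower <= c1$mean + 1e-12 & c1$mean <= c1$upper + 1e-12))
  expect_error(bootstrap_ci(reps2[1, , drop = FALSE]), "at least 2")
})
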