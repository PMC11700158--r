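# Weight-shift quantification: rescaling, merge/mirror, windowed total
# variation, per-participant normalization — checked against a brute-force
# reimplementation.

test_that("rescale_by_weight converts to body-weight fraction", {
  fs <- 100
  rec <- recording(rbind(rep(400, 300), rep(400, 300)), fs)
  out <- rescale_by_weight(rec, 800)
  expect_true(all(out$data == 0.5))

  rec2 <- recording(rbind(rep(800, 10), rep(0, 10)), fs)
  out2 <- rescale_by_weight(rec2, 800)
  expect_equal(out2$data[1, ], rep(1, 10))
  expect_equal(out2$data[2, ], rep(0, 10))

  ## scale invariance: doubling force and weight changes nothing
  out3 <- rescale_by_weight(recording(2 * rec$data, fs), 1600)
  expect_equal(out3$data, out$data)
  expect_error(rescale_by_weight(rec, 0), "positive")
})

test_that("merge_and_mirror applies the max/mirror rule per sample", {
  expect_equal(merge_and_mirror(1.0, 0.0)$values, 1.0)
  expect_equal(merge_and_mirror(0.0, 1.0)$values, 0.0)
  m <- merge_and_mirror(c(0.5, 0.7, 0.2), c(0.5, 0.3, 0.9))
  expect_equal(m$values, c(0.5, 0.7, 0.1))
  expect_identical(m$origin_flags, c("L", "L", "R"))
  expect_error(merge_and_mirror(1:3 / 10, 1:2 / 10), "different lengths")

  ## balanced stance maps to 0.5 regardless of origin
  expect_equal(merge_and_mirror(0.5, 0.5)$values, 0.5)
})

test_that("windowed_shift is the total variation over 2 s windows", {
  fs <- 100
  const <- merge_and_mirror(rep(0.5, 400), rep(0.5, 400), fs = fs)
  s <- windowed_shift(const)
  expect_true(all(s$raw_values == 0))
  expect_equal(s$times[1], 2.0)
  expect_equal(diff(s$times), rep(0.1, length(s$times) - 1))

  ## one full 0 -> 1 -> 0 triangular excursion inside a window has TV = 2
  tri <- c(rep(0, 50), seq(0, 1, length.out = 51)[-1],
           seq(1, 0, length.out = 51)[-1], rep(0, 50))
  mt <- structure(list(values = tri, fs = fs, t0 = 0), class = "merged_trace")
  s2 <- windowed_shift(mt)
  expect_equal(max(s2$raw_values), 2.0, tolerance = 1e-12)

  ## total variation is 1-homogeneous
  mt2 <- mt; mt2$values <- 2 * mt$values
  expect_equal(windowed_shift(mt2)$raw_values, 2 * s2$raw_values)

  short <- merge_and_mirror(rep(0.5, 100), rep(0.5, 100), fs = fs)
  expect_warning(s3 <- windowed_shift(short), "shorter than one window")
  expect_length(s3$raw_values, 0)
})

test_that("normalization maps the participant max across visits to 1", {
  mk <- function(mx) {
    v <- c(0, mx / 2, mx, mx / 4)
    lfpgait:::new_shift_series(seq_along(v) * 0.1 + 2, v, 2, 0.1)
  }
  out <- normalize_across_visits(list(v1 = mk(1.4), v2 = mk(2.0), v3 = mk(1.1)))
  expect_equal(out$v1$normalizer, 2.0)
  expect_equal(max(out$v1$normalized_values), 0.7)
  expect_equal(max(sapply(out, function(s) max(s$normalized_values))), 1.0)
  ## all visits live inside [0, 1] and only one attains 1 here
  expect_true(all(sapply(out, function(s) all(s$normalized_values >= 0 &
                                              s$normalized_values <= 1))))
  expect_equal(sum(sapply(out, function(s) max(s$normalized_values) == 1)), 1L)

  single <- normalize_across_visits(list(only = mk(0.37)))
  expect_equal(max(single$only$normalized_values), 1.0)

  zero <- lfpgait:::new_shift_series(c(2, 2.1), c(0, 0), 2, 0.1)
  expect_error(normalize_across_visits(list(a = zero)), "no movement detected")

  ## restricting the normalizer to the training visit
  tr <- normalize_across_visits(list(train = mk(1.0), test = mk(2.0)),
                                normalizer_from = "train", train_visit = "train")
  expect_equal(tr$test$normalizer, 1.0)
  expect_equal(max(tr$test$normalized_values), 2.0)
})

test_that("pipeline matches the brute-force oracle on random plate pairs", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(300:500, 1)
    left <- runif(n)
    right <- runif(n)
    oracle <- brute_weight_shift(left, right)
    m <- merge_and_mirror(left, right, fs = 100)
    expect_equal(m$values, oracle$merged, tolerance = 1e-15)
    s <- windowed_shift(m)
    expect_lt(max(abs(s$raw_values - oracle$raw)), 1e-9)
    expect_equal(s$times, oracle$times)
  }
})

test_that("swapping plates mirrors the merged trace and preserves shifts", {
  set.seed(7)
  left <- runif(400); right <- runif(400)
  m1 <- merge_and_mirror(left, right, fs = 100)
  m2 <- merge_and_mirror(right, left, fs = 100)
  ## ties (measure zero for runif) aside, swap maps merged -> 1 - merged
  expect_equal(m2$values, 1 - m1$values, tolerance = 1e-12)
  expect_equal(windowed_shift(m2)$raw_values, windowed_shift(m1)$raw_values,
               tolerance = 1e-12)
})

test_that("weight-shift series serializes to CSV", {
  s <- lfpgait:::new_shift_series(c(2, 2.1), c(0.5, 1.0), 2, 0.1,
                                  normalized = c(0.5, 1.0), normalizer = 1.0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_weight_shift(s, path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("time_s", "raw", "normalized"))
  expect_equal(df$raw, c(0.5, 1.0))
})
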