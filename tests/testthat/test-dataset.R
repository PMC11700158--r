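# Windowed dataset assembly: counts, alignment, manifest validation.

make_label_series <- function(T_dur, fs = 100, seed = 1) {
  set.seed(seed)
  n <- round(T_dur * fs)
  merged <- merge_and_mirror(runif(n), runif(n), fs = fs)
  s <- windowed_shift(merged)
  normalize_across_visits(list(v = s))$v
}

test_that("window counts follow the closed form", {
  lfp <- recording(matrix(rnorm(2 * 21100), 2), fs = 211)
  labels <- make_label_series(100)
  ds <- build_windowed_dataset(lfp, labels)
  expect_equal(length(ds), floor((100 - 5) / 0.1) + 1)  # 951
  expect_identical(dim(ds$x), c(2L, 1055L, 951L))
  expect_equal(ds$end_times[1], 5.0)
  expect_equal(diff(ds$end_times), rep(0.1, 950), tolerance = 1e-9)

  short_lfp <- recording(matrix(rnorm(2 * round(4.9 * 211)), 2), fs = 211)
  short_labels <- make_label_series(4.9)
  expect_warning(ds0 <- build_windowed_dataset(short_lfp, short_labels),
                 "shorter than one input window")
  expect_equal(length(ds0), 0L)
})

test_that("labels align with the shift window ending at the same time", {
  lfp <- recording(matrix(rnorm(2 * 2110), 2), fs = 211)
  labels <- make_label_series(10)
  ds <- build_windowed_dataset(lfp, labels)
  i <- which(abs(ds$end_times - 10.0) < 1e-9)
  j <- which(abs(labels$times - 10.0) < 1e-9)
  expect_equal(ds$y[i], labels$normalized_values[j])
  ## the LFP window is the recording's final 5 s (nearest-sample mapping)
  expect_equal(ds$x[, , i], lfp$data[, (2110 - 1055 + 1):2110])
  ## no window escapes the recording; all labels in [0, 1]
  expect_true(all(ds$y >= 0 & ds$y <= 1))
})

test_that("misaligned label grids are rejected", {
  lfp <- recording(matrix(rnorm(2 * 2110), 2), fs = 211, t0 = 0)
  labels <- make_label_series(10)
  labels$times <- labels$times + 0.037  # off the 0.1 s grid
  expect_error(build_windowed_dataset(lfp, labels), "misaligned")
})

test_that("manifest validation enforces roles and chronology", {
  visit <- function(label, mo, role) {
    list(visit_label = label, months_since_IP = mo, lfp_path = "x.csv",
         force_path = "y.csv", baseline_interval = c(1, 4), role = role)
  }
  ok <- list(visit("a", 6, "train"), visit("b", 9, "validation"),
             visit("c", 12, "test"))
  expect_s3_class(session_manifest("p1", ok), "session_manifest")

  bad_order <- list(visit("a", 6, "test"), visit("b", 9, "validation"),
                    visit("c", 12, "train"))
  expect_error(session_manifest("p1", bad_order), "chronological")

  dup <- list(visit("a", 6, "train"), visit("b", 9, "train"),
              visit("c", 12, "test"))
  expect_error(session_manifest("p1", dup), "more than one visit")

  missing <- list(visit("a", 6, "train"), visit("b", 9, "validation"))
  expect_error(session_manifest("p1", missing), "missing role")
})

test_that("assemble_splits is deterministic and reconstructs labels from force", {
  spec <- synthetic_spec(seed = 3L, duration_s = 20)
  dir <- withr::local_tempdir()
  man <- generate_participant(spec, out_dir = dir)
  s1 <- assemble_splits(man)
  s2 <- assemble_splits(man)
  expect_identical(s1$train$y, s2$train$y)
  expect_identical(s1$train$x, s2$train$x)
  expect_equal(length(s1$train), floor((20 - 5) / 0.1) + 1)

  ## labels reconstructed independently from the raw force file agree
  v <- lfpgait:::visit_by_role(man, "train")
  force <- read_recording(v$force_path)
  w <- estimate_body_weight(force, v$baseline_interval)
  shift <- force_to_shift(force, w)
  keep <- shift$times >= 5 - 1e-9
  expect_equal(s1$train$y, shift$raw_values[keep] / s1$normalizer,
               tolerance = 1e-12)

  ## subsampling keeps every n-th example
  s5 <- assemble_splits(man, subsample = 5L)
  expect_equal(s5$train$y, s1$train$y[seq(1, length(s1$train$y), by = 5)])
  expect_equal(length(s5$test), length(s1$test))  # test never subsampled
})
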