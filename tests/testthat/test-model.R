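# Architecture: variant factory, bias audit, block contracts, gradients.

test_that("variant names map to the right block flags", {
  expect_identical(variant_flags("full"),
                   list(use_div = TRUE, use_se = TRUE, use_bi = TRUE))
  expect_identical(variant_flags("FExt-Div+SE+Bi"),
                   list(use_div = FALSE, use_se = TRUE, use_bi = TRUE))
  expect_identical(variant_flags("FExt"),
                   list(use_div = TRUE, use_se = FALSE, use_bi = FALSE))
  expect_error(variant_flags("N2G"), "valid names")
})

test_that("config validation catches inconsistent geometry", {
  expect_error(tiny_cfg(n_filters_per_channel = 5L), "even")
  expect_error(tiny_cfg(n_filters_per_channel = 6L, se_reduction = 5L),
               "divisible")
  expect_error(tiny_cfg(conv_kernel_len = 99L), "exceed")
})

test_that("feature extraction output geometry and degenerate input", {
  m <- build_model("full", tiny_cfg())
  Tlen <- floor((40 - 10) / 5) + 1
  feats <- extract_features(m, matrix(0, 2, 40))
  expect_identical(dim(feats), c(8L, as.integer(Tlen)))
  expect_true(all(is.finite(feats)))
  ## zero input: constant across time (batch-norm shift only)
  expect_true(all(abs(feats - feats[, 1]) < 1e-12))
})

test_that("squared features are 2-homogeneous with batch norm bypassed", {
  m <- build_model("FExt", tiny_cfg())
  tt <- seq_len(40) / 211
  w1 <- rbind(sin(2 * pi * 20 * tt), cos(2 * pi * 20 * tt))
  f1 <- extract_features(m, w1, bn_bypass = TRUE, apply_div = FALSE)
  f2 <- extract_features(m, 2 * w1, bn_bypass = TRUE, apply_div = FALSE)
  expect_equal(f2, 4 * f1, tolerance = 1e-12)
  expect_true(all(f1 >= 0))  # squaring precedes pooling
})

test_that("relative division: worked example, scaling, zero denominators", {
  feats <- matrix(c(4, 9, 2, 3, 4, 9, 2, 3), ncol = 1)  # two leads of [num; den]
  out <- relative_division(feats, epsilon = 0)
  expect_equal(out[, 1], c(4, 9, 2, 3, 4, 9, 2, 3))

  set.seed(3)
  z <- matrix(runif(8 * 5, 0.5, 2), 8, 5)
  r1 <- relative_division(z, epsilon = 1e-9)
  r2 <- relative_division(10 * z, epsilon = 1e-9)
  ## relative half unchanged under joint scaling, original half scales
  expect_equal(r2[3:4, ], r1[3:4, ], tolerance = 1e-6)
  expect_equal(r2[7:8, ], r1[7:8, ], tolerance = 1e-6)
  expect_equal(r2[1:2, ], 10 * r1[1:2, ])

  zz <- z; zz[3:4, ] <- 0; zz[7:8, ] <- 0
  r0 <- relative_division(zz, epsilon = 1e-6)
  expect_true(all(is.finite(r0)))
  expect_equal(r0[3, ], zz[1, ] / 1e-6)

  expect_error(relative_division(matrix(1, 6, 2)), "even")
})

test_that("squeeze-and-excitation gates bound and share parameters over time", {
  m <- build_model("FExt+SE", tiny_cfg())
  set.seed(8)
  Z <- matrix(rnorm(8 * 6), 8, 6)
  Z[, 4] <- Z[, 2]  # duplicate time slice
  out <- lfpgait:::se_fwd(m$params, Z)
  expect_true(all(abs(out$Y) <= abs(Z) + 1e-15))  # gates in (0, 1)
  expect_equal(out$Y[, 4], out$Y[, 2])            # time-shared parameters
  z0 <- matrix(0, 8, 1)
  expect_equal(lfpgait:::se_fwd(m$params, z0)$Y, z0)  # 0 x gate = 0
})

test_that("BiLSTM output geometry and tied-weight time-reversal symmetry", {
  cfg <- tiny_cfg(lstm_hidden = 5L, lstm_layers = 1L)
  m <- build_model("full", cfg)
  B <- 2L; Tlen <- 7L
  set.seed(9)
  Z <- matrix(rnorm(8 * Tlen * B), 8, Tlen * B)
  f <- lfpgait:::lstm_dir_fwd(m$params$lstm1f_wx, m$params$lstm1f_wh, Z,
                              Tlen, B, reverse = FALSE)
  expect_identical(dim(f$H), c(5L, Tlen * B))

  ## with tied weights, the forward pass on time-reversed input reproduces
  ## the time-reverse of the backward pass on the original input
  rev_cols <- as.vector(sapply(rev(seq_len(Tlen)),
                               function(t) (t - 1) * B + seq_len(B)))
  Zrev <- Z[, rev_cols]
  fwd_on_rev <- lfpgait:::lstm_dir_fwd(m$params$lstm1f_wx, m$params$lstm1f_wh,
                                       Zrev, Tlen, B, reverse = FALSE)
  bwd_on_orig <- lfpgait:::lstm_dir_fwd(m$params$lstm1f_wx, m$params$lstm1f_wh,
                                        Z, Tlen, B, reverse = TRUE)
  expect_equal(fwd_on_rev$H[, rev_cols], bwd_on_orig$H, tolerance = 1e-12)

  ## constant-over-time input stays finite
  Zc <- matrix(rep(rnorm(8), Tlen * B), 8, Tlen * B)
  fc <- lfpgait:::lstm_dir_fwd(m$params$lstm1f_wx, m$params$lstm1f_wh, Zc,
                               Tlen, B, reverse = FALSE)
  expect_true(all(is.finite(fc$H)))
})

test_that("prediction is exactly the ReLU of the exposed preactivation", {
  m <- build_model("full", tiny_cfg())
  set.seed(10)
  x <- array(rnorm(2 * 40 * 200), c(2, 40, 200))
  out <- predict_model(m, x)
  expect_equal(out$pred, pmax(out$preact, 0))
  expect_true(all(out$pred >= 0))
  expect_true(any(out$preact < 0))  # both branches exercised
})

test_that("bias audit and parameter-count relations hold for all variants", {
  counts <- sapply(VALID_VARIANTS <- c("FExt", "FExt+SE", "FExt+Bi",
                                       "FExt+SE+Bi", "FExt-Div", "FExt-Div+SE",
                                       "FExt-Div+Bi", "FExt-Div+SE+Bi"),
                   function(v) {
    m <- build_model(v, tiny_cfg())
    sr <- m$structural_report
    expect_true(sr$bias_only_in_se, label = v)
    if (!m$config$use_se) expect_length(sr$bias_parameters, 0)
    sr$parameter_count
  })
  expect_gt(counts[["FExt+SE+Bi"]], counts[["FExt+SE"]])
  expect_gt(counts[["FExt+SE+Bi"]], counts[["FExt+Bi"]])
  ## division adds no parameters
  expect_equal(counts[["FExt"]], counts[["FExt-Div"]])
  expect_equal(counts[["FExt+SE+Bi"]], counts[["FExt-Div+SE+Bi"]])
})

test_that("forward pass is deterministic and batch-size invariant", {
  m1 <- build_model("full", tiny_cfg(seed = 77L))
  m2 <- build_model("full", tiny_cfg(seed = 77L))
  set.seed(4)
  x <- array(rnorm(2 * 40 * 10), c(2, 40, 10))
  expect_identical(predict_model(m1, x)$pred, predict_model(m2, x)$pred)

  p_all <- predict_model(m1, x, batch_size = 10)$pred
  p_one <- vapply(1:10, function(i)
    predict_model(m1, x[, , i, drop = FALSE], batch_size = 1)$pred, 0)
  expect_equal(p_all, p_one, tolerance = 1e-5)
})

test_that("analytic gradients match finite differences in every variant", {
  set.seed(7)
  B <- 3L
  x <- array(rnorm(2 * 40 * B), c(2, 40, B))
  w <- rnorm(B)  # gradient of sum(w * preact): smooth, avoids ReLU kinks
  for (v in c("FExt+SE+Bi", "FExt", "FExt-Div+SE", "FExt+Bi")) {
    m <- build_model(v, tiny_cfg())
    out <- model_forward(m, x, train = TRUE, want_cache = TRUE)
    grads <- model_backward(m, out$cache, w)
    loss_fn <- function(model) {
      sum(w * model_forward(model, x, train = TRUE)$preact)
    }
    set.seed(12)
    for (nm in names(m$params)) {
      for (ii in sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))) {
        h <- 1e-6
        mp <- m; mp$params[[nm]][ii] <- mp$params[[nm]][ii] + h
        mm <- m; mm$params[[nm]][ii] <- mm$params[[nm]][ii] - h
        g_fd <- (loss_fn(mp) - loss_fn(mm)) / (2 * h)
        g_an <- grads[[nm]][ii]
        expect_lt(abs(g_fd - g_an) / max(abs(g_fd), abs(g_an), 1e-6), 1e-4,
                  label = sprintf("%s / %s[%d]", v, nm, ii))
      }
    }
  }
})

test_that("one small ADAM step does not increase the loss on an example", {
  m <- build_model("full", tiny_cfg())
  set.seed(21)
  x <- array(rnorm(2 * 40 * 1), c(2, 40, 1))
  y <- 0.8
  loss_of <- function(model) {
    abs(model_forward(model, x, train = TRUE)$pred - y)
  }
  out <- model_forward(m, x, train = TRUE, want_cache = TRUE)
  l0 <- abs(out$pred - y)
  dpre <- sign(out$pred - y) * (out$preact > 0)
  grads <- model_backward(m, out$cache, dpre)
  st <- lfpgait:::adam_step(m$params, grads, lfpgait:::adam_init(m$params), 1e-5)
  m$params <- st$params
  expect_lte(loss_of(m), l0 + 1e-8)
})
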