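## Model definition: a four-block regression network mapping a 5 s,
## two-lead LFP window to a single nonnegative weight-shift prediction.
##   1. feature extraction: depthwise 1-D conv -> batch norm -> square ->
##      average pool (imitating band-power computation), optionally followed
##      by element-wise division into relative features;
##   2. temporal squeeze-and-excitation gating (parameters shared over time);
##   3. 3-layer bidirectional LSTM;
##   4. regression head: groupwise temporal conv (forward/backward groups) ->
##      pointwise conv -> global temporal average -> dense -> ReLU.
## Only the SE block carries bias parameters.

VALID_VARIANTS <- c("FExt", "FExt+SE", "FExt+Bi", "FExt+SE+Bi",
                    "FExt-Div", "FExt-Div+SE", "FExt-Div+Bi", "FExt-Div+SE+Bi")

#' Map an ablation-variant name to block flags
#'
#' Naming convention: `FExt` is the feature-extraction block including the
#' element-wise division; the `-Div` suffix removes the division; `+SE` and
#' `+Bi` add the squeeze-and-excitation and bidirectional LSTM blocks. The
#' complete model is `"FExt+SE+Bi"` (alias `"full"`).
#'
#' @param name one of `r paste(VALID_VARIANTS, collapse = ", ")` or
#'   `"full"`.
#' @return list with logicals `use_div`, `use_se`, `use_bi`.
#' @export
variant_flags <- function(name) {
  if (identical(name, "full")) name <- "FExt+SE+Bi"
  if (!name %in% VALID_VARIANTS) {
    stop(sprintf("unknown variant '%s'; valid names: %s (or 'full')",
                 name, paste(VALID_VARIANTS, collapse = ", ")))
  }
  list(use_div = !grepl("-Div", name, fixed = TRUE),
       use_se = grepl("+SE", name, fixed = TRUE),
       use_bi = grepl("+Bi", name, fixed = TRUE))
}

#' Model hyperparameter configuration
#'
#' Defaults give a post-pooling frame rate of ~19 Hz over a 1055-sample
#' (5 s at 211 Hz) window, enough temporal resolution for beta-burst-scale
#' dynamics.
#'
#' @param use_div,use_se,use_bi block flags (see [variant_flags()]).
#' @param n_filters_per_channel conv filters per lead (default 32; must be
#'   even when `use_div`).
#' @param conv_kernel_len conv kernel length in samples (default 63).
#' @param pool_len,pool_stride average-pooling geometry (defaults 53 / 11).
#' @param se_reduction SE bottleneck reduction ratio (default 4).
#' @param lstm_hidden LSTM units per direction (default 64).
#' @param lstm_layers stacked BiLSTM layers (default 3).
#' @param division_epsilon stabilizer added to division denominators.
#' @param input_len window length in samples (default 1055 = 5 s at 211 Hz).
#' @param head_kernel_len groupwise head conv kernel (default 5).
#' @param head_channels_per_group head conv output channels per group.
#' @param head_merge_channels pointwise merge channels before the dense
#'   output.
#' @param seed integer seed for parameter initialization.
#' @return a `"model_config"` list.
#' @export
model_config <- function(use_div = TRUE, use_se = TRUE, use_bi = TRUE,
                         n_filters_per_channel = 32L, conv_kernel_len = 63L,
                         pool_len = 53L, pool_stride = 11L, se_reduction = 4L,
                         lstm_hidden = 64L, lstm_layers = 3L,
                         division_epsilon = 1e-6, input_len = 1055L,
                         head_kernel_len = 5L, head_channels_per_group = 16L,
                         head_merge_channels = 16L, seed = 1L) {
  cfg <- list(use_div = use_div, use_se = use_se, use_bi = use_bi,
              n_filters_per_channel = as.integer(n_filters_per_channel),
              conv_kernel_len = as.integer(conv_kernel_len),
              pool_len = as.integer(pool_len),
              pool_stride = as.integer(pool_stride),
              se_reduction = as.integer(se_reduction),
              lstm_hidden = as.integer(lstm_hidden),
              lstm_layers = as.integer(lstm_layers),
              division_epsilon = division_epsilon,
              input_len = as.integer(input_len),
              head_kernel_len = as.integer(head_kernel_len),
              head_channels_per_group = as.integer(head_channels_per_group),
              head_merge_channels = as.integer(head_merge_channels),
              seed = as.integer(seed))
  if (cfg$use_div && cfg$n_filters_per_channel %% 2L != 0L) {
    stop("n_filters_per_channel must be even when use_div is TRUE")
  }
  stopifnot(cfg$n_filters_per_channel > 0, cfg$conv_kernel_len > 0,
            cfg$pool_len > 0, cfg$pool_stride > 0, cfg$lstm_hidden > 0,
            cfg$lstm_layers > 0, cfg$division_epsilon > 0)
  if (cfg$conv_kernel_len > cfg$input_len || cfg$pool_len > cfg$input_len) {
    stop("kernel/pool lengths must not exceed the input window length")
  }
  D <- 2L * cfg$n_filters_per_channel
  if (cfg$use_se && D %% cfg$se_reduction != 0L) {
    stop("feature dimension must be divisible by se_reduction")
  }
  class(cfg) <- "model_config"
  cfg
}

n_time_steps <- function(cfg) {
  floor((cfg$input_len - cfg$pool_len) / cfg$pool_stride) + 1L
}

init_params <- function(cfg) {
  set.seed(cfg$seed)
  Fn <- cfg$n_filters_per_channel
  K <- cfg$conv_kernel_len
  D <- 2L * Fn
  H <- cfg$lstm_hidden
  p <- list(
    conv_w1 = matrix(stats::rnorm(Fn * K, sd = sqrt(2 / K)), Fn, K),
    conv_w2 = matrix(stats::rnorm(Fn * K, sd = sqrt(2 / K)), Fn, K),
    bn_gamma = rep(1, D)
  )
  if (cfg$use_se) {
    Dr <- D %/% cfg$se_reduction
    lim1 <- sqrt(1 / D); lim2 <- sqrt(1 / Dr)
    p$se_w1 <- matrix(stats::runif(Dr * D, -lim1, lim1), Dr, D)
    p$se_b1 <- rep(0, Dr)
    p$se_w2 <- matrix(stats::runif(D * Dr, -lim2, lim2), D, Dr)
    p$se_b2 <- rep(0, D)
  }
  if (cfg$use_bi) {
    lim <- sqrt(1 / H)
    din <- D
    for (l in seq_len(cfg$lstm_layers)) {
      for (d in c("f", "b")) {
        p[[sprintf("lstm%d%s_wx", l, d)]] <-
          matrix(stats::runif(4L * H * din, -lim, lim), 4L * H, din)
        p[[sprintf("lstm%d%s_wh", l, d)]] <-
          matrix(stats::runif(4L * H * H, -lim, lim), 4L * H, H)
      }
      din <- 2L * H
    }
  }
  G <- if (cfg$use_bi) 2L else 1L
  Cin <- if (cfg$use_bi) 2L * H else D
  Cin_g <- Cin %/% G
  Cg <- cfg$head_channels_per_group
  Cm <- cfg$head_merge_channels
  k <- cfg$head_kernel_len
  limg <- sqrt(1 / (Cin_g * k))
  for (g in seq_len(G)) {
    p[[sprintf("head_gw%d", g)]] <-
      matrix(stats::runif(Cg * Cin_g * k, -limg, limg), Cg, Cin_g * k)
  }
  limp <- sqrt(1 / (G * Cg))
  p$head_pw <- matrix(stats::runif(Cm * G * Cg, -limp, limp), Cm, G * Cg)
  p$head_dense <- matrix(stats::runif(Cm, -sqrt(1 / Cm), sqrt(1 / Cm)), 1L, Cm)
  p
}

#' Build a model (the complete network or an ablation variant)
#'
#' @param variant variant name (see [variant_flags()]); ignored when an
#'   explicit `config` already carries the block flags and
#'   `use_config_flags = TRUE`.
#' @param config a [model_config()]; its flags are overwritten by `variant`
#'   unless `use_config_flags`.
#' @param use_config_flags take `use_div/use_se/use_bi` from `config`
#'   instead of `variant`.
#' @return a `"model_handle"`: list with `config`, `params` (named list of
#'   weight arrays), `buffers` (batch-norm running statistics) and
#'   `structural_report` (block presence, bias audit, parameter count).
#' @export
build_model <- function(variant = "full", config = model_config(),
                        use_config_flags = FALSE) {
  if (!use_config_flags) {
    fl <- variant_flags(variant)
    config$use_div <- fl$use_div
    config$use_se <- fl$use_se
    config$use_bi <- fl$use_bi
    config <- do.call(model_config, unclass(config))
  }
  params <- init_params(config)
  D <- 2L * config$n_filters_per_channel
  buffers <- list(bn_mean = rep(0, D), bn_var = rep(1, D))
  m <- structure(list(config = config, params = params, buffers = buffers,
                      variant = if (use_config_flags) NA_character_ else variant),
                 class = "model_handle")
  m$structural_report <- structural_report(m)
  m
}

#' Structural report: blocks, bias audit, parameter count
#' @param model a `"model_handle"`.
#' @return list with `blocks`, `bias_parameters` (names of all bias-like
#'   parameters), `bias_only_in_se` (logical), `parameter_count`.
#' @export
structural_report <- function(model) {
  bias_names <- grep("_b[0-9]*$", names(model$params), value = TRUE)
  list(
    blocks = list(feature_extraction = TRUE, division = model$config$use_div,
                  squeeze_excitation = model$config$use_se,
                  bilstm = model$config$use_bi, regression_head = TRUE),
    bias_parameters = bias_names,
    bias_only_in_se = all(grepl("^se_", bias_names)),
    parameter_count = parameter_count(model)
  )
}

#' Total number of trainable parameters
#' @param model a `"model_handle"`.
#' @return integer count.
#' @export
parameter_count <- function(model) {
  sum(vapply(model$params, length, 0L))
}

#' @export
print.model_handle <- function(x, ...) {
  fl <- x$config
  cat(sprintf("<model_handle> div=%s se=%s bi=%s, %d parameters\n",
              fl$use_div, fl$use_se, fl$use_bi, parameter_count(x)))
  invisible(x)
}

## ---- forward / backward ---------------------------------------------------

#' Forward pass
#'
#' @param model a `"model_handle"`.
#' @param x input array `(2, input_len, B)` or matrix `2 x input_len` for a
#'   single window.
#' @param train use batch statistics in batch norm and update running
#'   statistics (training mode); otherwise running statistics are used.
#' @param want_cache keep intermediate activations for [model_backward()].
#' @param bn_bypass skip batch normalization entirely (test instrumentation
#'   for scale-homogeneity checks).
#' @return list with `pred` (length-B, `= pmax(preact, 0)`), `preact`,
#'   `model` (with updated batch-norm buffers when `train`), and `cache`.
#' @export
model_forward <- function(model, x, train = FALSE, want_cache = FALSE,
                          bn_bypass = FALSE) {
  cfg <- model$config
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L, dim(x)[1] == 2L,
            dim(x)[2] == cfg$input_len)
  B <- dim(x)[3]
  L <- cfg$input_len
  Fn <- cfg$n_filters_per_channel
  Tlen <- n_time_steps(cfg)
  cache <- list(B = B, Tlen = Tlen, bn_bypass = bn_bypass)

  cv <- conv_depthwise_fwd(model$params, x, keep = want_cache)
  A <- cv$A
  if (bn_bypass) {
    bn <- list(Y = A, train = FALSE)
  } else {
    bn <- bn_fwd(A, model$params$bn_gamma, model$buffers, train,
                 keep = want_cache)
    model$buffers <- bn$buffers
  }
  S <- bn$Y * bn$Y
  PB <- pool_matrix(L, cfg$pool_len, cfg$pool_stride, B)
  P0 <- as.matrix(S %*% PB)

  if (cfg$use_div) {
    dv <- div_fwd(P0, Fn, cfg$division_epsilon)
    Z <- dv$Y
  } else {
    dv <- NULL
    Z <- P0
  }
  if (cfg$use_se) {
    se <- se_fwd(model$params, Z, keep = want_cache)
    Zs <- se$Y
  } else {
    se <- NULL
    Zs <- Z
  }
  lstm_caches <- NULL
  if (cfg$use_bi) {
    inp <- Zs
    lstm_caches <- vector("list", cfg$lstm_layers)
    for (l in seq_len(cfg$lstm_layers)) {
      cf <- lstm_dir_fwd(model$params[[sprintf("lstm%df_wx", l)]],
                         model$params[[sprintf("lstm%df_wh", l)]],
                         inp, Tlen, B, reverse = FALSE, keep = want_cache)
      cb <- lstm_dir_fwd(model$params[[sprintf("lstm%db_wx", l)]],
                         model$params[[sprintf("lstm%db_wh", l)]],
                         inp, Tlen, B, reverse = TRUE, keep = want_cache)
      lstm_caches[[l]] <- list(f = cf, b = cb, input = inp)
      inp <- rbind(cf$H, cb$H)
    }
    M <- inp
  } else {
    M <- Zs
  }

  G <- if (cfg$use_bi) 2L else 1L
  Cin_g <- nrow(M) %/% G
  k <- cfg$head_kernel_len
  Sgs <- vector("list", G)
  Ys <- vector("list", G)
  for (g in seq_len(G)) {
    Mg <- M[(g - 1L) * Cin_g + seq_len(Cin_g), , drop = FALSE]
    Sgs[[g]] <- head_im2col(Mg, k, Tlen, B)
    Ys[[g]] <- model$params[[sprintf("head_gw%d", g)]] %*% Sgs[[g]]
  }
  Ycat <- do.call(rbind, Ys)
  Pm <- model$params$head_pw %*% Ycat
  AV <- avg_matrix(Tlen, B)
  avg <- as.matrix(Pm %*% AV)
  preact <- as.numeric(model$params$head_dense %*% avg)
  pred <- pmax(preact, 0)

  if (want_cache) {
    cache$conv <- cv; cache$bn <- bn; cache$bn_Y <- bn$Y; cache$PB <- PB
    cache$div <- dv; cache$se <- se; cache$Z_pre_se <- Z
    cache$lstm <- lstm_caches; cache$M <- M
    cache$Sgs <- Sgs; cache$Ycat <- Ycat; cache$avg <- avg
    cache$AV <- AV; cache$G <- G; cache$Cin_g <- Cin_g
  }
  list(pred = pred, preact = preact, model = model,
       cache = if (want_cache) cache else NULL)
}

#' Backward pass: gradients of a scalar loss w.r.t. all parameters
#'
#' @param model a `"model_handle"`.
#' @param cache the cache from [model_forward()] (`want_cache = TRUE`,
#'   same mode).
#' @param dpreact length-B gradient of the loss w.r.t. the pre-ReLU output.
#' @return named list of gradients matching `model$params`.
#' @export
model_backward <- function(model, cache, dpreact) {
  cfg <- model$config
  B <- cache$B; Tlen <- cache$Tlen
  Fn <- cfg$n_filters_per_channel
  grads <- list()

  dpre <- matrix(dpreact, 1L, B)
  grads$head_dense <- tcrossprod(dpre, cache$avg)
  davg <- crossprod(model$params$head_dense, dpre)
  dPm <- as.matrix(Matrix::tcrossprod(davg, cache$AV))
  grads$head_pw <- tcrossprod(dPm, cache$Ycat)
  dYcat <- crossprod(model$params$head_pw, dPm)
  G <- cache$G; Cin_g <- cache$Cin_g
  Cg <- cfg$head_channels_per_group
  k <- cfg$head_kernel_len
  dM <- matrix(0, Cin_g * G, Tlen * B)
  for (g in seq_len(G)) {
    dYg <- dYcat[(g - 1L) * Cg + seq_len(Cg), , drop = FALSE]
    grads[[sprintf("head_gw%d", g)]] <- tcrossprod(dYg, cache$Sgs[[g]])
    dSg <- crossprod(model$params[[sprintf("head_gw%d", g)]], dYg)
    dM[(g - 1L) * Cin_g + seq_len(Cin_g), ] <-
      head_im2col_bwd(dSg, Cin_g, k, Tlen, B)
  }

  if (cfg$use_bi) {
    H <- cfg$lstm_hidden
    dOut <- dM
    for (l in rev(seq_len(cfg$lstm_layers))) {
      lc <- cache$lstm[[l]]
      bf <- lstm_dir_bwd(model$params[[sprintf("lstm%df_wx", l)]],
                         model$params[[sprintf("lstm%df_wh", l)]],
                         lc$input, dOut[seq_len(H), , drop = FALSE], lc$f)
      bb <- lstm_dir_bwd(model$params[[sprintf("lstm%db_wx", l)]],
                         model$params[[sprintf("lstm%db_wh", l)]],
                         lc$input, dOut[H + seq_len(H), , drop = FALSE], lc$b)
      grads[[sprintf("lstm%df_wx", l)]] <- bf$dwx
      grads[[sprintf("lstm%df_wh", l)]] <- bf$dwh
      grads[[sprintf("lstm%db_wx", l)]] <- bb$dwx
      grads[[sprintf("lstm%db_wh", l)]] <- bb$dwh
      dOut <- bf$dZ + bb$dZ
    }
    dZs <- dOut
  } else {
    dZs <- dM
  }

  if (cfg$use_se) {
    sb <- se_bwd(model$params, dZs, cache$se)
    grads$se_w1 <- sb$se_w1; grads$se_b1 <- sb$se_b1
    grads$se_w2 <- sb$se_w2; grads$se_b2 <- sb$se_b2
    dZ <- sb$dZ
  } else {
    dZ <- dZs
  }

  dP0 <- if (cfg$use_div) div_bwd(dZ, cache$div) else dZ
  dS <- as.matrix(Matrix::tcrossprod(dP0, cache$PB))
  dBnY <- 2 * cache$bn_Y * dS
  if (cache$bn_bypass) {
    dA <- dBnY
    grads$bn_gamma <- rep(0, length(model$params$bn_gamma))
  } else {
    bb <- bn_bwd(dBnY, cache$bn, model$params$bn_gamma)
    dA <- bb$dX
    grads$bn_gamma <- bb$bn_gamma
  }
  grads <- c(grads, conv_depthwise_bwd(dA, cache$conv, Fn))
  grads[names(model$params)]
}

#' Batched evaluation-mode prediction
#'
#' @param model a `"model_handle"`.
#' @param x input array `(2, input_len, N)`.
#' @param batch_size forward batch size (predictions are batch-size
#'   invariant in evaluation mode).
#' @return list with `pred` and `preact`, each length N.
#' @export
predict_model <- function(model, x, batch_size = 64L) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  N <- dim(x)[3]
  pred <- numeric(N); preact <- numeric(N)
  i <- 1L
  while (i <= N) {
    j <- min(i + batch_size - 1L, N)
    out <- model_forward(model, x[, , i:j, drop = FALSE], train = FALSE)
    pred[i:j] <- out$pred
    preact[i:j] <- out$preact
    i <- j + 1L
  }
  list(pred = pred, preact = preact)
}

#' Feature-extraction block output (exposed for inspection and tests)
#'
#' Runs conv -> batch norm -> square -> average pool (and division when
#' enabled) for a single window.
#'
#' @param model a `"model_handle"`.
#' @param window matrix `2 x input_len`.
#' @param bn_bypass skip batch normalization (test mode).
#' @param apply_div apply the division stage when the model has it.
#' @return feature matrix `(2 * n_filters_per_channel) x n_time_steps`.
#' @export
extract_features <- function(model, window, bn_bypass = FALSE,
                             apply_div = model$config$use_div) {
  cfg <- model$config
  stopifnot(is.matrix(window), nrow(window) == 2L, ncol(window) == cfg$input_len)
  x <- array(window, c(2L, cfg$input_len, 1L))
  cv <- conv_depthwise_fwd(model$params, x)
  A <- cv$A
  Y <- if (bn_bypass) A else bn_fwd(A, model$params$bn_gamma, model$buffers,
                                    train = FALSE)$Y
  S <- Y * Y
  P0 <- as.matrix(S %*% pool_matrix(cfg$input_len, cfg$pool_len,
                                    cfg$pool_stride, 1L))
  if (apply_div) div_fwd(P0, cfg$n_filters_per_channel,
                         cfg$division_epsilon)$Y else P0
}

#' Relative-feature division on an explicit feature matrix
#'
#' Splits each lead's feature rows into numerator and denominator halves and
#' returns `[numerators; numerators / (denominators + epsilon)]` (same total
#' feature count; denominators are not emitted as standalone features).
#'
#' @param features matrix, `2 * F` rows (lead 1 block then lead 2 block).
#' @param epsilon stabilizer (default 1e-6).
#' @return matrix of the same shape.
#' @export
relative_division <- function(features, epsilon = 1e-6) {
  Fn <- nrow(features) %/% 2L
  if (nrow(features) %% 2L != 0L || Fn %% 2L != 0L) {
    stop("per-lead feature count must be even for the division split")
  }
  div_fwd(features, Fn, epsilon)$Y
}
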