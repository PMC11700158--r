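## Neural-network internals: vectorized forward/backward passes for every
## block, written against BLAS-backed matrix products. No deep-learning
## framework is used; gradients are derived by hand and verified by
## finite-difference tests.
##
## Layout conventions:
##   * batch input    : array (2 leads, L samples, B examples)
##   * pre-pool maps  : matrix (features x (L * B)), EXAMPLE-major columns,
##                      column index (b - 1) * L + t  (natural im2col order)
##   * post-pool maps : matrix (features x (Tlen * B)), TIME-major columns,
##                      column index (t - 1) * B + b, so each LSTM time step
##                      and each temporal shift is a contiguous column block.
## All layers are bias-free except the squeeze-and-excitation block.

sigm <- function(x) 1 / (1 + exp(-x))

## cache of structural objects (pooling/averaging matrices, gather indices)
.mat_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  v <- .mat_cache[[key]]
  if (is.null(v)) {
    v <- builder()
    .mat_cache[[key]] <- v
  }
  v
}

## sparse average-pooling operator, example-major input columns ->
## time-major output columns
pool_matrix <- function(L, pool_len, pool_stride, B) {
  cache_get(paste("pool", L, pool_len, pool_stride, B, sep = "_"), function() {
    Tlen <- floor((L - pool_len) / pool_stride) + 1L
    starts <- (seq_len(Tlen) - 1L) * pool_stride + 1L
    ## rows: input sample t of example b at (b-1)*L + t
    ## cols: output step t of example b at (t-1)*B + b
    i <- integer(0); j <- integer(0)
    off <- 0:(pool_len - 1L)
    for (b in seq_len(B)) {
      i <- c(i, as.vector(outer(off, starts + (b - 1L) * L, `+`)))
      j <- c(j, rep((seq_len(Tlen) - 1L) * B + b, each = pool_len))
    }
    Matrix::sparseMatrix(i = i, j = j, x = 1 / pool_len,
                         dims = c(L * B, Tlen * B))
  })
}

## time-major global temporal average: (Tlen*B) columns -> B columns
avg_matrix <- function(Tlen, B) {
  cache_get(paste("avg", Tlen, B, sep = "_"), function() {
    Matrix::sparseMatrix(i = seq_len(Tlen * B),
                         j = rep(seq_len(B), times = Tlen),
                         x = 1 / Tlen, dims = c(Tlen * B, B))
  })
}

## ---- depthwise 1-D convolution (same padding, cross-correlation) ---------

im2col_idx <- function(L, K, B) {
  cache_get(paste("im2col", L, K, B, sep = "_"), function() {
    pad <- (K - 1L) %/% 2L
    Lp <- L + K - 1L
    ## element (k, (b-1)*L + t) of the im2col matrix reads padded sample
    ## row t + k - 1 of example b
    k <- rep.int(seq_len(K), L * B)
    bt <- rep(seq_len(L * B) - 1L, each = K)
    b <- bt %/% L
    t <- bt %% L + 1L
    b * Lp + t + k - 1L
  })
}

im2col_1d <- function(X, K) {
  ## X: L x B (time x batch); returns K x (L*B), zero-padded at the edges
  L <- nrow(X); B <- ncol(X)
  pad <- (K - 1L) %/% 2L
  Xp <- rbind(matrix(0, pad, B), X, matrix(0, K - 1L - pad, B))
  matrix(Xp[im2col_idx(L, K, B)], K, L * B)
}

conv_depthwise_fwd <- function(params, x, keep = TRUE) {
  ## x: (2, L, B); output: (2F) x (L*B) example-major, lead-1 features first
  L <- dim(x)[2]; B <- dim(x)[3]
  K <- ncol(params$conv_w1)
  C1 <- im2col_1d(matrix(x[1, , ], L, B), K)
  C2 <- im2col_1d(matrix(x[2, , ], L, B), K)
  A <- rbind(params$conv_w1 %*% C1, params$conv_w2 %*% C2)
  if (keep) list(A = A, C1 = C1, C2 = C2) else list(A = A)
}

conv_depthwise_bwd <- function(dA, cache, Fn) {
  ## dA: (2F) x (L*B). Input gradients are not needed (first layer).
  list(conv_w1 = tcrossprod(dA[seq_len(Fn), , drop = FALSE], cache$C1),
       conv_w2 = tcrossprod(dA[Fn + seq_len(Fn), , drop = FALSE], cache$C2))
}

## ---- batch normalization (scale gamma, no shift: bias-free contract) -----

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_fwd <- function(A, gamma, buffers, train, keep = TRUE) {
  if (train) {
    mu <- rowMeans(A)
    v <- pmax(rowMeans(A * A) - mu^2, 0)
    N <- ncol(A)
    unb <- if (N > 1) N / (N - 1) else 1
    buffers$bn_mean <- (1 - BN_MOMENTUM) * buffers$bn_mean + BN_MOMENTUM * mu
    buffers$bn_var <- (1 - BN_MOMENTUM) * buffers$bn_var + BN_MOMENTUM * v * unb
  } else {
    mu <- buffers$bn_mean
    v <- buffers$bn_var
  }
  istd <- 1 / sqrt(v + BN_EPS)
  xhat <- (A - mu) * istd
  out <- list(Y = gamma * xhat, buffers = buffers, train = train)
  if (keep) {
    out$xhat <- xhat
    out$istd <- istd
  }
  out
}

bn_bwd <- function(dY, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- rowSums(dY * xhat)
  dxhat <- dY * gamma
  if (cache$train) {
    N <- ncol(dY)
    dx <- (cache$istd / N) *
      (N * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  } else {
    dx <- dxhat * cache$istd
  }
  list(dX = dx, bn_gamma = dgamma)
}

## ---- element-wise division: relative oscillatory features ----------------

div_fwd <- function(Z, Fn, eps) {
  ## per lead block of Fn rows: first half numerators, second half
  ## denominators; output = [numerators; numerator/(denominator + eps)]
  half <- Fn %/% 2L
  out <- Z
  idx <- list()
  for (lead in 1:2) {
    r0 <- (lead - 1L) * Fn
    num <- Z[r0 + seq_len(half), , drop = FALSE]
    den <- Z[r0 + half + seq_len(half), , drop = FALSE]
    out[r0 + half + seq_len(half), ] <- num / (den + eps)
    idx[[lead]] <- list(num = r0 + seq_len(half), den = r0 + half + seq_len(half))
  }
  list(Y = out, Z = Z, idx = idx, eps = eps)
}

div_bwd <- function(dY, cache) {
  Z <- cache$Z
  dZ <- dY  # numerator rows pass through; denominator rows overwritten below
  for (lead in 1:2) {
    ni <- cache$idx[[lead]]$num
    di <- cache$idx[[lead]]$den
    num <- Z[ni, , drop = FALSE]
    den_eps <- Z[di, , drop = FALSE] + cache$eps
    drel <- dY[di, , drop = FALSE]
    dZ[ni, ] <- dY[ni, , drop = FALSE] + drel / den_eps
    dZ[di, ] <- -drel * num / (den_eps * den_eps)
  }
  dZ
}

## ---- squeeze-and-excitation (the only biased block) ----------------------

se_fwd <- function(params, Z, keep = TRUE) {
  pre1 <- params$se_w1 %*% Z + params$se_b1
  h <- pre1 * (pre1 > 0)
  u <- params$se_w2 %*% h + params$se_b2
  g <- sigm(u)
  out <- list(Y = g * Z)
  if (keep) {
    out$Z <- Z; out$h <- h; out$mask <- pre1 > 0; out$g <- g
  }
  out
}

se_bwd <- function(params, dY, cache) {
  Z <- cache$Z; g <- cache$g; h <- cache$h
  dZ <- dY * g
  du <- (dY * Z) * g * (1 - g)
  dW2 <- tcrossprod(du, h)
  db2 <- rowSums(du)
  dh <- crossprod(params$se_w2, du) * cache$mask
  dW1 <- tcrossprod(dh, Z)
  db1 <- rowSums(dh)
  dZ <- dZ + crossprod(params$se_w1, dh)
  list(dZ = dZ, se_w1 = dW1, se_b1 = db1, se_w2 = dW2, se_b2 = db2)
}

## ---- LSTM (bias-free), time-major activations -----------------------------

lstm_dir_fwd <- function(wx, wh, Z, Tlen, B, reverse, keep = TRUE) {
  ## Z: Din x (Tlen*B) time-major; returns hidden H x (Tlen*B) time-major
  H <- nrow(wh) %/% 4L
  GX <- wx %*% Z
  ord <- if (reverse) rev(seq_len(Tlen)) else seq_len(Tlen)
  h <- matrix(0, H, B); c <- matrix(0, H, B)
  hs <- array(0, c(H, B, Tlen))
  if (keep) {
    ig <- array(0, c(H, B, Tlen)); fg <- ig; gg <- ig; og <- ig
    cs <- ig; tc <- ig
  }
  ri <- seq_len(H); rf <- H + ri; rg <- 2L * H + ri; ro <- 3L * H + ri
  for (t in ord) {
    cols <- ((t - 1L) * B + 1L):(t * B)
    a <- GX[, cols, drop = FALSE] + wh %*% h
    i_t <- sigm(a[ri, , drop = FALSE])
    f_t <- sigm(a[rf, , drop = FALSE])
    g_t <- tanh(a[rg, , drop = FALSE])
    o_t <- sigm(a[ro, , drop = FALSE])
    c <- f_t * c + i_t * g_t
    tct <- tanh(c)
    h <- o_t * tct
    hs[, , t] <- h
    if (keep) {
      ig[, , t] <- i_t; fg[, , t] <- f_t; gg[, , t] <- g_t; og[, , t] <- o_t
      cs[, , t] <- c; tc[, , t] <- tct
    }
  }
  out <- list(H = matrix(hs, H, Tlen * B), ord = ord, Tlen = Tlen, B = B)
  if (keep) {
    out$ig <- ig; out$fg <- fg; out$gg <- gg; out$og <- og
    out$cs <- cs; out$tc <- tc; out$hs <- hs
  }
  out
}

lstm_dir_bwd <- function(wx, wh, Z, dH, cache) {
  Tlen <- cache$Tlen; B <- cache$B
  H <- nrow(wh) %/% 4L
  ord <- cache$ord
  dh_next <- matrix(0, H, B); dc_next <- matrix(0, H, B)
  dAfull <- matrix(0, 4L * H, Tlen * B)
  Hprev <- array(0, c(H, B, Tlen))  # processing-order predecessor states
  zero <- matrix(0, H, B)
  for (k in rev(seq_along(ord))) {
    t <- ord[k]
    cols <- ((t - 1L) * B + 1L):(t * B)
    i_t <- cache$ig[, , t]; f_t <- cache$fg[, , t]; g_t <- cache$gg[, , t]
    o_t <- cache$og[, , t]; tct <- cache$tc[, , t]
    c_prev <- if (k > 1L) cache$cs[, , ord[k - 1L]] else zero
    h_prev <- if (k > 1L) cache$hs[, , ord[k - 1L]] else zero
    dh <- dH[, cols, drop = FALSE] + dh_next
    do_ <- dh * tct
    dc <- dh * o_t * (1 - tct * tct) + dc_next
    dAfull[, cols] <- rbind((dc * g_t) * i_t * (1 - i_t),
                            (dc * c_prev) * f_t * (1 - f_t),
                            (dc * i_t) * (1 - g_t * g_t),
                            do_ * o_t * (1 - o_t))
    Hprev[, , t] <- h_prev
    dc_next <- dc * f_t
    dh_next <- crossprod(wh, dAfull[, cols, drop = FALSE])
  }
  list(dwx = tcrossprod(dAfull, Z),
       dwh = tcrossprod(dAfull, matrix(Hprev, H, Tlen * B)),
       dZ = crossprod(wx, dAfull))
}

## ---- temporal shift / im2col for the groupwise head conv (time-major) ----

shift_cols <- function(M, s, Tlen, B) {
  ## shift each example's time axis by s steps (zero fill); time-major
  ## layout makes this a single contiguous block copy
  if (s == 0L) return(M)
  out <- matrix(0, nrow(M), ncol(M))
  t0 <- max(1L, 1L - s); t1 <- min(Tlen, Tlen - s)
  if (t0 > t1) return(out)
  out[, ((t0 - 1L) * B + 1L):(t1 * B)] <-
    M[, ((t0 + s - 1L) * B + 1L):((t1 + s) * B)]
  out
}

head_im2col <- function(M, k, Tlen, B) {
  ## stack k temporally shifted copies: (nrow(M)*k) x (Tlen*B)
  pad <- (k - 1L) %/% 2L
  nr <- nrow(M)
  S <- matrix(0, nr * k, ncol(M))
  for (o in seq_len(k)) {
    S[(o - 1L) * nr + seq_len(nr), ] <- shift_cols(M, o - 1L - pad, Tlen, B)
  }
  S
}

head_im2col_bwd <- function(dS, nr, k, Tlen, B) {
  pad <- (k - 1L) %/% 2L
  dM <- matrix(0, nr, ncol(dS))
  for (o in seq_len(k)) {
    s <- o - 1L - pad
    dM <- dM + shift_cols(dS[(o - 1L) * nr + seq_len(nr), , drop = FALSE],
                          -s, Tlen, B)
  }
  dM
}
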