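## Subject-dependent training: ADAM on shuffled minibatches with L1 loss,
## per-epoch validation, early stopping on stalled validation loss, and
## selection of the best-validation-epoch parameters.

#' Training configuration
#'
#' Defaults follow the reference protocol: ADAM with learning rate 1e-5,
#' batch size 16, up to 2000 epochs, early stopping after 100 epochs without
#' a strictly better validation L1. The `fast` profile is a CI/acceptance
#' device for 1-CPU runs: lr 1e-3, 30 epochs, patience 10 (see the methods
#' vignette for why the full-profile learning rate cannot learn measurably
#' in a desk-scale budget).
#'
#' @param learning_rate ADAM step size.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param patience epochs without strict validation improvement before
#'   stopping.
#' @param shuffle_seed seed for minibatch shuffling.
#' @param fast logical; switch to the fast CI profile.
#' @return a `"training_config"`.
#' @export
training_config <- function(learning_rate = 1e-5, batch_size = 16L,
                            max_epochs = 2000L, patience = 100L,
                            shuffle_seed = 1L, fast = FALSE) {
  if (fast) {
    learning_rate <- 1e-3
    max_epochs <- 30L
    patience <- 10L
  }
  cfg <- list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs), patience = as.integer(patience),
              loss = "l1", shuffle_seed = as.integer(shuffle_seed), fast = fast)
  stopifnot(cfg$learning_rate > 0, cfg$batch_size > 0, cfg$max_epochs > 0,
            cfg$patience > 0, cfg$patience < cfg$max_epochs)
  class(cfg) <- "training_config"
  cfg
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = params, state = state)
}

#' Early-stopping / best-epoch selection rule
#'
#' "Improvement" means strictly lower than the best validation loss seen so
#' far. Training stops after `patience` consecutive epochs without
#' improvement; the selected epoch is the first occurrence of the minimum.
#'
#' @param val_curve numeric vector of per-epoch validation losses.
#' @param patience integer.
#' @return list with `best_epoch` (first argmin), `stop_epoch` (last epoch
#'   that would be run under early stopping) and `stopped_early`.
#' @export
select_best_epoch <- function(val_curve, patience) {
  best <- Inf; best_epoch <- 0L; stop_epoch <- length(val_curve)
  stopped_early <- FALSE
  for (e in seq_along(val_curve)) {
    if (val_curve[e] < best) {
      best <- val_curve[e]
      best_epoch <- e
    } else if (e - best_epoch >= patience) {
      stop_epoch <- e
      stopped_early <- TRUE
      break
    }
  }
  list(best_epoch = best_epoch, stop_epoch = stop_epoch,
       stopped_early = stopped_early)
}

mean_l1_loss <- function(model, ds, batch_size = 64L) {
  pr <- predict_model(model, ds$x, batch_size)
  mean(abs(pr$pred - ds$y))
}

#' Train a model on one participant's windowed datasets
#'
#' ADAM updates with L1 loss on shuffled minibatches; per-epoch
#' mean-per-example validation L1; early stopping after `patience` epochs
#' without strict improvement; the returned model carries the parameters of
#' the best-validation epoch. The last incomplete minibatch is used, not
#' dropped.
#'
#' @param model a `"model_handle"` (see [build_model()]).
#' @param train_ds,val_ds `"windowed_dataset"`s.
#' @param cfg a [training_config()].
#' @param verbose print per-epoch losses.
#' @return a `"train_result"`: list with `model` (best-epoch parameters),
#'   `best_epoch`, `best_val_l1`, `train_curve`, `val_curve`,
#'   `stopped_early`, `epochs_run`.
#' @export
train_model <- function(model, train_ds, val_ds, cfg = training_config(),
                        verbose = FALSE) {
  stopifnot(length(train_ds) > 0L, length(val_ds) > 0L)
  n <- length(train_ds)
  state <- adam_init(model$params)
  train_curve <- numeric(0)
  val_curve <- numeric(0)
  best_val <- Inf; best_epoch <- 0L; best_params <- model$params
  best_buffers <- model$buffers
  stopped_early <- FALSE
  set.seed(cfg$shuffle_seed)
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    i <- 1L
    while (i <= n) {
      j <- min(i + cfg$batch_size - 1L, n)
      idx <- perm[i:j]
      xb <- train_ds$x[, , idx, drop = FALSE]
      yb <- train_ds$y[idx]
      out <- model_forward(model, xb, train = TRUE, want_cache = TRUE)
      model <- out$model
      resid <- out$pred - yb
      loss <- mean(abs(resid))
      if (!is.finite(loss)) {
        stop(sprintf("NaN/Inf loss at epoch %d, batch starting %d", epoch, i))
      }
      epoch_loss <- epoch_loss + loss * length(idx)
      dpred <- sign(resid) / length(idx)
      dpre <- dpred * (out$preact > 0)
      grads <- model_backward(model, out$cache, dpre)
      st <- adam_step(model$params, grads, state, cfg$learning_rate)
      model$params <- st$params
      state <- st$state
      i <- j + 1L
    }
    train_curve[epoch] <- epoch_loss / n
    val_curve[epoch] <- mean_l1_loss(model, val_ds)
    if (verbose) {
      message(sprintf("epoch %4d  train l1 %.4f  val l1 %.4f", epoch,
                      train_curve[epoch], val_curve[epoch]))
    }
    if (val_curve[epoch] < best_val) {
      best_val <- val_curve[epoch]
      best_epoch <- epoch
      best_params <- model$params
      best_buffers <- model$buffers
    } else if (epoch - best_epoch >= cfg$patience) {
      stopped_early <- TRUE
      break
    }
  }
  model$params <- best_params
  model$buffers <- best_buffers
  structure(
    list(model = model, best_epoch = best_epoch, best_val_l1 = best_val,
         train_curve = train_curve, val_curve = val_curve,
         stopped_early = stopped_early, epochs_run = length(val_curve),
         training_config = cfg),
    class = "train_result"
  )
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %d epochs run, best epoch %d (val l1 %.4f)%s\n",
              x$epochs_run, x$best_epoch, x$best_val_l1,
              if (x$stopped_early) ", stopped early" else ""))
  invisible(x)
}

#' Predict a weight-shift series for every example of a dataset
#'
#' Evaluation mode (fixed batch-norm statistics); order-preserving; one
#' prediction per example, aligned to `end_times`.
#'
#' @param model a trained `"model_handle"` (or a `"train_result"`).
#' @param dataset a `"windowed_dataset"`.
#' @param batch_size forward batch size.
#' @return data.frame with `end_time`, `pred`, `preact`, `label`.
#' @export
predict_series <- function(model, dataset, batch_size = 64L) {
  if (inherits(model, "train_result")) model <- model$model
  if (dim(dataset$x)[2] != model$config$input_len) {
    stop("dataset window length does not match the model input length")
  }
  pr <- predict_model(model, dataset$x, batch_size)
  data.frame(end_time = dataset$end_times, pred = pr$pred,
             preact = pr$preact, label = dataset$y)
}

#' Save a model checkpoint
#'
#' Writes the binary state (RDS) plus a JSON sidecar with the config,
#' structural report and parameter count.
#'
#' @param model a `"model_handle"` or `"train_result"`.
#' @param path checkpoint path (`.rds`); sidecar written as `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  tr <- NULL
  if (inherits(model, "train_result")) {
    tr <- model[setdiff(names(model), "model")]
    model <- model$model
  }
  saveRDS(list(model = model, train_result = tr), path)
  side <- list(config = unclass(model$config),
               structural_report = structural_report(model))
  if (!is.null(tr)) {
    side$best_epoch <- tr$best_epoch
    side$best_val_l1 <- tr$best_val_l1
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#' @param path path written by [save_checkpoint()].
#' @return the `"model_handle"` (train-result metadata in attribute
#'   `"train_result"`).
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  m <- obj$model
  attr(m, "train_result") <- obj$train_result
  m
}
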