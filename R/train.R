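#' Training hyper-parameters
#'
#' Defaults follow the study protocol: Adam at learning rate 1e-4, batch size
#' 4, up to 1000 epochs, early stopping on validation mIOU with patience 100,
#' and learning-rate decay (multiplicative, factor 0.1) after 100
#' non-improving epochs. The loss is per-pixel categorical cross-entropy over
#' the two softmax channels; mIOU is tracked as a separate validation metric.
#'
#' @param lr Initial learning rate.
#' @param batch_size Slices per optimiser step (gradients are averaged).
#' @param max_epochs Epoch budget.
#' @param early_stop_patience Epochs without a strictly better validation
#'   mIOU tolerated before stopping.
#' @param lr_decay_patience Non-improving epochs before the learning rate is
#'   multiplied by `lr_decay_factor`.
#' @param lr_decay_factor Multiplicative decay, in (0, 1).
#' @param seed Seed for data ordering.
#' @return A `train_config` object.
#' @export
train_config <- function(lr = 1e-4, batch_size = 4L, max_epochs = 1000L,
                         early_stop_patience = 100L, lr_decay_patience = 100L,
                         lr_decay_factor = 0.1, seed = 1L) {
  for (f in c("lr", "batch_size", "max_epochs", "early_stop_patience", "lr_decay_patience"))
    if (get(f) <= 0) stopf("train_config: %s must be positive", f)
  if (lr_decay_factor <= 0 || lr_decay_factor >= 1)
    stopf("train_config: lr_decay_factor must be in (0, 1)")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_decay_patience = as.integer(lr_decay_patience),
                 lr_decay_factor = lr_decay_factor, seed = as.integer(seed)),
            class = "train_config")
}

# element-wise Adam over the nested parameter list
adam_init <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (k in seq_along(p)) {   # by index: nested parameter lists are unnamed
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out$p[[k]] <- r$p; out$m[[k]] <- r$m; out$v[[k]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      list(p = p - lr * (m / bc1) / (sqrt(v / bc2) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

grad_accumulate <- function(acc, g, scale = 1) {
  if (is.null(acc)) {
    if (is.list(g)) lapply(g, grad_accumulate, acc = NULL, scale = scale)
    else g * scale
  } else if (is.list(g)) {
    for (k in seq_along(g)) acc[[k]] <- grad_accumulate(acc[[k]], g[[k]], scale)
    acc
  } else acc + g * scale
}

val_miou <- function(net, val_pairs) {
  mean(vapply(val_pairs, function(p) {
    pred <- unet_predict(net, p$image)$mask
    jaccard(pred, p$mask)
  }, numeric(1)))
}

check_disjoint_patients <- function(train_pairs, val_pairs) {
  tp <- unlist(lapply(train_pairs, `[[`, "patient_id"))
  vp <- unlist(lapply(val_pairs, `[[`, "patient_id"))
  common <- intersect(tp, vp)
  if (length(common) > 0)
    stopf("training and validation sets share patient(s): %s",
          paste(utils::head(common, 3), collapse = ", "))
  invisible(TRUE)
}

#' Train a U-Net with early stopping and learning-rate decay
#'
#' Minimises per-pixel cross-entropy with Adam; after each epoch the
#' foreground mIOU is computed on the (un-augmented) validation set. The
#' checkpoint with the best validation mIOU is returned. Training stops at
#' `max_epochs` or once the validation mIOU has not strictly improved for
#' `early_stop_patience` consecutive epochs; after `lr_decay_patience`
#' non-improving epochs the learning rate is multiplied by
#' `lr_decay_factor` (and the decay counter resets). Fully deterministic
#' given the seed: data order is the only stochastic element, the weight
#' initialisation having been seeded at [build_unet()].
#'
#' @param net A `unet` (its weights are the starting point).
#' @param train_pairs,val_pairs Lists of `list(image, mask, patient_id)` with
#'   images already normalised to `[0, 1]`; patient ids, when present, must
#'   not overlap between the two sets.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `train_result`: list with `net` (best checkpoint), `history`
#'   (data frame: epoch, train_loss, val_miou, lr), `best_epoch`,
#'   `best_val_miou`, `stopped_epoch`.
#' @export
train_unet <- function(net, train_pairs, val_pairs, config = train_config(),
                       verbose = FALSE) {
  if (!inherits(config, "train_config")) stopf("config must be a train_config")
  if (length(train_pairs) == 0) stopf("training set is empty")
  if (length(val_pairs) == 0) stopf("validation set is empty")
  check_disjoint_patients(train_pairs, val_pairs)
  local_seed(config$seed, {
    state <- adam_init(net$params)
    lr <- config$lr
    best <- list(miou = -Inf, params = net$params, epoch = 0L)
    bad <- 0L; bad_lr <- 0L
    hist <- vector("list", config$max_epochs)
    stopped <- config$max_epochs
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(length(train_pairs))
      losses <- numeric(0)
      i <- 1L
      while (i <= length(ord)) {
        batch <- ord[i:min(i + config$batch_size - 1L, length(ord))]
        acc <- NULL
        bl <- 0
        for (j in batch) {
          p <- train_pairs[[j]]
          fwd <- unet_forward(net, p$image, train = TRUE)
          bk <- unet_backward(net, fwd, p$mask)
          bl <- bl + bk$loss
          acc <- grad_accumulate(acc, bk$grads, scale = 1 / length(batch))
        }
        losses <- c(losses, bl / length(batch))
        st <- adam_step(net$params, acc, state, lr)
        net$params <- st$params
        state <- st$state
        i <- i + config$batch_size
      }
      vm <- val_miou(net, val_pairs)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(losses),
                                  val_miou = vm, lr = lr)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f val mIOU %.4f lr %.2g",
                        epoch, mean(losses), vm, lr))
      if (vm > best$miou) {
        best <- list(miou = vm, params = net$params, epoch = epoch)
        bad <- 0L; bad_lr <- 0L
      } else {
        bad <- bad + 1L; bad_lr <- bad_lr + 1L
        if (bad_lr >= config$lr_decay_patience) {
          lr <- lr * config$lr_decay_factor
          bad_lr <- 0L
        }
        if (bad >= config$early_stop_patience) { stopped <- epoch; break }
      }
    }
    net$params <- best$params
    structure(list(net = net, history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]),
                   best_epoch = best$epoch, best_val_miou = best$miou,
                   stopped_epoch = stopped),
              class = "train_result")
  })
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("train_result: stopped at epoch %d; best val mIOU %.4f (epoch %d)\n",
              x$stopped_epoch, x$best_val_miou, x$best_epoch))
  invisible(x)
}
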