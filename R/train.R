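#' Training configuration
#'
#' Defaults follow the clinical training recipe: Adam with learning rate
#' 1e-4, 100 epochs of 600 steps, batches of 10 slices, binary cross-entropy
#' plus soft-Dice loss. For CPU-scale experiments see
#' [scaled_down_profile()].
#'
#' @param learning_rate Adam learning rate (`> 0`).
#' @param epochs Number of epochs (`>= 1`).
#' @param steps_per_epoch Optimizer steps per epoch; `NULL` means one pass
#'   over the training set (`ceiling(n / batch_size)`).
#' @param batch_size Slices per optimizer step.
#' @param loss Loss identifier (currently `"bce_dice"`).
#' @param seed Integer seed covering shuffling and augmentation draws.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 100L,
                         steps_per_epoch = 600L, batch_size = 10L,
                         loss = "bce_dice", seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (epochs < 1 || batch_size < 1 ||
      (!is.null(steps_per_epoch) && steps_per_epoch < 1))
    stop("all counts must be positive", call. = FALSE)
  loss <- match.arg(loss, "bce_dice")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 steps_per_epoch = if (is.null(steps_per_epoch)) NULL
                 else as.integer(steps_per_epoch),
                 batch_size = as.integer(batch_size), loss = loss,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' CPU-scale training profile
#'
#' A compact configuration bundle for desk-scale experiments on 64 x 64
#' phantom slices: a depth-2, 8-filter U-Net, Adam at 1e-3 for 10 epochs of
#' one pass each, batch size 10, with the full augmentation recipe. The
#' clinical-scale recipe remains available through [train_config()]
#' defaults.
#'
#' @param architecture Passed to [model_config()].
#' @param epochs Number of epochs (default 8).
#' @param seed Seed shared by weight init and training.
#' @return List with elements `model` ([model_config()]), `train`
#'   ([train_config()]), `augment` ([augmentation_config()]).
#' @export
scaled_down_profile <- function(architecture = "unet", epochs = 10L, seed = 1L) {
  list(model = model_config(architecture, depth = 2L, base_filters = 8L,
                            input_size = c(64L, 64L)),
       train = train_config(learning_rate = 1e-3, epochs = epochs,
                            steps_per_epoch = NULL, batch_size = 10L,
                            seed = seed),
       augment = augmentation_config())
}

#' Train a slice segmentation model
#'
#' Minimizes binary cross-entropy plus soft-Dice with Adam over randomly
#' shuffled batches of (slice, mask) pairs, optionally augmenting each drawn
#' pair. When `steps_per_epoch` exceeds the dataset, sampling cycles with
#' reshuffling. Per-epoch training loss and validation Dice are recorded
#' and the weights with the best validation Dice are retained (final
#' weights when no validation set is given). Fully deterministic for a
#' given `tcfg$seed`.
#'
#' @param model A [build_model()] object.
#' @param train_pairs Non-empty list of `list(image, mask)` pairs (equal
#'   shapes).
#' @param val_pairs Optional validation pairs (may be empty).
#' @param tcfg A [train_config()].
#' @param acfg Optional [augmentation_config()]; `NULL` disables
#'   augmentation.
#' @return List with `model` (trained) and `history` (`data.frame` with
#'   `epoch`, `loss`, `val_dsc`).
#' @export
train_model <- function(model, train_pairs, val_pairs = list(),
                        tcfg = train_config(), acfg = NULL) {
  stopifnot(inherits(model, "unet_model"), inherits(tcfg, "train_config"))
  if (length(train_pairs) < 1)
    stop("training set must contain at least one pair", call. = FALSE)
  n <- length(train_pairs)
  steps <- tcfg$steps_per_epoch %||% ceiling(n / tcfg$batch_size)
  params <- model$params
  state <- adam_state(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_dsc = numeric(0))
  best <- list(dsc = -Inf, params = params)
  t_global <- 0L
  with_seed(tcfg$seed, {
    order <- sample.int(n)
    ptr <- 1L
    for (epoch in seq_len(tcfg$epochs)) {
      losses <- numeric(steps)
      for (s in seq_len(steps)) {
        take <- integer(0)
        while (length(take) < tcfg$batch_size) {
          if (ptr > n) { order <- sample.int(n); ptr <- 1L }
          k <- min(n, ptr + (tcfg$batch_size - length(take)) - 1L)
          take <- c(take, order[ptr:k])
          ptr <- k + 1L
        }
        pairs <- lapply(train_pairs[take], function(p) {
          if (is.null(acfg)) p else augment(p$image, p$mask, acfg)
        })
        shp <- dim(pairs[[1]]$image)
        x <- array(unlist(lapply(pairs, `[[`, "image"), use.names = FALSE),
                   c(shp[1], shp[2], length(pairs), 1))
        y <- array(unlist(lapply(pairs, `[[`, "mask"), use.names = FALSE),
                   c(shp[1], shp[2], length(pairs), 1))
        pbx <- pad_batch(x, model$cfg$depth)
        pby <- pad_batch(y, model$cfg$depth)
        ctx <- nn_ctx(params)
        logits <- model_forward(ctx, nn_tensor(ctx, pbx$arr), model$cfg)
        l <- bce_dice_loss(logits$val, pby$arr)
        losses[s] <- l$loss
        grads <- nn_backward(ctx, logits, l$dlogits)
        t_global <- t_global + 1L
        upd <- adam_step(params, grads$param, state, tcfg$learning_rate,
                         t_global)
        params <- upd$params; state <- upd$state
      }
      val_dsc <- NA_real_
      if (length(val_pairs) > 0) {
        m_now <- model; m_now$params <- params
        val_dsc <- mean(vapply(val_pairs, function(p) {
          pred <- predict_slice(m_now, p$image)
          derive_metrics(confusion(pred, p$mask))$dsc / 100
        }, numeric(1)))
        if (val_dsc > best$dsc) best <- list(dsc = val_dsc, params = params)
      }
      history[nrow(history) + 1L, ] <- list(epoch, mean(losses), val_dsc)
    }
  })
  model$params <- if (length(val_pairs) > 0) best$params else params
  list(model = model, history = history)
}

#' Write a training history as CSV
#'
#' @param history The `history` component of [train_model()]'s result.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
save_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
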