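#' Model configuration for the 2D slice segmenters
#'
#' Describes a U-Net or U-Net++ that maps a single-channel 2D ultrasound
#' slice to a per-pixel probability of synovial tissue. Channel width at
#' level `i` is `base_filters * 2^(i-1)`. The U-Net++ variant uses nested
#' dense skip pathways and, with `encoder = "resnet"`, residual
#' (ResNet-style basic block) encoder stages; deep supervision is off — the
#' output is read from the final nested node.
#'
#' @param architecture `"unet"` or `"unetpp"`.
#' @param depth Number of resolution levels (`>= 2`).
#' @param base_filters Channels at the first level (`>= 1`).
#' @param input_size Nominal training input `(h, w)`; both must be divisible
#'   by `2^(depth - 1)`. Inference accepts any size via internal padding.
#' @param encoder `"plain"` or `"resnet"` (residual encoder blocks; the
#'   default for `unetpp`).
#' @return An object of class `model_config`.
#' @export
model_config <- function(architecture = c("unet", "unetpp"), depth = 2L,
                         base_filters = 8L, input_size = c(64L, 64L),
                         encoder = NULL) {
  architecture <- match.arg(architecture)
  depth <- as.integer(depth); base_filters <- as.integer(base_filters)
  if (depth < 2) stop("depth must be >= 2", call. = FALSE)
  if (base_filters < 1) stop("base_filters must be >= 1", call. = FALSE)
  m <- 2^(depth - 1)
  if (any(input_size %% m != 0))
    stop(sprintf("input size must be divisible by 2^(depth-1) = %d", m),
         call. = FALSE)
  if (is.null(encoder))
    encoder <- if (architecture == "unetpp") "resnet" else "plain"
  encoder <- match.arg(encoder, c("plain", "resnet"))
  structure(list(architecture = architecture, depth = depth,
                 base_filters = base_filters,
                 input_size = as.integer(input_size), encoder = encoder),
            class = "model_config")
}

# Named list of conv shapes for an architecture: each entry c(cin, cout, k).
model_param_spec <- function(cfg) {
  d <- cfg$depth
  ch <- cfg$base_filters * 2^(seq_len(d) - 1)
  spec <- list()
  add_block <- function(name, cin, cout, residual) {
    spec[[paste0(name, ".c1")]] <<- c(cin, cout, 3)
    spec[[paste0(name, ".c2")]] <<- c(cout, cout, 3)
    if (residual && cin != cout)
      spec[[paste0(name, ".proj")]] <<- c(cin, cout, 1)
  }
  res <- cfg$encoder == "resnet"
  add_block("enc1", 1, ch[1], res)
  for (i in 2:d) add_block(paste0("enc", i), ch[i - 1], ch[i], res)
  if (cfg$architecture == "unet") {
    for (i in seq_len(d - 1))
      add_block(paste0("dec", i), ch[i] + ch[i + 1], ch[i], FALSE)
  } else {
    for (i in seq_len(d - 1)) for (j in seq_len(d - i))
      add_block(sprintf("nd%d_%d", i, j), j * ch[i] + ch[i + 1], ch[i], FALSE)
  }
  spec[["out"]] <- c(ch[1], 1, 1)
  spec
}

#' Build a slice segmentation model
#'
#' Initializes all convolution weights (He initialization, seeded) for the
#' configured architecture and reports the parameter count.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `unet_model` with fields `cfg`, `params`,
#'   `n_params`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  spec <- model_param_spec(cfg)
  params <- with_seed(seed, lapply(spec, function(s) {
    fan_in <- s[1] * s[3]^2
    list(W = matrix(stats::rnorm(fan_in * s[2], sd = sqrt(2 / fan_in)),
                    fan_in, s[2]),
         b = numeric(s[2]))
  }))
  n_params <- sum(vapply(params, function(p) length(p$W) + length(p$b),
                         numeric(1)))
  structure(list(cfg = cfg, params = params, n_params = n_params),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> %s, depth %d, base %d filters, encoder %s: %d parameters\n",
              x$cfg$architecture, x$cfg$depth, x$cfg$base_filters,
              x$cfg$encoder, x$n_params))
  invisible(x)
}

nn_block <- function(ctx, x, name, residual) {
  h <- t_relu(ctx, t_conv3(ctx, x, paste0(name, ".c1")))
  h <- t_conv3(ctx, h, paste0(name, ".c2"))
  if (residual) {
    skip <- if (!is.null(ctx$params[[paste0(name, ".proj")]]))
      t_conv1(ctx, x, paste0(name, ".proj")) else x
    h <- t_add(ctx, h, skip)
  }
  t_relu(ctx, h)
}

# Forward pass producing the logits tensor (pre-sigmoid).
model_forward <- function(ctx, x, cfg) {
  d <- cfg$depth
  res <- cfg$encoder == "resnet"
  if (cfg$architecture == "unet") {
    skips <- vector("list", d - 1)
    h <- x
    for (i in seq_len(d - 1)) {
      h <- nn_block(ctx, h, paste0("enc", i), res)
      skips[[i]] <- h
      h <- t_maxpool2(ctx, h)
    }
    h <- nn_block(ctx, h, paste0("enc", d), res)
    for (i in rev(seq_len(d - 1))) {
      h <- t_upsample2(ctx, h)
      h <- t_concat(ctx, list(skips[[i]], h))
      h <- nn_block(ctx, h, paste0("dec", i), FALSE)
    }
  } else {
    X <- vector("list", d)
    for (i in seq_len(d)) X[[i]] <- vector("list", d - i + 1)
    h <- x
    for (i in seq_len(d)) {
      if (i > 1) h <- t_maxpool2(ctx, h)
      h <- nn_block(ctx, h, paste0("enc", i), res)
      X[[i]][[1]] <- h
    }
    for (j in seq_len(d - 1)) for (i in seq_len(d - j)) {
      up <- t_upsample2(ctx, X[[i + 1]][[j]])
      inputs <- c(X[[i]][seq_len(j)], list(up))
      X[[i]][[j + 1]] <- nn_block(ctx, t_concat(ctx, inputs),
                                  sprintf("nd%d_%d", i, j), FALSE)
    }
    h <- X[[1]][[d]]
  }
  t_conv1(ctx, h, "out")
}

# Pad a (H, W, N, C) batch so H and W are divisible by 2^(depth-1).
pad_batch <- function(arr, depth) {
  m <- 2^(depth - 1)
  d <- dim(arr)
  H2 <- ceiling(d[1] / m) * m; W2 <- ceiling(d[2] / m) * m
  if (H2 == d[1] && W2 == d[2]) return(list(arr = arr, H = d[1], W = d[2]))
  out <- array(0, c(H2, W2, d[3], d[4]))
  out[seq_len(d[1]), seq_len(d[2]), , ] <- arr
  list(arr = out, H = d[1], W = d[2])
}

# Probability maps for a list of equally shaped slice images.
predict_prob_batch <- function(model, images) {
  shp <- dim(images[[1]])
  arr <- array(unlist(images, use.names = FALSE),
               c(shp[1], shp[2], length(images), 1))
  pb <- pad_batch(arr, model$cfg$depth)
  ctx <- nn_ctx(model$params)
  logits <- model_forward(ctx, nn_tensor(ctx, pb$arr), model$cfg)
  probs <- sigmoid(logits$val)
  lapply(seq_along(images), function(k)
    matrix(probs[seq_len(pb$H), seq_len(pb$W), k, 1], pb$H, pb$W))
}

#' Probability map for one slice
#'
#' Runs the network on a single 2D slice. Any slice shape is accepted: the
#' image is zero-padded to the next multiple of `2^(depth-1)` and the map is
#' cropped back to the native shape.
#'
#' @param model A trained [build_model()] object.
#' @param image 2D intensity matrix in `[0, 1]`.
#' @return Probability matrix of the same shape as `image`.
#' @export
predict_prob <- function(model, image) {
  stopifnot(inherits(model, "unet_model"), is.matrix(image))
  predict_prob_batch(model, list(image))[[1]]
}

#' Thresholded binary prediction for one slice
#'
#' @inheritParams predict_prob
#' @param threshold Probability threshold (default 0.5).
#' @return Binary mask matrix (0/1) of the slice shape.
#' @export
predict_slice <- function(model, image, threshold = 0.5) {
  p <- predict_prob(model, image)
  matrix(as.numeric(p >= threshold), nrow(p), ncol(p))
}

#' Predict masks for every slice of a stack
#'
#' One binary mask per slice, order preserved; slices are batched for
#' efficiency.
#'
#' @param model A trained [build_model()] object.
#' @param stack A [slice_stack()].
#' @param threshold Probability threshold.
#' @param batch_size Slices per forward pass.
#' @return List of binary mask matrices, one per stack slice.
#' @export
predict_stack <- function(model, stack, threshold = 0.5, batch_size = 8L) {
  stopifnot(inherits(stack, "slice_stack"))
  out <- vector("list", length(stack$images))
  for (s in seq(1, length(stack$images), by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, length(stack$images))
    probs <- predict_prob_batch(model, stack$images[idx])
    for (j in seq_along(idx))
      out[[idx[j]]] <- matrix(as.numeric(probs[[j]] >= threshold),
                              nrow(probs[[j]]), ncol(probs[[j]]))
  }
  out
}

#' Save / load a model checkpoint
#'
#' Weights go to `<path>.rds` (R's standard serialization); the model
#' configuration is mirrored in a human-readable `<path>.json` sidecar.
#'
#' @param model A [build_model()] object.
#' @param path Checkpoint path prefix (no extension).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, paste0(path, ".rds"))
  jsonlite::write_json(model$cfg[c("architecture", "depth", "base_filters",
                                   "input_size", "encoder")],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(paste0(path, ".rds"))
  stopifnot(inherits(model, "unet_model"))
  model
}
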