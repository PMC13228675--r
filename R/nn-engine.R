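# Minimal reverse-mode engine for the slice segmenters. Tensors are R arrays
# in (H, W, N, C) layout — spatial dims first, channels last, so im2col is a
# plain reshape with no transposition. Each op pushes a backward closure onto
# a tape and gradients are accumulated by tensor id; the heavy lifting is
# dense matrix multiplication over im2col matrices.

nn_ctx <- function(params) {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- params
  ctx$tape <- list()
  ctx$next_id <- 1L
  ctx
}

nn_tensor <- function(ctx, val) {
  id <- ctx$next_id
  ctx$next_id <- id + 1L
  list(id = id, val = val)
}

nn_record <- function(ctx, node) {
  ctx$tape[[length(ctx$tape) + 1L]] <- node
  invisible(NULL)
}

# Per-shape cache of gather indices for im2col (runtime memoization only).
.im2col_cache <- new.env(parent = emptyenv())

im2col_idx <- function(H, W, N, C) {
  key <- paste(H, W, N, C, sep = "x")
  idx <- .im2col_cache[[key]]
  if (!is.null(idx)) return(idx)
  drs <- rep(0:2, times = 3); dcs <- rep(0:2, each = 3)
  hw <- outer(seq_len(H), (seq_len(W) - 1L) * (H + 2L), `+`)  # (h, w) base
  O <- as.vector(outer((seq_len(N) - 1L) * (H + 2L) * (W + 2L),
                       (seq_len(C) - 1L) * (H + 2L) * (W + 2L) * N, `+`))
  idx <- unlist(lapply(seq_len(9L), function(k) {
    B <- as.vector(hw + drs[k] + (H + 2L) * dcs[k])
    outer(B, O, `+`)
  }), use.names = FALSE)
  .im2col_cache[[key]] <- idx
  idx
}

# (H, W, N, C) -> (H*W*N, 9*C); column block k holds the k-th 3x3 offset,
# implemented as one gather over the zero-padded array.
im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  xp <- array(0, c(H + 2, W + 2, N, C))
  xp[2:(H + 1), 2:(W + 1), , ] <- x
  cols <- xp[im2col_idx(H, W, N, C)]
  dim(cols) <- c(H * W * N, 9L * C)
  cols
}

# 180-degree-rotated, channel-transposed kernel: the input gradient of a
# same-padded correlation is the same-padded correlation of the output
# gradient with this kernel.
rotate_kernel <- function(Wm, Cin) {
  Cout <- ncol(Wm)
  arr <- array(Wm, c(Cin, 9, Cout))          # (cin, offset, cout)
  rot <- aperm(arr[, 9:1, , drop = FALSE], c(3, 2, 1))  # (cout, offset', cin)
  dim(rot) <- c(9 * Cout, Cin)
  rot
}

# 3x3 same-padding convolution; weight matrix (9*Cin, Cout), bias (Cout).
# Weight row (k-1)*Cin + c maps offset k, input channel c.
t_conv3 <- function(ctx, x, wname) {
  Wm <- ctx$params[[wname]]$W
  b <- ctx$params[[wname]]$b
  d <- dim(x$val); H <- d[1]; W_ <- d[2]; N <- d[3]; C <- d[4]
  cols <- im2col3(x$val)
  ym <- cols %*% Wm
  ym <- sweep(ym, 2, b, `+`)
  dim(ym) <- c(H, W_, N, ncol(Wm))
  out <- nn_tensor(ctx, ym)
  nn_record(ctx, list(
    out_id = out$id, in_ids = x$id,
    backward = function(dout, grads) {
      dm <- dout
      dim(dm) <- c(H * W_ * N, dim(dout)[4])
      grads$param[[wname]]$W <- (grads$param[[wname]]$W %||% 0) + crossprod(cols, dm)
      grads$param[[wname]]$b <- (grads$param[[wname]]$b %||% 0) + colSums(dm)
      dx <- im2col3(dout) %*% rotate_kernel(Wm, C)
      dim(dx) <- c(H, W_, N, C)
      list(dx)
    }))
  out
}

# 1x1 convolution; weights (Cin, Cout) plus bias.
t_conv1 <- function(ctx, x, wname) {
  Wm <- ctx$params[[wname]]$W
  b <- ctx$params[[wname]]$b
  d <- dim(x$val); H <- d[1]; W_ <- d[2]; N <- d[3]; C <- d[4]
  xm <- x$val
  dim(xm) <- c(H * W_ * N, C)
  ym <- sweep(xm %*% Wm, 2, b, `+`)
  dim(ym) <- c(H, W_, N, ncol(Wm))
  out <- nn_tensor(ctx, ym)
  nn_record(ctx, list(
    out_id = out$id, in_ids = x$id,
    backward = function(dout, grads) {
      dm <- dout
      dim(dm) <- c(H * W_ * N, dim(dout)[4])
      grads$param[[wname]]$W <- (grads$param[[wname]]$W %||% 0) + crossprod(xm, dm)
      grads$param[[wname]]$b <- (grads$param[[wname]]$b %||% 0) + colSums(dm)
      dx <- dm %*% t(Wm)
      dim(dx) <- c(H, W_, N, C)
      list(dx)
    }))
  out
}

t_relu <- function(ctx, x) {
  mask <- x$val > 0
  out <- nn_tensor(ctx, x$val * mask)
  nn_record(ctx, list(out_id = out$id, in_ids = x$id,
                      backward = function(dout, grads) list(dout * mask)))
  out
}

t_add <- function(ctx, a, b) {
  out <- nn_tensor(ctx, a$val + b$val)
  nn_record(ctx, list(out_id = out$id, in_ids = c(a$id, b$id),
                      backward = function(dout, grads) list(dout, dout)))
  out
}

t_maxpool2 <- function(ctx, x) {
  d <- dim(x$val); H <- d[1]; W_ <- d[2]
  ri <- seq(1, H, 2); ci <- seq(1, W_, 2)
  s <- list(x$val[ri, ci, , , drop = FALSE],
            x$val[ri + 1, ci, , , drop = FALSE],
            x$val[ri, ci + 1, , , drop = FALSE],
            x$val[ri + 1, ci + 1, , , drop = FALSE])
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  dim(m) <- dim(s[[1]])
  out <- nn_tensor(ctx, m)
  nn_record(ctx, list(
    out_id = out$id, in_ids = x$id,
    backward = function(dout, grads) {
      dx <- array(0, d)
      taken <- array(FALSE, dim(m))
      offs <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
      for (k in 1:4) {
        msk <- (s[[k]] == m) & !taken
        taken <- taken | msk
        dx[ri + offs[[k]][1], ci + offs[[k]][2], , ] <- dout * msk
      }
      list(dx)
    }))
  out
}

t_upsample2 <- function(ctx, x) {
  d <- dim(x$val); H <- d[1]; W_ <- d[2]
  y <- x$val[rep(seq_len(H), each = 2), rep(seq_len(W_), each = 2), , ,
             drop = FALSE]
  out <- nn_tensor(ctx, y)
  nn_record(ctx, list(
    out_id = out$id, in_ids = x$id,
    backward = function(dout, grads) {
      ri <- seq(1, 2 * H, 2); ci <- seq(1, 2 * W_, 2)
      dx <- dout[ri, ci, , , drop = FALSE] +
        dout[ri + 1, ci, , , drop = FALSE] +
        dout[ri, ci + 1, , , drop = FALSE] +
        dout[ri + 1, ci + 1, , , drop = FALSE]
      list(dx)
    }))
  out
}

# Concatenate along the channel (4th) dimension.
t_concat <- function(ctx, xs) {
  chans <- vapply(xs, function(t) dim(t$val)[4], integer(1))
  d <- dim(xs[[1]]$val)
  y <- array(0, c(d[1], d[2], d[3], sum(chans)))
  at <- 0L
  for (t in xs) {
    cs <- dim(t$val)[4]
    y[, , , at + seq_len(cs)] <- t$val
    at <- at + cs
  }
  out <- nn_tensor(ctx, y)
  nn_record(ctx, list(
    out_id = out$id, in_ids = vapply(xs, function(t) t$id, integer(1)),
    backward = function(dout, grads) {
      at <- 0L
      lapply(chans, function(cs) {
        g <- dout[, , , at + seq_len(cs), drop = FALSE]
        at <<- at + cs
        g
      })
    }))
  out
}

# Backpropagate from tensor `from` with upstream gradient `dout`; returns an
# environment whose $param holds named parameter gradients.
nn_backward <- function(ctx, from, dout) {
  grads <- new.env(parent = emptyenv())
  grads$param <- list()
  gmap <- vector("list", ctx$next_id)
  gmap[[from$id]] <- dout
  for (k in rev(seq_along(ctx$tape))) {
    node <- ctx$tape[[k]]
    g <- gmap[[node$out_id]]
    if (is.null(g)) next
    dins <- node$backward(g, grads)
    for (j in seq_along(node$in_ids)) {
      id <- node$in_ids[j]
      gmap[[id]] <- if (is.null(gmap[[id]])) dins[[j]] else gmap[[id]] + dins[[j]]
    }
    gmap[node$out_id] <- list(NULL)
  }
  grads
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Binary cross-entropy plus soft-Dice loss on logits; returns the scalar
# loss and its gradient with respect to the logits.
bce_dice_loss <- function(logits, y, eps = 1e-6) {
  p <- sigmoid(logits)
  n <- length(p)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  bce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  sp <- sum(p); sy <- sum(y); spy <- sum(p * y)
  dice <- (2 * spy + eps) / (sp + sy + eps)
  loss <- bce + (1 - dice)
  dbce_dz <- (p - y) / n
  ddice_dp <- (2 * y * (sp + sy + eps) - (2 * spy + eps)) / (sp + sy + eps)^2
  ddice_dz <- ddice_dp * p * (1 - p)
  list(loss = loss, bce = bce, dice = dice, dlogits = dbce_dz - ddice_dz)
}

adam_state <- function(params) {
  lapply(params, function(p) list(
    mW = array(0, dim(p$W)), vW = array(0, dim(p$W)),
    mb = numeric(length(p$b)), vb = numeric(length(p$b))))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  b1t <- 1 - beta1^t; b2t <- 1 - beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    params[[nm]]$W <- params[[nm]]$W - lr * (st$mW / b1t) / (sqrt(st$vW / b2t) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (st$mb / b1t) / (sqrt(st$vb / b2t) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}
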