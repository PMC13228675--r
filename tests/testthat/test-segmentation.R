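test_that("model construction respects its config contract", {
  m <- build_model(model_config("unet", depth = 2, base_filters = 8), seed = 1)
  p <- predict_prob(m, matrix(0, 64, 64))
  expect_equal(dim(p), c(64, 64))
  expect_true(all(p >= 0 & p <= 1))
  # U-Net++ with residual encoder builds and runs
  mpp <- build_model(model_config("unetpp", depth = 3, base_filters = 4),
                     seed = 1)
  ppp <- predict_prob(mpp, matrix(0.5, 32, 32))
  expect_true(all(ppp >= 0 & ppp <= 1))
  # doubling base filters strictly increases the parameter count
  n8 <- build_model(model_config("unet", 2, 8), seed = 1)$n_params
  n16 <- build_model(model_config("unet", 2, 16), seed = 1)$n_params
  expect_gt(n16, n8)
  expect_error(model_config("unet", depth = 3, input_size = c(30, 30)),
               "divisible")
  expect_error(model_config("unet", depth = 1), "depth")
})

test_that("analytic gradients agree with finite differences", {
  got <- with_seed(19, {
    xs <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
    ys <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 2, 1))
    errs <- c()
    for (arch in c("unet", "unetpp")) {
      cfgx <- model_config(arch, 2, 2, c(8, 8))
      mo <- build_model(cfgx, 3)
      lossfun <- function(params) {
        ctx <- nn_ctx(params)
        lg <- model_forward(ctx, nn_tensor(ctx, xs), cfgx)
        bce_dice_loss(lg$val, ys)$loss
      }
      ctx <- nn_ctx(mo$params)
      lg <- model_forward(ctx, nn_tensor(ctx, xs), cfgx)
      l <- bce_dice_loss(lg$val, ys)
      g <- nn_backward(ctx, lg, l$dlogits)
      for (nm in names(mo$params)) {
        W <- mo$params[[nm]]$W
        for (i in sample(length(W), min(3, length(W)))) {
          p1 <- mo$params; p1[[nm]]$W[i] <- p1[[nm]]$W[i] + 1e-5
          p2 <- mo$params; p2[[nm]]$W[i] <- p2[[nm]]$W[i] - 1e-5
          num <- (lossfun(p1) - lossfun(p2)) / 2e-5
          errs <- c(errs, abs(num - g$param[[nm]]$W[i]) /
                      max(1e-6, abs(num) + abs(g$param[[nm]]$W[i])))
        }
      }
    }
    errs
  })
  # median over sampled weights; isolated ReLU-kink crossings are tolerated
  expect_lt(median(got), 1e-6)
  expect_gte(mean(got < 1e-4), 0.9)
})

test_that("augmentation applies one transform to both image and mask", {
  img <- matrix(runif(64 * 64), 64, 64)
  msk <- disc_mask(64, 12)
  off <- augmentation_config(FALSE, FALSE, 0, 0, 0)
  same <- augment(img, msk, off)
  expect_identical(same$image, img)
  expect_identical(same$mask, msk)
  cfg <- augmentation_config()
  for (s in 1:10) {
    out <- with_seed(s, augment(img, msk, cfg))
    expect_equal(dim(out$image), dim(img))
    expect_true(all(out$mask %in% c(0, 1)))
  }
  expect_error(augment(img, msk[1:32, ], cfg), "identical shape")
})

test_that("a bounded rotation preserves the area of a centred disc", {
  msk <- disc_mask(64, 20)
  cfg <- augmentation_config(FALSE, FALSE, 20, 0, 0)
  for (s in 1:8) {
    out <- with_seed(s, augment(msk, msk, cfg))
    expect_lt(abs(sum(out$mask) - sum(msk)) / sum(msk), 0.02)
  }
})

test_that("flips are involutions on the pixel grid", {
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(img[, ncol(img):1][, ncol(img):1], img)
  # flip-only augmentation either flips or not, and twice restores
  cfg <- augmentation_config(TRUE, FALSE, 0, 0, 0)
  out <- with_seed(1, augment(img, img, cfg))
  again <- if (identical(out$image, img)) out$image else out$image[, ncol(img):1]
  expect_identical(again, img)
})

test_that("training a single pair for one epoch reduces its loss", {
  got <- with_seed(77, {
    ph <- generate_phantom(small_phantom_params(seed = 3))
    img <- ph$volume$voxels[12, , ]
    msk <- ph$label$voxels[12, , ]
    cfg <- model_config("unet", 2, 4, c(48, 48))
    model <- build_model(cfg, seed = 5)
    loss_of <- function(m) {
      x <- array(img, c(48, 48, 1, 1)); y <- array(msk, c(48, 48, 1, 1))
      ctx <- nn_ctx(m$params)
      lg <- model_forward(ctx, nn_tensor(ctx, x), cfg)
      bce_dice_loss(lg$val, y)$loss
    }
    before <- loss_of(model)
    fit <- train_model(model, list(list(image = img, mask = msk)),
                       tcfg = train_config(1e-3, epochs = 1,
                                           steps_per_epoch = 5,
                                           batch_size = 1, seed = 1))
    c(before = before, after = loss_of(fit$model))
  })
  expect_lt(got["after"], got["before"])
})

test_that("steps_per_epoch beyond the dataset cycles with reshuffling", {
  ph <- generate_phantom(small_phantom_params(seed = 3))
  pairs <- list(list(image = ph$volume$voxels[10, , ],
                     mask = ph$label$voxels[10, , ]),
                list(image = ph$volume$voxels[14, , ],
                     mask = ph$label$voxels[14, , ]))
  fit <- train_model(build_model(model_config("unet", 2, 2, c(48, 48)), 1),
                     pairs,
                     tcfg = train_config(1e-3, epochs = 1,
                                         steps_per_epoch = 4, batch_size = 2,
                                         seed = 2))
  expect_equal(nrow(fit$history), 1)
  expect_true(is.finite(fit$history$loss))
  expect_error(train_model(build_model(model_config("unet", 2, 2), 1),
                           list(), tcfg = train_config()),
               "at least one")
})

test_that("thresholding bounds and monotonicity hold for predictions", {
  model <- build_model(model_config("unet", 2, 4), seed = 2)
  img <- with_seed(1, matrix(runif(64 * 64), 64, 64))
  expect_equal(sum(predict_slice(model, img, threshold = 1.01)), 0)
  expect_equal(sum(predict_slice(model, img, threshold = 0)), 64 * 64)
  counts <- vapply(c(0.25, 0.5, 0.75), function(th)
    sum(predict_slice(model, img, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("stack prediction is deterministic and order-equivariant", {
  model <- build_model(model_config("unet", 2, 4), seed = 3)
  ph <- generate_phantom(phantom_params(shape = c(8L, 64L, 64L), seed = 2))
  st <- reslice(ph$volume, 8)
  m1 <- predict_stack(model, st)
  m2 <- predict_stack(model, st)
  expect_identical(m1, m2)
  expect_length(m1, 8)
  # identical images give identical masks; an empty image does not crash
  same <- slice_stack(list(st$images[[3]], st$images[[3]]), c(1L, 2L),
                      st$in_plane_spacing, st$slice_spacing, 8)
  ms <- predict_stack(model, same)
  expect_identical(ms[[1]], ms[[2]])
  zero <- slice_stack(list(matrix(0, 64, 64)), 1L, c(0.114, 0.114), 0.333, 8)
  expect_silent(predict_stack(model, zero))
  # permuting the stack permutes the outputs identically
  perm <- c(5, 1, 8, 3, 2, 7, 4, 6)
  stp <- slice_stack(st$images[perm], seq_len(8), st$in_plane_spacing,
                     st$slice_spacing, 8)
  mp <- predict_stack(model, stp)
  for (k in seq_len(8)) expect_identical(mp[[k]], m1[[perm[k]]])
})

test_that("model checkpoints round-trip with their JSON sidecar", {
  model <- build_model(model_config("unetpp", 2, 4), seed = 9)
  path <- file.path(withr::local_tempdir(), "ckpt")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$params, model$params)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$architecture, "unetpp")
  img <- with_seed(2, matrix(runif(64 * 64), 64, 64))
  expect_identical(predict_prob(model, img), predict_prob(back, img))
})
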