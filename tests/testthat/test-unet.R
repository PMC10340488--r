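# U-Net architecture contract, training harness and fold plans.

test_that("forward pass maps (H, W, 3) to (H, W, out) with a 16x bottleneck", {
  spec <- unet_spec(channels = c(4, 8, 8, 16, 16), dropout_p = 0)
  set.seed(1)
  params <- wbcseg:::unet_init(spec)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  fwd <- wbcseg:::unet_forward(params, spec, x)
  expect_equal(dim(fwd$prob), c(64, 64, 1, 1))
  expect_true(all(fwd$prob > 0 & fwd$prob < 1))
  # bottleneck spatial size = input / prod(strides) = 64/16
  bott <- fwd$caches[[5]]$cv$in_shape
  expect_equal(c(bott$h * 1L, bott$w * 1L) / 1L, c(8, 8)) # level-5 input 8x8
  expect_error(wbcseg:::unet_forward(params, spec,
                                     array(0, c(60, 64, 3, 1))),
               "divisible by 16")
})

test_that("spec validation enforces the architecture invariants", {
  expect_error(unet_spec(channels = c(8, 16), strides = c(1, 2)),
               "16-fold")
  expect_error(unet_spec(strides = c(1, 2, 2, 2, 3)), "strides")
  s <- unet_spec()
  expect_equal(s$channels, c(32L, 64L, 128L, 256L, 512L))
  expect_equal(prod(s$strides), 16)
})

test_that("network gradients agree with finite differences", {
  spec <- unet_spec(channels = c(2, 3, 3, 4, 4), dropout_p = 0)
  set.seed(2)
  params <- wbcseg:::unet_init(spec)
  lp <- loss_params()
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))[, , 1, , drop = FALSE]
  lossfun <- function(pp) {
    fwd <- wbcseg:::unet_forward(pp, spec, x)
    unified_focal_loss(fwd$prob[, , 1, , drop = FALSE], y, lp)
  }
  fwd <- wbcseg:::unet_forward(params, spec, x)
  g <- wbcseg:::ufl_grad(fwd$prob[, , 1, , drop = FALSE], y, lp)
  dprob <- array(0, dim(fwd$prob)); dprob[, , 1, ] <- g
  grads <- wbcseg:::unet_backward(params, spec, fwd, dprob)
  for (k in c("enc1_W", "enc4_W", "dec2_W", "enc3_g", "dec1_be", "head_W")) {
    for (i in sample(length(params[[k]]), min(3, length(params[[k]])))) {
      h <- 1e-5
      p1 <- params; p1[[k]][i] <- p1[[k]][i] + h
      p2 <- params; p2[[k]][i] <- p2[[k]][i] - h
      num <- (lossfun(p1) - lossfun(p2)) / (2 * h)
      expect_equal(grads[[k]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("fold plans partition the samples with near-equal sizes", {
  for (n in c(10, 23, 57)) {
    fp <- fold_plan(n, 10, seed = n)
    expect_equal(sort(unique(fp$assignments)), 1:10)
    sizes <- tabulate(fp$assignments, 10)
    expect_lte(diff(range(sizes)), 1)
    expect_equal(sum(sizes), n)
  }
  expect_identical(fold_plan(20, 10, 3)$assignments,
                   fold_plan(20, 10, 3)$assignments)
  expect_error(fold_plan(5, 10), "fewer samples")
})

test_that("training is deterministic under a fixed seed", {
  fx <- tiny_smears(4)
  imgs <- lapply(fx, `[[`, "image"); msks <- lapply(fx, `[[`, "mask")
  spec <- unet_spec(channels = c(4, 4, 8, 8, 8), dropout_p = 0.2)
  f1 <- wbc_unet(imgs, msks, spec = spec, epochs = 2, seed = 5,
                 augment = augment_policy())
  f2 <- wbc_unet(imgs, msks, spec = spec, epochs = 2, seed = 5,
                 augment = augment_policy())
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$params, f2$params)
  # inference is deterministic too
  expect_identical(predict(f1, imgs[[1]]), predict(f2, imgs[[1]]))
})

test_that("a small net overfits one image and predicts its mask", {
  fx <- tiny_smears(1, size = 32)
  img <- fx[[1]]$image; msk <- fx[[1]]$mask
  fit <- wbc_unet(list(img), list(msk),
                  spec = unet_spec(channels = c(8, 16, 16, 32, 32),
                                   dropout_p = 0),
                  epochs = 60, lr = 3e-3, seed = 3)
  pred <- predict(fit, img)
  expect_gte(evaluate_masks(pred, msk)$iou, 0.9)
  # all-background target collapses to an empty prediction
  fit0 <- wbc_unet(list(img), list(matrix(FALSE, 32, 32)),
                   spec = unet_spec(channels = c(4, 4, 8, 8, 8),
                                    dropout_p = 0),
                   epochs = 150, lr = 1e-2, seed = 4)
  expect_false(any(predict(fit0, img)))
})

test_that("cross-validation trains per fold and scores the held-out fold", {
  fx <- tiny_smears(6)
  imgs <- lapply(fx, `[[`, "image"); msks <- lapply(fx, `[[`, "mask")
  cv <- train_crossval(imgs, msks,
                       spec = unet_spec(channels = c(4, 4, 8, 8, 8),
                                        dropout_p = 0),
                       plan = fold_plan(6, 3, seed = 1),
                       augment = NULL, epochs = 2, seed = 9)
  expect_length(cv$fits, 3)
  expect_equal(nrow(cv$held_out), 3)
  expect_true(all(c("val_loss", "val_iou") %in% names(cv$histories[[1]])))
  expect_equal(nrow(cv$histories[[1]]), 2)
})

test_that("augmentation preserves the image/mask pairing", {
  fx <- tiny_smears(1, size = 32)[[1]]
  set.seed(8)
  for (i in 1:10) {
    au <- wbcseg:::apply_augment(fx$image, fx$mask, augment_policy())
    expect_identical(dim(au$image)[1:2], dim(au$mask))
    # foreground fraction is invariant under the geometric transforms
    expect_equal(mean(au$mask), mean(fx$mask), tolerance = 0.02)
  }
  # resize policy lands on the requested shape
  au <- wbcseg:::apply_augment(fx$image, fx$mask,
                               augment_policy(resize = 48))
  expect_equal(dim(au$mask), c(48L, 48L))
})
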